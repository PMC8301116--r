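test_that("SNV gives unit-variance zero-mean rows and is affine-invariant", {
  expect_equal(snv_transform(rbind(c(1, 2, 3), c(4, 6, 8)))[1, ], c(-1, 0, 1))

  set.seed(1)
  X <- matrix(rnorm(60), 5, 12)
  Z <- snv_transform(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv_transform(Z), Z, tolerance = 1e-12)      # idempotent
  expect_equal(snv_transform(3.7 * X + 2), Z, tolerance = 1e-10)

  sm <- rand_sm(3, 8, seed = 2)
  sm$X[2, ] <- 5
  expect_error(snv_transform(sm), "s2")
})

test_that("MSC inverts per-row affine scatter and matches a per-row OLS oracle", {
  set.seed(42)
  ref <- abs(rnorm(40)) + 1
  X <- rbind(2 * ref + 1, ref, 0.5 * ref - 2)
  out <- msc_fit(X, reference = ref)
  expect_equal(out$X[1, ], ref, tolerance = 1e-12)
  expect_equal(out$X[2, ], ref, tolerance = 1e-12)

  # scatter model: x_i = b_i s + a_i + noise; MSC recovers s up to noise
  s <- colMeans(matrix(abs(rnorm(200)), 4)) + 2
  b <- c(0.8, 1.1, 1.3, 0.9); a <- c(-0.5, 0.2, 0.9, 0)
  Xs <- t(vapply(1:4, function(i) b[i] * s + a[i] + rnorm(50, 0, 0.01),
                 numeric(50)))
  corr <- msc_fit(Xs, reference = s)$X
  expect_lt(max(abs(corr - rep(s, each = 4))), 0.05)
  # against stats::lm per row
  for (i in 1:4) {
    co <- coef(lm(Xs[i, ] ~ s))
    expect_equal(corr[i, ], (Xs[i, ] - co[1]) / co[2], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # idempotence with a fixed reference
  twice <- msc_apply(msc_apply(Xs, s), s)
  expect_equal(twice, msc_apply(Xs, s), tolerance = 1e-10)
})

test_that("mean-centering stores calibration means and reapplies them", {
  set.seed(3)
  X <- matrix(rnorm(48), 6, 8)
  cen <- mean_center(X)
  expect_lt(max(abs(colMeans(cen$X))), 1e-10)
  expect_equal(mean_center(matrix(1, 4, 3))$X, matrix(0, 4, 3))

  # a held-out duplicate of a calibration row reproduces its centered row
  dup <- X[3, , drop = FALSE]
  expect_equal(mean_center(dup, means = cen$means)$X, cen$X[3, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("ppm windows subset the grid as closed intervals", {
  syn <- small_synth(n = 4, points = 200)
  sm <- syn$spectra
  w <- window_set(c(220, 55))
  sub <- apply_windows(sm, w)
  expect_true(all(sub$grid >= 55 & sub$grid <= 220))
  expect_equal(sum(sm$grid >= 55 & sm$grid <= 220), length(sub$grid))

  full <- apply_windows(sm, window_set(c(221, -1)))
  expect_equal(full$X, sm$X)

  two <- apply_windows(sm, window_set(c(220, 150), c(100, 50)))
  expect_equal(length(two$grid),
               sum(sm$grid <= 220 & sm$grid >= 150) +
                 sum(sm$grid <= 100 & sm$grid >= 50))

  expect_error(window_set(c(50, 60)), "exceed")
  expect_error(window_set(c(100, 50), c(60, 20)), "overlap")
  expect_error(apply_windows(sm, window_set(c(300, 250))), "no grid points")
})

test_that("pretreatment chain is windows -> correction -> centering, fit on calibration only", {
  syn <- small_synth(n = 10, points = 300)
  cal <- structure(list(sample_ids = syn$spectra$sample_ids[1:7],
                        grid = syn$spectra$grid,
                        X = syn$spectra$X[1:7, ]), class = "spectra_matrix")
  val <- structure(list(sample_ids = syn$spectra$sample_ids[8:10],
                        grid = syn$spectra$grid,
                        X = syn$spectra$X[8:10, ]), class = "spectra_matrix")
  ft <- pretreat_fit(cal, kind = "msc", windows = window_set(c(220, 55)))
  expect_lt(max(abs(colMeans(ft$X$X))), 1e-10)
  expect_equal(length(ft$pre$msc_reference), length(ft$pre$grid))

  # applying to a duplicate of a calibration row reproduces that row
  dup <- structure(list(sample_ids = "dup", grid = cal$grid,
                        X = cal$X[2, , drop = FALSE]), class = "spectra_matrix")
  expect_equal(pretreat_apply(dup, ft$pre)$X, ft$X$X[2, , drop = FALSE],
               tolerance = 1e-10, ignore_attr = TRUE)

  # validation transform must use calibration parameters, not refit its own:
  # centering val with its own means would zero its column means; with the
  # calibration means it does not.
  va <- pretreat_apply(val, ft$pre)
  expect_gt(max(abs(colMeans(va$X))), 1e-6)
})
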