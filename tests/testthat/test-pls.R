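test_that("an exactly linear single-component system is solved by one LV", {
  set.seed(21)
  shape <- exp(-((1:40) - 20)^2 / 30)
  conc <- runif(8, 1, 5)
  X <- outer(conc, shape)
  m <- fit_pls(X, conc, n_lv = 1)
  pred <- predict(m, X)
  expect_lt(sqrt(mean((pred - conc)^2)), 1e-8)
  expect_equal(cor(pred, conc), 1, tolerance = 1e-9)
})

test_that("NIPALS matches the textbook oracle and least squares at full rank", {
  for (case in 1:20) {
    set.seed(100 + case)
    n <- sample(6:10, 1); p <- sample(8:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    a <- sample(2:4, 1)
    m <- fit_pls(X, y, n_lv = a)
    or <- oracle_nipals(X, y, a)
    for (j in seq_len(a)) {
      s <- sign(sum(m$W[, j] * or$W[, j]))
      expect_equal(m$W[, j], s * or$W[, j], tolerance = 1e-8)
      expect_equal(m$P[, j], s * or$P[, j], tolerance = 1e-8)
      expect_equal(m$q[j], s * or$q[j], tolerance = 1e-8)
      expect_equal(m$T[, j], s * or$T[, j], tolerance = 1e-8)
    }
    # full rank: predictions equal the minimum-norm least-squares predictions
    full <- fit_pls(X, y, n_lv = min(n - 1, p))
    expect_equal(predict(full, X), oracle_lsq_pred(X, y), tolerance = 1e-6)
  }
})

test_that("prediction is self-consistent and row-order invariant", {
  syn <- small_synth(n = 12, points = 256)
  X <- syn$spectra$X; y <- syn$refs$protein
  m <- fit_pls(X, y, n_lv = 3)
  expect_equal(predict(m, X), drop(X %*% m$regression_vector) + m$intercept,
               tolerance = 1e-12)
  expect_equal(predict(m, X[5, , drop = FALSE]), predict(m, X)[5],
               tolerance = 1e-10)

  perm <- sample(nrow(X))
  m2 <- fit_pls(X[perm, ], y[perm], n_lv = 3)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-8)

  expect_error(predict(m, matrix(0, 2, 5)), "grid length")
  expect_error(fit_pls(X, rep(1, nrow(X)), 2), "constant")
})

test_that("deflation residual decreases monotonically with added components", {
  set.seed(31)
  X <- matrix(rnorm(9 * 30), 9, 30)
  y <- rnorm(9)
  m <- fit_pls(X, y, n_lv = 6)
  C <- sweep(X, 2, m$x_means)
  res <- sapply(1:6, function(a) {
    Ta <- m$T[, 1:a, drop = FALSE]; Pa <- m$P[, 1:a, drop = FALSE]
    norm(C - Ta %*% t(Pa), "F")
  })
  expect_true(all(diff(res) < 0))
})

test_that("noise-free forward simulation is recovered within 1e-6", {
  cfg <- generator_config(n_samples = 12, grid_points = 400, noise_sd = 0,
                          scatter_slope_sd = 0, scatter_offset_sd = 0,
                          seed = 5)
  syn <- synthesize(cfg)
  m <- fit_pls(syn$spectra$X, syn$refs$protein, n_lv = 4)
  expect_lt(max(abs(predict(m, syn$spectra$X) - syn$refs$protein)), 1e-6)
})

test_that("leave-one-out RMSECV equals a brute-force oracle", {
  syn <- small_synth(n = 12, points = 128, noise = 0.02)
  X <- syn$spectra; y <- syn$refs$reducing_sugars
  for (kind in c("none", "snv")) {
    cv <- loo_cv(X, y, a_max = 4, kind = kind)
    expect_equal(cv$rmsecv_by_lv, oracle_loo_rmsecv(X$X, y, 4, kind),
                 tolerance = 1e-10)
  }
})

test_that("a noise-free one-component system cross-validates to zero error", {
  shape <- exp(-((1:50) - 25)^2 / 40)
  set.seed(22)
  conc <- runif(10, 1, 4)
  cv <- loo_cv(outer(conc, shape), conc, a_max = 1)
  expect_lt(cv$rmsecv_by_lv[1], 1e-6)
})

test_that("cross-validated correlation does not exceed calibration correlation", {
  syn <- synthesize(generator_config(seed = 3))
  run <- run_calibration(syn$spectra, syn$refs, seed = 3)
  expect_true(all(run$report$r_cv < run$report$r))
})

test_that("LV selection follows the parsimony plateau rule", {
  expect_equal(select_n_lv(c(5, 2, 1.99, 2.5), 0.02), 2L)
  expect_equal(select_n_lv(c(5, 3, 1, 1.001, 1.0005), 0.02), 3L)
  expect_equal(select_n_lv(c(4), 0.02), 1L)
  expect_equal(select_n_lv(c(3, 2.9, 2.89), 0), 3L)  # strict argmin when tol 0
})

test_that("VIP scores satisfy the normalization identity and closed forms", {
  set.seed(41)
  X <- matrix(rnorm(10 * 25), 10, 25)
  y <- rnorm(10)
  m <- fit_pls(X, y, n_lv = 3)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)

  m1 <- fit_pls(X, y, n_lv = 1)
  expect_equal(vip_scores(m1), sqrt(25) * abs(m1$W[, 1]), tolerance = 1e-10)
})

test_that("VIP localizes the informative spectral region", {
  # protein signal confined to 160-180 ppm; other components elsewhere
  pkdf <- function(center, width, amplitude)
    data.frame(center = center, width = width, amplitude = amplitude,
               shape = "lorentzian", stringsAsFactors = FALSE)
  basis <- list(
    lipid = structure(list(name = "lipid", peaks = pkdf(30, 2, 1)),
                      class = "component_basis"),
    polysaccharide = structure(list(name = "polysaccharide",
                                    peaks = pkdf(72, 2, 1)),
                               class = "component_basis"),
    protein = structure(list(name = "protein", peaks = pkdf(170, 3, 1)),
                        class = "component_basis"),
    polyphenol = structure(list(name = "polyphenol", peaks = pkdf(115, 2, 1)),
                           class = "component_basis"),
    tannin = structure(list(name = "tannin", peaks = pkdf(150, 2, 1)),
                       class = "component_basis"))
  cfg <- generator_config(n_samples = 20, grid_points = 512, noise_sd = 0.01,
                          closure = FALSE, seed = 9)
  syn <- synthesize(cfg, basis = basis)
  ft <- pretreat_fit(syn$spectra, kind = "none")
  m <- fit_pls(ft$X, syn$refs$protein, n_lv = 4)
  v <- vip_scores(m)
  inside <- syn$spectra$grid <= 180 & syn$spectra$grid >= 160
  expect_gt(mean(v[inside]), mean(v[!inside]))
})

test_that("PLS model files round-trip predictions bit-exactly", {
  syn <- small_synth(n = 10, points = 128)
  ft <- pretreat_fit(syn$spectra, kind = "msc", windows = window_set(c(220, 55)))
  m <- fit_pls(ft$X, syn$refs$fat, n_lv = 3, property_name = "fat",
               pre = ft$pre)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pls_model(m, f)
  m2 <- read_pls_model(f)
  newx <- pretreat_apply(syn$spectra, m2$pre)
  expect_identical(predict(m2, newx), predict(m, pretreat_apply(syn$spectra, ft$pre)))
  expect_equal(m2$property_name, "fat")
})
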