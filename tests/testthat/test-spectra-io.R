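test_that("xy-delimited parsing echoes input and normalizes orientation", {
  f <- withr::local_tempfile(fileext = ".xy")
  writeLines(c("200.0 1.0", "100.0 2.0"), f)
  s <- read_spectrum(f, "xy-delimited")
  expect_equal(s$ppm, c(200, 100))
  expect_equal(s$intensity, c(1, 2))

  # ascending rows give the identical spectrum after reversal
  writeLines(c("100.0 2.0", "200.0 1.0"), f)
  s2 <- read_spectrum(f, "xy-delimited")
  expect_equal(s2$ppm, s$ppm)
  expect_equal(s2$intensity, s$intensity)
})

test_that("spectrum invariants are enforced", {
  expect_error(nmr_spectrum(c(1, 1, 2), c(0, 0, 0)), "monotone")
  expect_error(nmr_spectrum(c(3, 2, 1), c(0, NA, 0)), "non-finite")
  expect_error(nmr_spectrum(numeric(0), numeric(0)), "at least 2")
  expect_error(nmr_spectrum(c(3, 2, 1), c(0, 0)), "equal length")
  expect_error(write_spectrum(structure(list(ppm = 1), class = "nmr_spectrum"),
                              tempfile()))
})

test_that("read/write round-trips are lossless for both dialects", {
  syn <- small_synth(n = 4, points = 3072)
  s <- nmr_spectrum(syn$spectra$grid, syn$spectra$X[1, ], sample_id = "rt",
                    meta = list(title = "rt", nucleus = "^13C"))
  for (d in c("xy-delimited", "jcamp-dx")) {
    f <- withr::local_tempfile(fileext = ".dx")
    write_spectrum(s, f, d)
    r <- read_spectrum(f, d)
    expect_equal(r$ppm, s$ppm, tolerance = 1e-9)
    expect_equal(r$intensity, s$intensity, tolerance = 1e-9)
  }
})

test_that("xy-delimited writer emits one line per point", {
  s <- nmr_spectrum(c(30, 20, 10), c(1, 2, 3))
  f <- withr::local_tempfile()
  write_spectrum(s, f, "xy-delimited")
  expect_length(readLines(f), 3L)
})

test_that("jcamp XYDATA tabular form is readable", {
  f <- withr::local_tempfile(fileext = ".dx")
  writeLines(c("##TITLE=tab", "##JCAMP-DX=4.24",
               "##NPOINTS=4", "##FIRSTX=200", "##LASTX=50",
               "##XYDATA=(X++(Y..Y))",
               "200 1.5 2.5", "100 3.5 4.5", "##END="), f)
  s <- read_spectrum(f, "jcamp-dx")
  expect_equal(s$ppm, c(200, 150, 100, 50))
  expect_equal(s$intensity, c(1.5, 2.5, 3.5, 4.5))
  expect_equal(s$meta$title, "tab")
})

test_that("assemble_matrix stacks, interpolates, and validates", {
  sp <- lapply(1:3, function(i)
    nmr_spectrum(c(200, 150, 100), c(i, i + 1, i + 2), sample_id = paste0("a", i)))
  m <- assemble_matrix(sp)
  expect_equal(dim(m$X), c(3L, 3L))
  expect_equal(m$X[2, ], c(2, 3, 4))

  # linear midpoint
  s1 <- nmr_spectrum(c(200, 100), c(0, 2), "m1")
  s2 <- nmr_spectrum(c(200, 100), c(1, 1), "m2")
  m2 <- assemble_matrix(list(s1, s2), grid = c(200, 150, 100))
  expect_equal(m2$X[1, 2], 1.0, ignore_attr = TRUE)

  expect_error(assemble_matrix(list(s1)), "at least 2")
  expect_error(assemble_matrix(list(s1, nmr_spectrum(c(200, 100), 1:2, "m1"))),
               "duplicate")
  s3 <- nmr_spectrum(c(90, 50), c(1, 2), "m3")
  expect_error(assemble_matrix(list(s1, s3)), "disjoint")
  expect_error(assemble_matrix(list(s1, s2), grid = c(250, 100)),
               "extrapolation")
})

test_that("interpolating smooth spectra to a finer grid and back is stable", {
  syn <- small_synth(n = 4, noise = 0, points = 600)
  g <- syn$spectra$grid
  sp <- nmr_spectrum(g, syn$spectra$X[1, ], "fine")
  fine <- seq(g[1], g[length(g)], length.out = 2 * length(g) - 1)
  up <- nmr_spectrum(fine, approx(sp$ppm, sp$intensity, xout = fine)$y, "up")
  up2 <- nmr_spectrum(fine, up$intensity, "up2")
  back <- assemble_matrix(list(up, up2), grid = g)
  interior <- 2:(length(g) - 1)
  expect_lt(max(abs(back$X[1, interior] - sp$intensity[interior])) /
              max(abs(sp$intensity)), 1e-6)
})

test_that("packaged reference table loads with 35 validated rows", {
  tbl <- load_reference_table()
  expect_s3_class(tbl, "reference_table")
  expect_equal(nrow(tbl), 35L)
  r30 <- tbl[tbl$sample_id == "30", ]
  expect_equal(r30$tp, 14.57)
  expect_equal(r30$abts, 264.8)
  expect_equal(r30$protein, 28.81)
  expect_equal(r30$n, 4.61)
  expect_equal(r30$ph, 5.80)
  r10 <- tbl[tbl$sample_id == "10", ]
  expect_equal(r10$tp, 4.16)
  expect_equal(r10$abts, 117.2)
})

test_that("reference-table invariants reject inconsistent rows", {
  tbl <- load_reference_table()
  f <- withr::local_tempfile(fileext = ".csv")
  bad <- tbl
  bad$protein[1] <- 20.0; bad$n[1] <- 4.0   # 6.25 * 4.0 = 25, not 20
  utils::write.csv(bad, f, row.names = FALSE, fileEncoding = "UTF-8")
  expect_error(load_reference_table(f), "6.25")

  bad2 <- tbl
  bad2$tp[3] <- -1
  utils::write.csv(bad2, f, row.names = FALSE, fileEncoding = "UTF-8")
  expect_error(load_reference_table(f), "positive")

  bad3 <- tbl
  bad3$nhcs[5] <- 10
  utils::write.csv(bad3, f, row.names = FALSE, fileEncoding = "UTF-8")
  expect_error(load_reference_table(f), "NHCS")
})

test_that("spectra-matrix CSV round-trips", {
  syn <- small_synth(n = 4, points = 64)
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(syn$spectra, f)
  m <- read_matrix_csv(f)
  expect_equal(m$sample_ids, syn$spectra$sample_ids)
  expect_equal(m$grid, syn$spectra$grid, tolerance = 1e-12)
  expect_equal(m$X, syn$spectra$X, tolerance = 1e-12, ignore_attr = TRUE)
})
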