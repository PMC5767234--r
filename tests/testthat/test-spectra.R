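make_ladder_spectrum <- function(mz0, intensities, rt, jitter = 0) {
  n <- length(intensities) - 1L
  centroid_spectrum(mz = mz0 + (0:n) * c13_spacing() + jitter,
                    intensity = intensities, rt = rt)
}

test_that("spectrum constructor enforces ordering and non-negativity", {
  s <- centroid_spectrum(c(150, 100), c(2, 1), rt = 5)
  expect_equal(s$mz, c(100, 150))  # sorted
  expect_equal(s$intensity, c(1, 2))
  expect_error(centroid_spectrum(c(100, 100), c(1, 1), rt = 1), "increasing")
  expect_error(centroid_spectrum(100, -1, rt = 1), "non-negative")
})

test_that("delimited spectra tables round-trip", {
  spectra <- list(
    centroid_spectrum(c(100.1, 200.2, 300.3), c(10, 20, 30), rt = 1.5,
                      polarity = "neg"),
    centroid_spectrum(c(151.05, 152.05), c(5, 1), rt = 2.0, ms_level = 2L,
                      precursor_mz = 151.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(spectra, path)
  back <- read_spectra(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-9)
  expect_equal(back[[1]]$intensity, spectra[[1]]$intensity, tolerance = 1e-9)
  expect_equal(back[[2]]$precursor_mz, 151.05)
  expect_equal(back[[2]]$ms_level, 2L)
  expect_error(read_spectra(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})

test_that("mzML export and import round-trip through mzR", {
  spectra <- list(
    centroid_spectrum(c(100.5, 250.25, 900.125), c(1e3, 5e4, 2e2), rt = 3.25,
                      polarity = "pos"),
    centroid_spectrum(c(167.0348, 168.0382), c(5e3, 4e2), rt = 9.9,
                      polarity = "neg"))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_spectra(spectra, path)
  back <- read_spectra(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$mz, spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, spectra[[i]]$intensity, tolerance = 1e-3)
    expect_equal(back[[i]]$rt, spectra[[i]]$rt, tolerance = 1e-6)
  }
})

test_that("a single on-target peak fills only the M0 slot", {
  tg <- feature_target("f1", 200.0, 5.0, "C5H10O5")
  s <- centroid_spectrum(200.0, 1234, rt = 5.0)
  m <- extract_isotopologues(list(s), tg)
  expect_equal(unname(m$intensity), c(1234, 0, 0, 0, 0, 0))
  expect_false(m$empty)
})

test_that("a planted ladder is recovered exactly and linearly", {
  planted <- c(100, 80, 60, 40, 20, 10)
  tg <- feature_target("f1", 300.0, 8.0, "C5H8O4")
  s <- make_ladder_spectrum(300.0, planted, rt = 8.0)
  m <- extract_isotopologues(list(s), tg)
  expect_equal(unname(m$intensity), planted)
  # linearity: doubling intensities doubles every slot
  s2 <- make_ladder_spectrum(300.0, planted * 2, rt = 8.0)
  expect_equal(extract_isotopologues(list(s2), tg)$intensity,
               2 * m$intensity)
  # intensities sum across spectra within the RT window
  m2 <- extract_isotopologues(list(s, s), tg)
  expect_equal(m2$intensity, 2 * m$intensity)
})

test_that("an orsellinic-acid-like ladder m/z 167..174 gives 8 shifted slots", {
  # 8-carbon feature whose parent ions shift from m/z 167 up to m/z 174
  tg <- feature_target("ors", 167.0348, 9.9, "C8H8O4")
  s <- make_ladder_spectrum(167.0348, c(5, 10, 20, 40, 60, 50, 30, 20, 10) * 100,
                            rt = 9.9)
  m <- extract_isotopologues(list(s), tg)
  expect_length(m$intensity, 9L)
  expect_equal(sum(m$intensity > 0), 9L)
  expect_gt(total_incorporation(relative_isotopic_abundance(m)), 0)
})

test_that("tightening the m/z tolerance never increases any slot", {
  tg <- feature_target("f1", 400.0, 2.0, "C10H20O2")
  set.seed(42)
  # peaks scattered on and off the ladder
  mz <- sort(400.0 + c(runif(10, -0.4, 10.4), (0:10) * c13_spacing() + rnorm(11, 0, 2e-3)))
  s <- centroid_spectrum(mz, runif(length(mz), 10, 100), rt = 2.0)
  tols <- c(50, 20, 10, 5, 1)
  prev <- NULL
  for (tol in tols) {
    cur <- extract_isotopologues(list(s), tg, mz_tol = tol)$intensity
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("disjoint RT windows partition the extracted intensity", {
  tg1 <- feature_target("f1", 500.0, 5.0, "C4H8O2")
  tg2 <- feature_target("f2", 500.0, 7.0, "C4H8O2")
  spectra <- list(make_ladder_spectrum(500.0, c(10, 5, 2, 1, 1), rt = 5.0),
                  make_ladder_spectrum(500.0, c(20, 8, 3, 2, 1), rt = 7.0))
  both <- feature_target("all", 500.0, 6.0, "C4H8O2")
  total <- extract_isotopologues(spectra, both, rt_window = 5)$intensity
  part <- extract_isotopologues(spectra, tg1, rt_window = 0.5)$intensity +
    extract_isotopologues(spectra, tg2, rt_window = 0.5)$intensity
  expect_equal(part, total)
})

test_that("no spectra inside the RT window yields a flagged empty result", {
  tg <- feature_target("f1", 300.0, 20.0, "C3H6O3")
  s <- make_ladder_spectrum(300.0, c(1, 1, 1, 1), rt = 2.0)
  m <- extract_isotopologues(list(s), tg)
  expect_true(m$empty)
  expect_equal(sum(m$intensity), 0)
})

test_that("MGF files round-trip spectra, precursors and group tags", {
  spectra <- list(
    msms_spectrum(279.0656, c(77.04, 117.03, 235.08), c(100, 50, 80),
                  id = "p279", group = "co"),
    msms_spectrum(490.3025, c(120.5, 300.25), c(10, 20), id = "p490",
                  group = "monoA"))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mz, 279.0656, tolerance = 1e-6)
  expect_equal(back[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-6)
  expect_identical(back[[1]]$id, "p279")
  expect_identical(back[[2]]$group, "monoA")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "50 1"), path)
  expect_error(read_mgf(path), "unterminated")
})
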