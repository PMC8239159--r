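test_that("centroiding collapses profile regions to weighted centroids", {
  s <- spectrum(c(100.00, 100.01, 100.02), c(10, 100, 10), rt = 1,
                centroided = FALSE)
  c1 <- centroidSpectrum(s)
  expect_equal(nrow(c1@peaks), 1L)
  expect_equal(unname(c1@peaks[1, "mz"]),
               (100.00 * 10 + 100.01 * 100 + 100.02 * 10) / 120)
  expect_equal(unname(c1@peaks[1, "intensity"]), 100)

  # single isolated point survives as itself
  s2 <- centroidSpectrum(spectrum(500, 42, rt = 1, centroided = FALSE))
  expect_equal(unname(s2@peaks[1, ]), c(500, 42))

  # flat zero spectrum empties out
  s3 <- centroidSpectrum(spectrum(c(1, 2, 3), c(0, 0, 0), rt = 1,
                                  centroided = FALSE))
  expect_equal(nrow(s3@peaks), 0L)

  # two maxima in one region split at the internal minimum
  s4 <- centroidSpectrum(spectrum(100 + (0:4) / 100, c(10, 90, 5, 80, 10),
                                  rt = 1, centroided = FALSE))
  expect_equal(nrow(s4@peaks), 2L)
  expect_equal(unname(s4@peaks[, "intensity"]), c(90, 80))
})

test_that("centroiding is idempotent", {
  set.seed(3)
  mz <- sort(runif(200, 100, 1000))
  int <- rexp(200) * 100
  int[sample(200, 50)] <- 0
  s <- spectrum(mz, int, rt = 5, centroided = FALSE)
  once <- centroidSpectrum(s)
  twice <- centroidSpectrum(once)
  expect_identical(once@peaks, twice@peaks)
  expect_true(all(diff(once@peaks[, "mz"]) > 0))
})

test_that("charge derivation reads the isotope spacing", {
  s <- spectrum(c(500, 500.5017), c(100, 60), rt = 1)
  expect_equal(deriveCharge(s, 500, maxCharge = 3), 2L)
  s1 <- spectrum(c(500, 501.0034), c(100, 60), rt = 1)
  expect_equal(deriveCharge(s1, 500, maxCharge = 3), 1L)
  lone <- spectrum(500, 100, rt = 1)
  expect_true(is.na(deriveCharge(lone, 500, maxCharge = 3)))
  # both spacings present: the larger (more specific) charge wins
  s2 <- spectrum(c(500, 500.5017, 501.0034), c(100, 60, 40), rt = 1)
  expect_equal(deriveCharge(s2, 500, maxCharge = 3), 2L)
  expect_error(deriveCharge(s, 500, maxCharge = 0), "maxCharge")
})

test_that("bucket queries equal a linear scan", {
  set.seed(99)
  specs <- lapply(1:5, function(i)
    spectrum(sort(runif(200, 100, 2000)), rexp(200) * 1000, rt = i,
             scanId = paste0("s", i)))
  run <- msRun(specs)
  idx <- buildPeakIndex(run, bucketWidth = 0.5)

  # self-retrieval at zero tolerance
  some <- idx@peaks[sample(nrow(idx@peaks), 50), ]
  for (i in seq_len(nrow(some)))
    expect_true(some$mz[i] %in% queryPeakIndex(idx, some$mz[i], 0)$mz)

  # random queries vs the linear-scan oracle
  for (i in 1:200) {
    m <- runif(1, 90, 2010)
    tol <- runif(1, 0, 2)
    got <- queryPeakIndex(idx, m, tol)
    want <- oracleQuery(idx@peaks, m, tol)
    expect_equal(got$mz, want$mz)
    expect_equal(got$intensity, want$intensity)
    expect_equal(got$scan, want$scan)
  }

  # empty region
  expect_equal(nrow(queryPeakIndex(idx, 5000, 1)), 0L)
  expect_error(buildPeakIndex(run, 0), "bucketWidth")
})

test_that("mzML writing and reading round-trips a run", {
  set.seed(5)
  specs <- lapply(1:3, function(i)
    spectrum(sort(runif(50, 200, 1500)), rexp(50) * 1e4, rt = i * 1.5,
             scanId = paste0("scan=", i)))
  run <- msRun(specs)
  path <- tempfile(fileext = ".mzML")
  writeMzML(run, path)
  back <- readMzML(path)
  expect_length(spectra(back), 3L)
  expect_equal(scanTimes(back), scanTimes(run), tolerance = 1e-6)
  for (i in 1:3) {
    expect_equal(spectra(back)[[i]]@peaks[, "mz"],
                 spectra(run)[[i]]@peaks[, "mz"], tolerance = 1e-6)
    expect_equal(spectra(back)[[i]]@peaks[, "intensity"],
                 spectra(run)[[i]]@peaks[, "intensity"], tolerance = 1e-6)
  }
})

test_that("runs are sorted by rt on construction and read", {
  shuffled <- list(spectrum(100, 1, rt = 9), spectrum(100, 1, rt = 2),
                   spectrum(100, 1, rt = 5))
  run <- msRun(shuffled)
  expect_equal(scanTimes(run), c(2, 5, 9))
  path <- tempfile(fileext = ".mzML")
  writeMzML(run, path)
  expect_equal(scanTimes(readMzML(path)), c(2, 5, 9), tolerance = 1e-9)
})

test_that("unreadable input is a fatal error naming the file", {
  bad <- tempfile(fileext = ".mzML")
  writeLines("this is not xml", bad)
  expect_error(readMzML(bad), basename(bad))
  expect_error(readMzML(tempfile()), "not found")
})
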