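traceOf <- function(intensity, rt = seq_along(intensity)) {
  new("XICTrace", composition = "HexNAc2Hex3Fuc0NeuAc0", charge = 1L,
      adduct = "proton", rt = as.numeric(rt),
      intensity = as.numeric(intensity), isotopeMz = c(1, 2, 3))
}

test_that("apex-first detection follows the boundary-and-minimum walk", {
  # hand-executed: apex 100, 50 >= 50 passes, minima extension reaches ends
  p <- detectPeaks(traceOf(c(10, 50, 100, 50, 10)), 0.5)
  expect_equal(nrow(p), 1L)
  expect_equal(p$apexRt, 3)
  expect_equal(p$leftRt, 1)
  expect_equal(p$rightRt, 5)

  # two gaussians separated by a deep valley resolve as two peaks
  rt <- seq(0, 10, 0.1)
  y <- 100 * exp(-(rt - 3)^2 / 0.5) + 80 * exp(-(rt - 7)^2 / 0.5)
  p2 <- detectPeaks(traceOf(y, rt), 0.5)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$apexRt, c(3, 7), tolerance = 1e-9)

  # monotone ramp: single peak with apex at the end
  p3 <- detectPeaks(traceOf(c(1, 2, 3, 4)), 0.5)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$apexRt, 4)

  # all-zero trace yields nothing
  expect_equal(nrow(detectPeaks(traceOf(rep(0, 5)), 0.5)), 0L)
  expect_error(detectPeaks(traceOf(1:3), 1.5), "boundaryCutoff")
})

test_that("detection is invariant to uniform rt shifts", {
  set.seed(31)
  y <- abs(rnorm(80)) + 50 * exp(-(seq(0, 7.9, 0.1) - 4)^2 / 0.3)
  a <- detectPeaks(traceOf(y, seq(0, 7.9, 0.1)), 0.5)
  b <- detectPeaks(traceOf(y, seq(0, 7.9, 0.1) + 13.7), 0.5)
  expect_equal(b$apexRt, a$apexRt + 13.7)
  expect_equal(b$leftRt, a$leftRt + 13.7)
  expect_equal(b$rightRt, a$rightRt + 13.7)
})

test_that("two-isomer pairs with sub-cutoff valleys are resolved >= 95%", {
  set.seed(17)
  hits <- 0L
  for (i in 1:100) {
    sep <- runif(1, 1.8, 3)
    h1 <- runif(1, 50, 150); h2 <- runif(1, 50, 150)
    rt <- seq(0, 10, 0.05)
    y <- h1 * exp(-(rt - 4)^2 / (2 * 0.3^2)) +
      h2 * exp(-(rt - 4 - sep)^2 / (2 * 0.3^2))
    # keep only pairs whose valley is below half the lower apex
    valley <- min(y[rt > 4 & rt < 4 + sep])
    if (valley >= 0.5 * min(h1, h2)) next
    p <- detectPeaks(traceOf(y, rt), 0.5)
    hits <- hits + (nrow(p) == 2L)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("integration matches closed forms", {
  # rectangle: constant 100 over 2 minutes
  expect_equal(integratePeak(traceOf(rep(100, 21), seq(0, 2, 0.1)), 0, 2), 200)
  # triangle
  expect_equal(integratePeak(traceOf(c(0, 100, 0), c(0, 1, 2)), 0, 2), 100)
  # gaussian over +-4 sigma vs h * sigma * sqrt(2 pi)
  h <- 250; sg <- 0.2
  rt <- seq(0, 10, 0.01)
  tr <- traceOf(h * exp(-(rt - 5)^2 / (2 * sg^2)), rt)
  expect_equal(integratePeak(tr, 5 - 4 * sg, 5 + 4 * sg),
               h * sg * sqrt(2 * pi), tolerance = 0.02)
  # literal summation option
  expect_equal(integratePeak(traceOf(c(1, 2, 3), 1:3), 1, 3, "sum"), 6)
  # zero-width span and inverted bounds
  expect_equal(integratePeak(tr, 5, 5), 0)
  expect_error(integratePeak(tr, 6, 5), "bounds")
})

test_that("areas are linear in intensity and bounded by the trace total", {
  set.seed(23)
  rt <- seq(0, 20, 0.05)
  y <- 100 * exp(-(rt - 5)^2 / 0.2) + 70 * exp(-(rt - 12)^2 / 0.3) +
    abs(rnorm(length(rt), 0, 0.5))
  tr <- traceOf(y, rt)
  tr2 <- traceOf(2 * y, rt)
  p <- detectPeaks(tr, 0.5)
  p2 <- detectPeaks(tr2, 0.5)
  a <- vapply(seq_len(nrow(p)), function(k)
    integratePeak(tr, p$leftRt[k], p$rightRt[k]), numeric(1))
  a2 <- vapply(seq_len(nrow(p2)), function(k)
    integratePeak(tr2, p2$leftRt[k], p2$rightRt[k]), numeric(1))
  expect_equal(a2, 2 * a, tolerance = 1e-12)
  expect_lte(sum(a), integratePeak(tr, min(rt), max(rt)) + 1e-9)
})

test_that("XICs recover planted elution profiles and absences", {
  gl <- glycanRow("HexNAc2Hex5Fuc0NeuAc0", gui = 3.0, height = 2e5)
  run <- generateRun(synthSpec(guRange = 2:4, glycans = gl, seed = 2,
                               rtRange = c(8, 25)))
  idx <- buildPeakIndex(run)
  cfg <- guConfig()
  tr <- buildXIC(run, idx, "HexNAc2Hex5Fuc0NeuAc0", 1L, "proton", cfg)
  gt <- groundTruth(run)$glycans
  apex <- tr@rt[which.max(tr@intensity)]
  expect_equal(apex, gt$rt)
  env <- isotopeEnvelope(glycanFormula(glycanComposition(2, 5)))
  p <- envelopeProbabilities(env)
  top3 <- sum(sort(p, decreasing = TRUE)[1:3]) / max(p)
  expect_equal(max(tr@intensity), gt$height * top3, tolerance = 1e-6)

  # absent glycan: all-zero trace of full MS1 length
  tr0 <- buildXIC(run, idx, "HexNAc4Hex4Fuc0NeuAc0", 1L, "proton", cfg)
  expect_equal(length(tr0@rt), length(ms1Indices(run)))
  expect_true(all(tr0@intensity == 0))
})

test_that("only the monoisotopic peak present still yields its intensity", {
  comp <- glycanComposition(2, 3)
  env <- isotopeEnvelope(glycanFormula(comp))
  monoMz <- ionMz(env@masses[1], 1)
  run <- msRun(list(spectrum(monoMz, 5000, rt = 1),
                    spectrum(monoMz * 2, 10, rt = 2)))
  tr <- buildXIC(run, buildPeakIndex(run), comp, 1L, "proton", guConfig())
  expect_equal(tr@intensity, c(5000, 0))
})

test_that("isomer areas add across charge states and scale linearly", {
  gl <- rbind(glycanRow("HexNAc2Hex5Fuc0NeuAc0", gui = 3.0, charge = 1L,
                        height = 2e5),
              glycanRow("HexNAc2Hex5Fuc0NeuAc0", gui = 3.0, charge = 2L,
                        height = 1e5),
              glycanRow("HexNAc2Hex5Fuc0NeuAc0", gui = 4.2, charge = 1L,
                        height = 3e5))
  spec <- synthSpec(guRange = 2:5, glycans = gl, seed = 6, rtRange = c(8, 28))
  run <- generateRun(spec)
  idx <- buildPeakIndex(run)
  cfg <- guConfig(maxHexNAc = 2, maxHex = 5, maxFuc = 0, maxNeuAc = 0,
                  guRange = 2:5)
  obs <- extractLadderCandidates(run, idx, cfg)
  model <- fitCalibration(ladderAssignment(assignLadder(obs, 2:5))[, c("rt", "gu")])
  ann <- annotateRun(run, idx, model, cfg)
  q <- quantifyRun(ann, run, idx, model, cfg)
  expect_equal(nrow(q), 2L)
  gt <- groundTruth(run)$glycans
  # isomer 1 sums the z=1 and z=2 planted areas
  expect_equal(q$area[1], sum(gt$analyticArea[gt$rt == q$apexRt[1]]),
               tolerance = 0.02)
  expect_equal(q$area[2], gt$analyticArea[3], tolerance = 0.02)
  expect_equal(q$totalArea, rep(sum(q$area), 2))
  expect_equal(q$gui, c(3.0, 4.2), tolerance = 0.05)

  # doubling every planted intensity doubles every area
  run2 <- generateRun(local({
    s2 <- spec
    s2$glycans$height <- s2$glycans$height * 2
    s2$ladderHeight <- s2$ladderHeight * 2
    s2
  }))
  idx2 <- buildPeakIndex(run2)
  ann2 <- annotateRun(run2, idx2, model, cfg)
  q2 <- quantifyRun(ann2, run2, idx2, model, cfg)
  expect_equal(q2$area, 2 * q$area, tolerance = 1e-9)
})
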