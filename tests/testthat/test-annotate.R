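# plant the exact theoretical envelope of a composition in one spectrum
plantSpectrum <- function(comp, charge = 1L, adduct = "proton", rt = 10,
                          scale = 1e5, jitter = NULL) {
  env <- isotopeEnvelope(glycanFormula(comp))
  len <- glycoGU:::.envelopeLength(env)
  anchor <- env@mostAbundant
  anchorMz <- ionMz(env@masses[anchor], charge, adduct)
  mz <- anchorMz + (seq_len(len) - anchor) * 1.0033548378 / charge
  int <- env@probabilities[seq_len(len)] * scale
  if (!is.null(jitter)) int <- int * jitter(length(int))
  spectrum(mz, int, rt = rt)
}

test_that("planted envelopes match with proportional intensities", {
  comp <- glycanComposition(2, 5)
  s <- plantSpectrum(comp)
  m <- matchEnvelope(s, comp)
  expect_false(is.null(m))
  expect_equal(m@observed / sum(m@observed),
               m@theoretical / sum(m@theoretical), tolerance = 1e-9)
  expect_equal(scoreMatch(m), 1, tolerance = 1e-12)
})

test_that("a missing anchor peak rejects the whole match", {
  comp <- glycanComposition(2, 5)
  s <- plantSpectrum(comp)
  env <- isotopeEnvelope(glycanFormula(comp))
  drop <- env@mostAbundant
  s2 <- spectrum(s@peaks[-drop, "mz"], s@peaks[-drop, "intensity"], rt = 10)
  expect_null(matchEnvelope(s2, comp))
})

test_that("an envelope planted at z=2 is not matched at z=1", {
  comp <- glycanComposition(4, 5, 1, 0)
  s <- plantSpectrum(comp, charge = 2L)
  expect_null(matchEnvelope(s, comp, charge = 1L))
  expect_false(is.null(matchEnvelope(s, comp, charge = 2L)))
})

test_that("the Pearson score is linear-invariant and matches hand values", {
  m <- new("EnvelopeMatch", theoretical = c(5, 3, 1), observed = c(5, 3, 1),
           mz = c(1, 2, 3), anchorIndex = 1L)
  expect_equal(scoreMatch(m), 1)

  set.seed(13)
  for (i in 1:25) {
    t <- sort(rexp(sample(3:8, 1)), decreasing = TRUE)
    a <- runif(1, 0.1, 10); b <- runif(1, 0, 100)
    m2 <- new("EnvelopeMatch", theoretical = t, observed = a * t + b,
              mz = seq_along(t), anchorIndex = 1L)
    expect_equal(scoreMatch(m2), 1, tolerance = 1e-12)
  }

  # reversed strictly-decaying 3-peak envelope, hand Pearson:
  # t = (5,3,1), o = (1,3,5): r = cov/(sd t * sd o) = -1 exactly
  m3 <- new("EnvelopeMatch", theoretical = c(5, 3, 1), observed = c(1, 3, 5),
            mz = 1:3, anchorIndex = 1L)
  expect_equal(scoreMatch(m3), -1)

  # zero variance is undefined, hence rejected
  m4 <- new("EnvelopeMatch", theoretical = c(5, 3, 1), observed = c(2, 2, 2),
            mz = 1:3, anchorIndex = 1L)
  expect_true(is.na(scoreMatch(m4)))
})

annotateSmallRun <- function(glycans, seed = 1, perturb = 0,
                             cutoff = 0.9, decoyDensity = 0) {
  spec <- synthSpec(guRange = 2:6, glycans = glycans, seed = seed,
                    rtRange = c(8, 35), decoyDensity = decoyDensity)
  run <- generateRun(spec)
  if (perturb > 0) {
    set.seed(seed + 1000L)
    run <- msRun(lapply(spectra(run), function(s) {
      p <- s@peaks
      if (nrow(p) == 0L) return(s)
      spectrum(p[, 1], p[, 2] * runif(nrow(p), 1 - perturb, 1 + perturb),
               s@rt, s@scanId, s@msLevel)
    }), metadata = run@metadata)
  }
  cfg <- guConfig(maxHexNAc = 4, maxHex = 6, maxFuc = 1, maxNeuAc = 1,
                  guRange = 2:6, scoreCutoff = cutoff)
  idx <- buildPeakIndex(run)
  obs <- extractLadderCandidates(run, idx, cfg)
  model <- fitCalibration(ladderAssignment(assignLadder(obs, 2:6))[, c("rt", "gu")],
                          "polynomial", 3)
  list(run = run,
       ann = annotateRun(run, idx, model, cfg))
}

fiveGlycans <- function() {
  data.frame(
    composition = c("HexNAc2Hex3Fuc0NeuAc0", "HexNAc2Hex5Fuc0NeuAc0",
                    "HexNAc3Hex4Fuc1NeuAc0", "HexNAc4Hex5Fuc0NeuAc1",
                    "HexNAc4Hex6Fuc1NeuAc1"),
    charge = c(1L, 1L, 1L, 2L, 2L), adduct = "proton",
    gui = c(2.5, 3.2, 4.0, 4.8, 5.5), rt = NA_real_,
    height = c(2e5, 3e5, 2.5e5, 4e5, 3.5e5), sigma = 0.15,
    stringsAsFactors = FALSE)
}

test_that("zero-noise planted glycans are recovered exactly and soundly", {
  res <- annotateSmallRun(fiveGlycans())
  gt <- groundTruth(res$run)$glycans
  expect_setequal(unique(res$ann$composition), gt$composition)
  for (i in seq_len(nrow(gt))) {
    ai <- res$ann[res$ann$composition == gt$composition[i], ]
    expect_true(gt$rt[i] %in% ai$rt)           # planted apex annotated
    expect_true(all(ai$score >= 0.9))
    apex <- ai[which.min(abs(ai$rt - gt$rt[i])), ]
    expect_equal(apex$score, 1, tolerance = 1e-9)  # uncorrupted envelope
    expect_equal(apex$charge, gt$charge[i])
  }
  # deterministic output order
  expect_false(is.unsorted(order(res$ann$composition, res$ann$rt,
                                 res$ann$charge)))
})

test_that("five percent envelope perturbation keeps recovery above 95%", {
  recovered <- 0L
  total <- 0L
  for (s in 1:25) {
    res <- annotateSmallRun(fiveGlycans(), seed = s, perturb = 0.05)
    gt <- groundTruth(res$run)$glycans
    total <- total + nrow(gt)
    recovered <- recovered +
      sum(gt$composition %in% res$ann$composition)
  }
  expect_gte(recovered / total, 0.95)
})

test_that("annotation count is monotone in the score cutoff", {
  res9 <- annotateSmallRun(fiveGlycans(), perturb = 0.05, cutoff = 0.9)
  res99 <- annotateSmallRun(fiveGlycans(), perturb = 0.05, cutoff = 0.999999)
  expect_lte(nrow(res99$ann), nrow(res9$ann))
})
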