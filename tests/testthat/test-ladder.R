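# helper: build an observation table from an intensity matrix I[scan, gu]
obsFromMatrix <- function(I, gus, rts = seq_len(nrow(I))) {
  rows <- which(I > 0, arr.ind = TRUE)
  data.frame(gu = gus[rows[, 2]], scan = rows[, 1],
             scanId = paste0("s", rows[, 1]), rt = rts[rows[, 1]],
             mz = 500, intensity = I[rows], charge = 1L, adduct = "proton",
             stringsAsFactors = FALSE)
}

test_that("DP resolves the worked elution sequences", {
  # three scans, unambiguous ladder with one decoy GU3 match at t1
  I <- rbind(c(100, 10, 0), c(0, 80, 0), c(0, 0, 90))
  obs <- obsFromMatrix(I, gus = 2:4)
  a <- ladderAssignment(assignLadder(obs, 2:4))
  expect_equal(a$gu, 2:4)
  expect_equal(a$rt, 1:3)
  expect_equal(a$intensity, c(100, 80, 90))

  # a decoy GU5 spike before GU3's true elution is excluded by the order
  # constraint (GU rows: 2,3,4,5)
  I2 <- rbind(c(100, 0, 0, 30),    # t1: true GU2 + decoy GU5
              c(0, 90, 0, 0),      # t2: true GU3
              c(0, 0, 85, 0),      # t3: true GU4
              c(0, 0, 0, 70))      # t4: true GU5
  a2 <- ladderAssignment(assignLadder(obsFromMatrix(I2, 2:5), 2:5))
  expect_equal(a2$gu, 2:5)
  expect_equal(a2$rt, 1:4)

  # single GU observed once
  a3 <- ladderAssignment(assignLadder(obsFromMatrix(matrix(50), 7), 7))
  expect_equal(a3$gu, 7L)
  expect_equal(a3$rt, 1)
})

test_that("DP total equals exhaustive enumeration on random instances", {
  set.seed(21)
  for (rep in 1:30) {
    nS <- sample(3:8, 1)
    nU <- sample(2:6, 1)
    I <- matrix(0, nS, nU)
    nz <- sample(length(I), ceiling(length(I) * 0.4))
    I[nz] <- round(runif(length(nz), 1, 100))
    if (all(I == 0)) next
    gus <- seq(2, 1 + nU)
    obs <- obsFromMatrix(I, gus)
    if (nrow(obs) == 0L) next
    fit <- suppressWarnings(assignLadder(obs, gus))
    a <- ladderAssignment(fit)
    expect_true(all(diff(a$rt[order(a$gu)]) > 0))
    # the DP optimum equals exhaustive enumeration over all
    # order-respecting assignments (ties between paths are legal)
    expect_equal(glycoGU:::.ladderOptimum(I), oracleLadderScore(I))
  }
})

test_that("assigned rts strictly increase with GU and gaps warn", {
  I <- rbind(c(100, 0, 0), c(0, 0, 0), c(0, 0, 90))   # GU3 never observed
  obs <- obsFromMatrix(I, 2:4)
  expect_warning(fit <- assignLadder(obs, 2:4), "GU 3")
  a <- ladderAssignment(fit)
  expect_equal(a$gu, c(2L, 4L))
  expect_true(all(diff(a$rt) > 0))
})

test_that("planted ladder ions are recovered at their planted rts", {
  run <- generateRun(synthSpec(seed = 4))
  idx <- buildPeakIndex(run)
  cfg <- guConfig()
  obs <- extractLadderCandidates(run, idx, cfg)
  gt <- groundTruth(run)$ladder
  expect_setequal(unique(obs$gu), 2:12)
  for (g in 2:12) {
    og <- obs[obs$gu == g, ]
    expect_true(gt$rt[gt$gu == g] %in% og$rt)
    # the apex-scan observation carries the planted height
    expect_equal(max(og$intensity), gt$height[gt$gu == g], tolerance = 1e-6)
  }
  a <- ladderAssignment(assignLadder(obs, 2:12))
  expect_equal(a$rt, gt$rt)
})

test_that("ions outside tolerance are not matched", {
  run <- generateRun(synthSpec(seed = 4))
  # shift every peak by 5x the 10 ppm tolerance
  shifted <- msRun(lapply(spectra(run), function(s) {
    p <- s@peaks
    spectrum(p[, 1] * (1 + 50e-6), p[, 2], s@rt, s@scanId, s@msLevel)
  }))
  idx <- buildPeakIndex(shifted)
  obs <- extractLadderCandidates(shifted, idx, guConfig())
  expect_equal(nrow(obs), 0L)
})

test_that("one observation per spectrum keeps the max across charges", {
  env1 <- isotopeEnvelope(dextrinFormula(3))
  m1 <- ionMz(env1@masses[env1@mostAbundant], 1)
  m2 <- ionMz(env1@masses[env1@mostAbundant], 2)
  s <- spectrum(sort(c(m1, m2)), c(300, 700)[order(c(m1, m2))], rt = 5)
  run <- msRun(list(s))
  obs <- extractLadderCandidates(run, buildPeakIndex(run),
                                 guConfig(guRange = 3))
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$intensity, 700)
  expect_equal(obs$charge, 2L)
})
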