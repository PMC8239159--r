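# Synthetic LC-MS run generator.
#
# Emulates a permethylated serum glycomics injection spiked with a dextrin
# ladder: ladder rungs GU 2-12 elute along a smooth, monotone GU-vs-rt
# curve; each planted species contributes its full aggregated isotope
# envelope scaled by a Gaussian elution profile; decoy peaks are uniform in
# m/z with log-normal intensities. Every generated run carries a
# ground-truth manifest (planted species, apex rts, heights, analytic
# areas) in its metadata, against which the pipeline's output is checked.

#' Default glucose-unit elution curve
#'
#' A monotone cubic mapping retention time (minutes) to GUI, placing GU 2-12
#' between roughly 10 and 55 minutes — the regime of a typical C18 gradient
#' for permethylated dextrins. Returned as a list with \code{guiAt(rt)} and
#' its numeric inverse \code{rtAt(gui)}.
#'
#' @return list with functions \code{guiAt}, \code{rtAt} and the coefficient
#'   vector \code{coef} (cubic in rt - 10)
#' @export
defaultGuCurve <- function() {
  cf <- c(2, 0.15, 0.0015, 0.000005)     # in powers of (rt - 10)
  guiAt <- function(rt) {
    x <- rt - 10
    cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
  }
  rtAt <- function(gui) {
    vapply(gui, function(g)
      stats::uniroot(function(rt) guiAt(rt) - g, c(-20, 200),
                     tol = 1e-10)$root, numeric(1))
  }
  list(guiAt = guiAt, rtAt = rtAt, coef = cf)
}

#' Specify a synthetic run
#'
#' @param guCurve elution curve as from \code{\link{defaultGuCurve}}
#' @param guRange ladder rungs to plant
#' @param ladderHeight apex intensity of the GU-2 rung; higher rungs decay
#'   geometrically by \code{ladderDecay} per GU, mimicking the weak
#'   high-GU rungs of real ladders
#' @param ladderDecay per-GU intensity decay factor
#' @param ladderCharge,ladderAdduct ion species of the planted rungs
#' @param sigma chromatographic peak width (Gaussian sigma, minutes)
#' @param glycans data.frame with columns composition (string), charge,
#'   adduct, gui (target GUI; NA to use rt), rt (apex minutes; ignored when
#'   gui given), height, sigma — or NULL for none
#' @param decoyDensity expected decoy peaks per scan (0 = clean run)
#' @param decoyIntensity median decoy intensity; decoys are log-normal with
#'   sdlog \code{decoySdLog}, uniform in m/z over \code{mzRange}. The
#'   default (NULL) places the median at one tenth of the weakest planted
#'   rung, the regime of baseline noise sitting well below the true ladder
#' @param decoySdLog log-scale sd of decoy intensities
#' @param mzRange m/z extent of the simulated scans
#' @param rtRange,rtStep scan grid (minutes); default 0.05-min spacing
#' @param seed integer seed; the same spec and seed give a bit-identical run
#' @return a list of class \code{synthSpec}
#' @export
synthSpec <- function(guCurve = defaultGuCurve(), guRange = 2:12,
                      ladderHeight = 1e6, ladderDecay = 0.75,
                      ladderCharge = 1L, ladderAdduct = "proton",
                      sigma = 0.15, glycans = NULL,
                      decoyDensity = 0, decoyIntensity = NULL,
                      decoySdLog = 0.3, mzRange = c(400, 3200),
                      rtRange = c(8, 58), rtStep = 0.05, seed = 1L) {
  if (is.null(decoyIntensity))
    decoyIntensity <- 0.1 * ladderHeight *
      ladderDecay^(if (length(guRange)) diff(range(guRange)) else 0)
  spec <- list(guCurve = guCurve, guRange = as.integer(guRange),
               ladderHeight = ladderHeight, ladderDecay = ladderDecay,
               ladderCharge = as.integer(ladderCharge),
               ladderAdduct = ladderAdduct, sigma = sigma,
               glycans = glycans, decoyDensity = decoyDensity,
               decoyIntensity = decoyIntensity, decoySdLog = decoySdLog,
               mzRange = mzRange, rtRange = rtRange, rtStep = rtStep,
               seed = as.integer(seed))
  stopifnot(spec$rtStep > 0, all(spec$guRange >= 1L), spec$sigma > 0,
            spec$decoyDensity >= 0)
  class(spec) <- "synthSpec"
  spec
}

# envelope peaks (mz, relative-to-anchor intensity) of one planted species
.speciesEnvelope <- function(formula, charge, adduct, nPeaks = 10L) {
  env <- isotopeEnvelope(formula, nPeaks)
  len <- .envelopeLength(env, 0.999, 3L)
  anchor <- env@mostAbundant
  anchorMz <- ionMz(env@masses[anchor], charge, adduct)
  mz <- anchorMz + (seq_len(len) - anchor) * .NEUTRON / charge
  p <- env@probabilities[seq_len(len)]
  list(mz = mz, rel = p / p[anchor], anchorMz = anchorMz,
       top3Fraction = sum(sort(p, decreasing = TRUE)[seq_len(min(3L, len))]) /
         p[anchor])
}

#' Generate a synthetic run
#'
#' Builds the MS1 scans of the specified run on the rt grid. The returned
#' run's \code{metadata$groundTruth} manifest lists every planted species
#' with its apex rt (and grid-snapped apex), height, target GUI and the
#' analytic top-3-isotope area \code{h * top3Fraction * sigma * sqrt(2*pi)}
#' of each Gaussian isomer.
#'
#' @param spec a \code{\link{synthSpec}}
#' @return an \linkS4class{MSRun}
#' @export
generateRun <- function(spec = synthSpec()) {
  stopifnot(inherits(spec, "synthSpec"))
  set.seed(spec$seed)
  grid <- seq(spec$rtRange[1L], spec$rtRange[2L], by = spec$rtStep)
  nScan <- length(grid)
  peakMz <- vector("list", nScan)
  peakInt <- vector("list", nScan)

  truth <- list(ladder = NULL, glycans = NULL)
  plant <- function(mz, rel, apexRt, height, sigma) {
    lo <- max(1L, findInterval(apexRt - 4 * sigma, grid))
    hi <- min(nScan, findInterval(apexRt + 4 * sigma, grid) + 1L)
    for (k in lo:hi) {
      scale <- height * exp(-(grid[k] - apexRt)^2 / (2 * sigma^2))
      if (scale < height * 1e-6) next
      peakMz[[k]] <<- c(peakMz[[k]], mz)
      peakInt[[k]] <<- c(peakInt[[k]], rel * scale)
    }
  }

  # dextrin ladder on the GU curve
  ladderRows <- list()
  for (gu in spec$guRange) {
    sp <- .speciesEnvelope(dextrinFormula(gu), spec$ladderCharge,
                           spec$ladderAdduct)
    apexRt <- spec$guCurve$rtAt(gu)
    if (apexRt < spec$rtRange[1L] || apexRt > spec$rtRange[2L])
      stop("ladder rung GU ", gu, " elutes outside the rt range")
    snapped <- grid[which.min(abs(grid - apexRt))]
    h <- spec$ladderHeight * spec$ladderDecay^(gu - min(spec$guRange))
    plant(sp$mz, sp$rel, snapped, h, spec$sigma)
    ladderRows[[length(ladderRows) + 1L]] <- data.frame(
      gu = gu, rt = snapped, height = h, anchorMz = sp$anchorMz,
      charge = spec$ladderCharge, stringsAsFactors = FALSE)
  }
  truth$ladder <- do.call(rbind, c(ladderRows, list(NULL)))

  # glycans (optionally placed at a target GUI through the curve)
  if (!is.null(spec$glycans) && nrow(spec$glycans) > 0L) {
    gl <- spec$glycans
    if (is.null(gl$sigma)) gl$sigma <- spec$sigma
    glyRows <- list()
    for (i in seq_len(nrow(gl))) {
      comp <- parseComposition(gl$composition[i])
      apexRt <- if (!is.null(gl$gui) && !is.na(gl$gui[i]))
        spec$guCurve$rtAt(gl$gui[i]) else gl$rt[i]
      if (apexRt < spec$rtRange[1L] || apexRt > spec$rtRange[2L])
        stop("glycan ", gl$composition[i], " elutes outside the rt range")
      snapped <- grid[which.min(abs(grid - apexRt))]
      sp <- .speciesEnvelope(glycanFormula(comp), gl$charge[i], gl$adduct[i])
      plant(sp$mz, sp$rel, snapped, gl$height[i], gl$sigma[i])
      glyRows[[length(glyRows) + 1L]] <- data.frame(
        composition = gl$composition[i], charge = gl$charge[i],
        adduct = gl$adduct[i], rt = snapped,
        gui = spec$guCurve$guiAt(snapped), height = gl$height[i],
        sigma = gl$sigma[i], anchorMz = sp$anchorMz,
        analyticArea = gl$height[i] * sp$top3Fraction * gl$sigma[i] *
          sqrt(2 * pi),
        stringsAsFactors = FALSE)
    }
    truth$glycans <- do.call(rbind, glyRows)
  }

  # decoy peaks: uniform m/z, log-normal intensity
  if (spec$decoyDensity > 0) {
    for (k in seq_len(nScan)) {
      nd <- stats::rpois(1L, spec$decoyDensity)
      if (nd == 0L) next
      peakMz[[k]] <- c(peakMz[[k]],
                       stats::runif(nd, spec$mzRange[1L], spec$mzRange[2L]))
      peakInt[[k]] <- c(peakInt[[k]],
                        stats::rlnorm(nd, log(spec$decoyIntensity),
                                      spec$decoySdLog))
    }
  }

  specs <- lapply(seq_len(nScan), function(k) {
    mzv <- peakMz[[k]]
    iv <- peakInt[[k]]
    if (is.null(mzv)) { mzv <- numeric(0); iv <- numeric(0) }
    # merge coincident m/z (same species at same grid m/z cannot occur, but
    # decoys may collide with planted peaks within float identity)
    o <- base::order(mzv)
    mzv <- mzv[o]; iv <- iv[o]
    if (anyDuplicated(mzv)) {
      iv <- vapply(split(iv, mzv), sum, numeric(1))
      mzv <- sort(unique(mzv))
    }
    spectrum(mzv, iv, rt = grid[k], scanId = sprintf("scan=%d", k),
             msLevel = 1L, centroided = TRUE)
  })
  msRun(specs, metadata = list(groundTruth = truth, spec = spec))
}

#' Ground-truth manifest of a synthetic run
#'
#' @param run a run produced by \code{\link{generateRun}}
#' @return list with elements \code{ladder} and \code{glycans}
#' @export
groundTruth <- function(run) {
  gt <- run@metadata$groundTruth
  if (is.null(gt)) stop("run carries no ground-truth manifest")
  gt
}

#' Write the ground-truth manifest as JSON
#'
#' @param run a run produced by \code{\link{generateRun}}
#' @param path output path
#' @export
writeGroundTruth <- function(run, path) {
  jsonlite::write_json(groundTruth(run), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
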