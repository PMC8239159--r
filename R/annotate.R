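# Glycan annotation by isotope-envelope matching.
#
# For each candidate (composition, charge, adduct) the m/z of the most
# abundant aggregated isotope peak is searched against the spectrum within
# tolerance; when that anchor is found, the match is extended to the
# neighbouring aggregated peaks at spacing 1.00335/z and the aligned
# theoretical/observed intensity vectors are scored by Pearson correlation,
# which is invariant to linear transformation of the observed intensities
# (detector gain and offset drop out).

# theoretical m/z positions of the scoring envelope and its anchor index
.envelopeGrid <- function(envelope, charge, adduct, coverage = 0.999,
                          minPeaks = 3L) {
  len <- .envelopeLength(envelope, coverage, minPeaks)
  anchor <- envelope@mostAbundant
  anchorMz <- ionMz(envelope@masses[anchor], charge, adduct)
  mz <- anchorMz + (seq_len(len) - anchor) * .NEUTRON / charge
  list(mz = mz, t = envelope@probabilities[seq_len(len)],
       anchor = anchor, anchorMz = anchorMz)
}

# nearest in-tolerance observed intensity per theoretical position (0 absent)
.pairObserved <- function(peakMz, peakInt, targets, tol) {
  vapply(targets, function(m) {
    if (length(peakMz) == 0L) return(0)
    d <- abs(peakMz - m)
    i <- which.min(d)
    if (d[i] <= tol) peakInt[i] else 0
  }, numeric(1))
}

#' Match a theoretical isotope envelope in one spectrum
#'
#' Returns \code{NULL} unless a peak lies within tolerance of the most
#' abundant isotopic ion (the anchor); otherwise each theoretical aggregated
#' peak is paired with the nearest in-tolerance observed peak (observed 0
#' where absent).
#'
#' @param spec a centroided \linkS4class{Spectrum}
#' @param comp a \linkS4class{GlycanComposition} or
#'   \linkS4class{ElementalFormula}
#' @param charge,adduct ion species searched
#' @param tolerancePpm mass tolerance in ppm
#' @param derivatization passed to \code{\link{glycanFormula}}
#' @param nPeaks aggregated envelope peaks computed
#' @return an \linkS4class{EnvelopeMatch}, or \code{NULL}
#' @export
matchEnvelope <- function(spec, comp, charge = 1L, adduct = "proton",
                          tolerancePpm = 10, derivatization = "permethylated",
                          nPeaks = 10L) {
  stopifnot(is(spec, "Spectrum"))
  formula <- if (is(comp, "GlycanComposition"))
    glycanFormula(comp, derivatization) else comp
  env <- isotopeEnvelope(formula, nPeaks)
  grid <- .envelopeGrid(env, charge, adduct)
  mzs <- spec@peaks[, 1L]
  ints <- spec@peaks[, 2L]
  tol <- .ppmTol(grid$anchorMz, tolerancePpm)
  if (length(mzs) == 0L || min(abs(mzs - grid$anchorMz)) > tol) return(NULL)
  obs <- .pairObserved(mzs, ints, grid$mz, tol)
  new("EnvelopeMatch", theoretical = grid$t, observed = obs,
      mz = grid$mz, anchorIndex = grid$anchor)
}

#' Pearson score of a matched envelope
#'
#' Standard Pearson correlation between the theoretical and observed
#' intensity vectors. Undefined (returns \code{NA}) when either vector has
#' zero variance or fewer than 2 positions; such matches are rejected
#' upstream. Negative correlations are never clipped.
#'
#' @param match an \linkS4class{EnvelopeMatch}
#' @return correlation in [-1, 1], or \code{NA}
#' @export
scoreMatch <- function(match) {
  stopifnot(is(match, "EnvelopeMatch"))
  t <- match@theoretical
  o <- match@observed
  if (length(t) < 2L || stats::sd(t) == 0 || stats::sd(o) == 0)
    return(NA_real_)
  stats::cor(t, o)
}

setMethod("show", "EnvelopeMatch", function(object) {
  cat("EnvelopeMatch:", length(object@mz), "aggregated peaks, anchor index",
      object@anchorIndex, "\n")
  print(data.frame(mz = round(object@mz, 4),
                   theoretical = signif(object@theoretical, 4),
                   observed = object@observed), row.names = FALSE)
})

#' Annotate a run with glycan compositions
#'
#' Searches every enumerated composition at every putative charge and adduct
#' across all MS1 spectra, keeps envelope matches whose Pearson score meets
#' the cutoff, and attaches the calibrated GUI of the scan's retention time.
#' Matches at different charges/adducts of one composition are reported
#' separately; merging is the quantification stage's job.
#'
#' @param run an \linkS4class{MSRun}
#' @param index a \linkS4class{BucketIndex} built over \code{run}
#' @param model a fitted \linkS4class{CalibrationModel}
#' @param config a \code{\link{guConfig}}
#' @param compositions optional pre-enumerated list of
#'   \linkS4class{GlycanComposition} (defaults to
#'   \code{enumerateGlycans} under the config bounds)
#' @return data.frame with columns composition, charge, adduct, scan,
#'   scanId, rt, gui, score, mz, intensity — ordered by (composition, rt,
#'   charge)
#' @export
annotateRun <- function(run, index, model, config = guConfig(),
                        compositions = NULL) {
  stopifnot(is(run, "MSRun"), is(index, "BucketIndex"),
            is(model, "CalibrationModel"))
  if (is.null(compositions))
    compositions <- enumerateGlycans(config$maxHexNAc, config$maxHex,
                                     config$maxFuc, config$maxNeuAc)
  rows <- list()
  for (comp in compositions) {
    cs <- compositionString(comp)
    env <- isotopeEnvelope(glycanFormula(comp, config$derivatization),
                           config$nIsotopePeaks)
    for (adduct in config$adducts) {
      for (z in seq_len(config$maxCharge)) {
        grid <- .envelopeGrid(env, z, adduct)
        tol <- .ppmTol(grid$anchorMz, config$tolerancePpm)
        hits <- queryPeakIndex(index, grid$anchorMz, tol)
        if (nrow(hits) == 0L) next
        for (scan in unique(hits$scan)) {
          s <- run@spectra[[scan]]
          obs <- .pairObserved(s@peaks[, 1L], s@peaks[, 2L], grid$mz, tol)
          m <- new("EnvelopeMatch", theoretical = grid$t, observed = obs,
                   mz = grid$mz, anchorIndex = grid$anchor)
          r <- scoreMatch(m)
          if (is.na(r) || r < config$scoreCutoff) next
          rows[[length(rows) + 1L]] <- data.frame(
            composition = cs, charge = z, adduct = adduct, scan = scan,
            scanId = s@scanId, rt = s@rt,
            gui = as.numeric(rtToGUI(model, s@rt)), score = r,
            mz = grid$anchorMz,
            intensity = obs[grid$anchor], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(composition = character(0), charge = integer(0),
                      adduct = character(0), scan = integer(0),
                      scanId = character(0), rt = numeric(0),
                      gui = numeric(0), score = numeric(0), mz = numeric(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[base::order(out$composition, out$rt, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}
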