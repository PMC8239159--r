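#' @import methods
NULL

#' Elemental formula
#'
#' A named vector of non-negative integer element counts (C, H, N, O, and
#' optionally S, Na). Formulas support \code{+}, \code{-} and integer
#' \code{*} element-wise, and carry a monoisotopic mass via
#' \code{\link{monoMass}}.
#'
#' @slot .Data named integer vector of element counts
#' @seealso \code{\link{elementalFormula}}
#' @export
setClass("ElementalFormula", contains = "integer", validity = function(object) {
  if (length(object) == 0L) return(TRUE)
  if (is.null(names(object)) || any(!nzchar(names(object))))
    return("all element counts must be named")
  if (!all(names(object) %in% names(.MONOISOTOPIC)))
    return(paste("unknown element(s):",
                 paste(setdiff(names(object), names(.MONOISOTOPIC)), collapse = ", ")))
  if (anyDuplicated(names(object))) return("duplicate element names")
  if (any(object < 0L)) return("element counts must be non-negative")
  TRUE
})

#' Glycan monosaccharide composition
#'
#' Counts of the four monosaccharide classes of an N-glycan composition:
#' HexNAc (N-acetylhexosamine), Hex (hexose), Fuc (deoxyhexose) and NeuAc
#' (N-acetylneuraminic acid). Structural (linkage) information is
#' deliberately not represented; compositional isomers share one object.
#'
#' @slot hexnac,hex,fuc,neuac non-negative integer counts
#' @seealso \code{\link{glycanComposition}}, \code{\link{enumerateGlycans}}
#' @export
setClass("GlycanComposition",
  representation(hexnac = "integer", hex = "integer",
                 fuc = "integer", neuac = "integer"),
  validity = function(object) {
    v <- c(object@hexnac, object@hex, object@fuc, object@neuac)
    if (length(v) != 4L || anyNA(v)) return("all four counts must be scalar integers")
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
  })

#' Aggregated isotope envelope
#'
#' The aggregated isotopic distribution of a molecule: probabilities per
#' nucleon-number offset from the monoisotopic peak, together with
#' probability-weighted centroid masses per aggregated peak.
#'
#' @slot probabilities numeric vector of aggregated probabilities, offset
#'   0 (monoisotopic) upward
#' @slot masses centroid mass (Da) of each aggregated peak
#' @slot mostAbundant integer, 1-based index of the most probable peak
#' @slot formula the \linkS4class{ElementalFormula} the envelope derives from
#' @seealso \code{\link{isotopeEnvelope}}
#' @export
setClass("IsotopeEnvelope",
  representation(probabilities = "numeric", masses = "numeric",
                 mostAbundant = "integer", formula = "ElementalFormula"),
  validity = function(object) {
    if (length(object@probabilities) != length(object@masses))
      return("probabilities and masses must have equal length")
    if (any(object@probabilities < -1e-12)) return("probabilities must be non-negative")
    if (sum(object@probabilities) > 1 + 1e-9) return("probabilities must sum to at most 1")
    if (object@mostAbundant != which.max(object@probabilities))
      return("mostAbundant must index the maximal probability")
    TRUE
  })

#' A single mass spectrum
#'
#' One scan: retention time, MS level and a peak list sorted ascending in
#' m/z. After centroiding the ordering is strictly ascending.
#'
#' @slot scanId character scan identifier
#' @slot rt retention time in minutes
#' @slot msLevel integer MS level (only level 1 is used downstream)
#' @slot peaks two-column numeric matrix (\code{mz}, \code{intensity})
#' @slot centroided logical, whether the peak list is centroided
#' @export
setClass("Spectrum",
  representation(scanId = "character", rt = "numeric", msLevel = "integer",
                 peaks = "matrix", centroided = "logical"),
  validity = function(object) {
    p <- object@peaks
    if (ncol(p) != 2L) return("peaks must have two columns (mz, intensity)")
    if (nrow(p) > 0L) {
      if (any(p[, 1L] <= 0)) return("m/z values must be positive")
      if (any(p[, 2L] < 0)) return("intensities must be non-negative")
      if (is.unsorted(p[, 1L])) return("peaks must be sorted ascending by m/z")
      if (isTRUE(object@centroided) && anyDuplicated(p[, 1L]))
        return("centroided peaks must be strictly ascending in m/z")
    }
    if (length(object@rt) != 1L || object@rt < 0) return("rt must be a single non-negative number")
    TRUE
  })

#' An LC-MS run
#'
#' A list of \linkS4class{Spectrum} objects sorted ascending by retention
#' time, plus free-form metadata (the synthetic generator stores its
#' ground-truth manifest there).
#'
#' @slot spectra list of \linkS4class{Spectrum}
#' @slot metadata named list
#' @export
setClass("MSRun",
  representation(spectra = "list", metadata = "list"),
  validity = function(object) {
    if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
      return("all elements of spectra must be Spectrum objects")
    rts <- vapply(object@spectra, function(s) s@rt, numeric(1))
    if (is.unsorted(rts)) return("spectra must be sorted by retention time")
    TRUE
  })

#' Bucket index over the peaks of a run
#'
#' Hash-bucket index of all MS1 peaks of a run keyed by
#' \code{floor(mz / bucketWidth)}, so that a tolerance query touches only
#' the few buckets overlapping \code{[m - tol, m + tol]} instead of scanning
#' every peak.
#'
#' @slot bucketWidth bucket width in Th
#' @slot peaks data.frame with columns \code{mz}, \code{intensity},
#'   \code{scan} (index into the run), \code{rt}, \code{scanId}
#' @slot buckets named list mapping bucket key to integer row indices
#' @seealso \code{\link{buildPeakIndex}}, \code{\link{queryPeakIndex}}
#' @export
setClass("BucketIndex",
  representation(bucketWidth = "numeric", peaks = "data.frame",
                 buckets = "list"),
  validity = function(object) {
    if (length(object@bucketWidth) != 1L || object@bucketWidth <= 0)
      return("bucketWidth must be a single positive number")
    TRUE
  })

#' Dextrin-ladder assignment
#'
#' The resolved glucose-unit elution sequence: per GU the chosen retention
#' time and supporting intensity, plus the raw candidate observations.
#'
#' @slot assignment data.frame with columns \code{gu}, \code{rt},
#'   \code{intensity}, \code{scanId}, \code{charge}
#' @slot observations the candidate observations the DP ran on
#' @seealso \code{\link{assignLadder}}
#' @export
setClass("LadderAssignment",
  representation(assignment = "data.frame", observations = "data.frame"),
  validity = function(object) {
    a <- object@assignment
    need <- c("gu", "rt", "intensity")
    if (!all(need %in% names(a))) return("assignment lacks gu/rt/intensity columns")
    if (nrow(a) > 1L) {
      o <- order(a$gu)
      if (any(diff(a$rt[o]) <= 0))
        return("assigned retention times must strictly increase with GU")
    }
    TRUE
  })

#' Retention-time to GUI calibration model
#'
#' A least-squares fit of glucose-unit index as a polynomial (or
#' single-term logarithmic) function of retention time. Coefficients are
#' reported on the raw rt scale; internally the design is centred and
#' scaled for conditioning.
#'
#' @slot kind "polynomial" or "logarithmic"
#' @slot order polynomial degree (1 for logarithmic)
#' @slot coefficients numeric, beta0..betaN on the raw (or log-rt) scale
#' @slot rSquared coefficient of determination on the fit points
#' @slot fitPoints data.frame(rt, gu) used for the fit
#' @slot rtRange range of fitted rts (evaluation outside is extrapolation)
#' @seealso \code{\link{fitCalibration}}, \code{\link{rtToGUI}}
#' @export
setClass("CalibrationModel",
  representation(kind = "character", order = "integer",
                 coefficients = "numeric", rSquared = "numeric",
                 fitPoints = "data.frame", rtRange = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("polynomial", "logarithmic"))
      return("kind must be 'polynomial' or 'logarithmic'")
    if (object@order < 1L) return("order must be >= 1")
    if (nrow(object@fitPoints) < object@order + 1L)
      return("need at least order + 1 fit points")
    TRUE
  })

#' Matched isotope envelope
#'
#' Aligned theoretical and observed intensity vectors for one candidate
#' annotation; unmatched theoretical positions carry observed 0.
#'
#' @slot theoretical,observed aligned numeric intensity vectors
#' @slot mz theoretical m/z per aggregated peak
#' @slot anchorIndex 1-based index of the most abundant (anchor) peak
#' @seealso \code{\link{matchEnvelope}}, \code{\link{scoreMatch}}
#' @export
setClass("EnvelopeMatch",
  representation(theoretical = "numeric", observed = "numeric",
                 mz = "numeric", anchorIndex = "integer"),
  validity = function(object) {
    if (length(object@theoretical) != length(object@observed))
      return("theoretical and observed must have equal length")
    TRUE
  })

#' Extracted-ion chromatogram
#'
#' Per-MS1-scan combined intensity of the three most probable theoretical
#' isotope peaks of one (composition, charge, adduct) ion; scans with no
#' matched peak contribute 0, keeping the trace dense.
#'
#' @slot composition composition string
#' @slot charge,adduct ion species
#' @slot rt ascending retention times (minutes), one per MS1 scan
#' @slot intensity combined top-3-isotope intensity per scan
#' @slot isotopeMz the three theoretical m/z values traced
#' @seealso \code{\link{buildXIC}}, \code{\link{detectPeaks}}
#' @export
setClass("XICTrace",
  representation(composition = "character", charge = "integer",
                 adduct = "character", rt = "numeric", intensity = "numeric",
                 isotopeMz = "numeric"),
  validity = function(object) {
    if (length(object@rt) != length(object@intensity))
      return("rt and intensity must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
      return("rt must be strictly ascending")
    if (any(object@intensity < 0)) return("intensities must be non-negative")
    TRUE
  })
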