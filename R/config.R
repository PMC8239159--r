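#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the field-standard defaults
#' for permethylated serum N-glycomes: 10 ppm mass tolerance, charges up to
#' +3, proton adduct, dextrin ladder GU 2-12, cubic polynomial calibration,
#' isotope-envelope Pearson cutoff 0.9, XIC boundary cutoff 50% of apex, and
#' composition bounds HexNAc <= 12, Hex <= 12, Fuc <= 5, NeuAc <= 4.
#'
#' @param tolerancePpm mass tolerance in ppm for all peak matching
#' @param maxCharge maximum putative ion charge
#' @param adducts character vector among "proton", "sodium"
#' @param guRange integer glucose-unit range of the spiked ladder
#' @param fitKind "polynomial" or "logarithmic" calibration
#' @param fitOrder polynomial degree of the calibration curve
#' @param scoreCutoff minimum Pearson correlation of a matched envelope
#' @param boundaryCutoff XIC peak-boundary fraction of apex intensity
#' @param maxHexNAc,maxHex,maxFuc,maxNeuAc composition enumeration bounds
#' @param derivatization "permethylated" or "native"
#' @param nIsotopePeaks aggregated envelope peaks computed per species
#' @param ladderIntensityFloor absolute intensity floor for ladder
#'   candidates (0 = off)
#' @param minApex minimum apex intensity for XIC peak detection (0 = off)
#' @param areaMethod "trapezoid" (intensity x minutes) or "sum" (raw
#'   intensity summation)
#' @param isomerRtWindow apex window (minutes) for merging isomers across
#'   charge states and adducts
#' @return a validated list of class \code{guConfig}
#' @export
guConfig <- function(tolerancePpm = 10, maxCharge = 3L,
                     adducts = "proton", guRange = 2:12,
                     fitKind = "polynomial", fitOrder = 3L,
                     scoreCutoff = 0.9, boundaryCutoff = 0.5,
                     maxHexNAc = 12L, maxHex = 12L, maxFuc = 5L,
                     maxNeuAc = 4L,
                     derivatization = "permethylated",
                     nIsotopePeaks = 10L, ladderIntensityFloor = 0,
                     minApex = 0, areaMethod = "trapezoid",
                     isomerRtWindow = 0.2) {
  cfg <- list(tolerancePpm = tolerancePpm, maxCharge = as.integer(maxCharge),
              adducts = adducts, guRange = as.integer(guRange),
              fitKind = match.arg(fitKind, c("polynomial", "logarithmic")),
              fitOrder = as.integer(fitOrder), scoreCutoff = scoreCutoff,
              boundaryCutoff = boundaryCutoff,
              maxHexNAc = as.integer(maxHexNAc), maxHex = as.integer(maxHex),
              maxFuc = as.integer(maxFuc), maxNeuAc = as.integer(maxNeuAc),
              derivatization = match.arg(derivatization,
                                         c("permethylated", "native")),
              nIsotopePeaks = as.integer(nIsotopePeaks),
              ladderIntensityFloor = ladderIntensityFloor,
              minApex = minApex,
              areaMethod = match.arg(areaMethod, c("trapezoid", "sum")),
              isomerRtWindow = isomerRtWindow)
  stopifnot(cfg$tolerancePpm > 0, cfg$maxCharge >= 1L,
            all(cfg$adducts %in% c("proton", "sodium")),
            length(cfg$guRange) >= 1L, all(cfg$guRange >= 1L),
            cfg$fitOrder >= 1L, cfg$scoreCutoff <= 1,
            cfg$boundaryCutoff > 0, cfg$boundaryCutoff < 1,
            cfg$nIsotopePeaks >= 3L, cfg$isomerRtWindow > 0)
  class(cfg) <- "guConfig"
  cfg
}

#' Read a configuration file
#'
#' A flat JSON object whose names are \code{\link{guConfig}} arguments;
#' unspecified fields keep their defaults.
#'
#' @param path JSON file path
#' @return a \code{guConfig}
#' @export
readConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(guConfig)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(guConfig, vals)
}

#' @export
print.guConfig <- function(x, ...) {
  cat("guConfig:\n")
  for (n in names(x)) cat(" ", n, "=", paste(format(x[[n]]), collapse = " "), "\n")
  invisible(x)
}
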