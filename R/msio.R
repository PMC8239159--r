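# mzML input/output and spectrum preprocessing. File parsing is delegated to
# Bioconductor's mzR (proteowizard backend); everything downstream works on
# the lightweight Spectrum/MSRun containers.

#' Construct a Spectrum
#'
#' @param mz,intensity numeric vectors of equal length
#' @param rt retention time in minutes
#' @param scanId scan identifier
#' @param msLevel MS level
#' @param centroided whether the peak list is already centroided
#' @return a \linkS4class{Spectrum}
#' @export
spectrum <- function(mz, intensity, rt, scanId = "scan", msLevel = 1L,
                     centroided = TRUE) {
  o <- order(mz)
  new("Spectrum", scanId = as.character(scanId), rt = as.numeric(rt),
      msLevel = as.integer(msLevel),
      peaks = cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o]),
      centroided = isTRUE(centroided))
}

#' Construct an MSRun
#'
#' @param spectra list of \linkS4class{Spectrum}; re-sorted by retention time
#' @param metadata named list
#' @return an \linkS4class{MSRun}
#' @export
msRun <- function(spectra, metadata = list()) {
  rts <- vapply(spectra, function(s) s@rt, numeric(1))
  new("MSRun", spectra = spectra[order(rts)], metadata = metadata)
}

#' @describeIn msRun the spectra as a list
#' @param run an \linkS4class{MSRun}
#' @export
spectra <- function(run) run@spectra

#' @describeIn msRun retention times (minutes) of all spectra
#' @export
scanTimes <- function(run) vapply(run@spectra, function(s) s@rt, numeric(1))

#' @describeIn msRun indices of the MS1 spectra
#' @export
ms1Indices <- function(run)
  which(vapply(run@spectra, function(s) s@msLevel, integer(1)) == 1L)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@scanId, sprintf("(MS%d, rt %.3f min):", object@msLevel,
      object@rt), nrow(object@peaks), "peaks",
      if (object@centroided) "(centroided)" else "(profile)", "\n")
})

setMethod("show", "MSRun", function(object) {
  n <- length(object@spectra)
  cat("MSRun:", n, "spectra")
  if (n) cat(sprintf(", rt %.2f-%.2f min", object@spectra[[1L]]@rt,
                     object@spectra[[n]]@rt))
  cat(",", length(ms1Indices(object)), "MS1\n")
})

#' Read an mzML run
#'
#' Reads a PSI-standard mzML file via \pkg{mzR}, normalizing retention times
#' to minutes. Spectra are returned sorted by retention time; MS2 scans are
#' retained in the container but excluded from annotation downstream.
#' Spectra not flagged centroided in the file are marked profile and should
#' be passed through \code{\link{centroidSpectrum}}.
#'
#' @param path path to an mzML file
#' @return an \linkS4class{MSRun}
#' @export
readMzML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("cannot read mzML file '", path,
                                              "': ", conditionMessage(e)))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L)
    return(msRun(list(), metadata = list(source = path)))
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  specs <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pk[[i]]
    cent <- hdr$centroided[i]
    spectrum(mz = p[, 1L], intensity = p[, 2L],
             rt = hdr$retentionTime[i] / 60,   # mzR reports seconds
             scanId = if (!is.null(hdr$spectrumId)) hdr$spectrumId[i]
                      else paste0("scan=", hdr$acquisitionNum[i]),
             msLevel = hdr$msLevel[i],
             centroided = !is.na(cent) && isTRUE(cent))
  })
  msRun(specs, metadata = list(source = path))
}

#' Write a run as mzML
#'
#' Writes a PSI-standard mzML file via \pkg{mzR}; \code{\link{readMzML}}
#' round-trips retention time, m/z and intensity at float precision.
#'
#' @param run an \linkS4class{MSRun}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMzML <- function(run, path) {
  stopifnot(is(run, "MSRun"))
  n <- length(run@spectra)
  pk <- lapply(run@spectra, function(s) {
    p <- s@peaks
    colnames(p) <- c("mz", "intensity")
    p
  })
  pad1 <- function(x, fill) if (n) x else fill   # keep data.frame() happy at n = 0
  hdr <- data.frame(
    seqNum = pad1(seq_len(n), 1L), acquisitionNum = pad1(seq_len(n), 1L),
    msLevel = pad1(vapply(run@spectra, function(s) s@msLevel, integer(1)), 1L),
    polarity = 1L,
    peaksCount = pad1(vapply(run@spectra, function(s) nrow(s@peaks), integer(1)), 0L),
    totIonCurrent = pad1(vapply(run@spectra, function(s) sum(s@peaks[, 2L]), numeric(1)), 0),
    retentionTime = pad1(vapply(run@spectra, function(s) s@rt * 60, numeric(1)), 0),
    basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 0, highMZ = 0,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = pad1(vapply(run@spectra, function(s) s@scanId, character(1)), "scan=1"),
    centroided = pad1(vapply(run@spectra, function(s) s@centroided, logical(1)), TRUE),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  hdr <- hdr[seq_len(n), , drop = FALSE]
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Centroid a profile spectrum
#'
#' Reduces profile data to local maxima: the spectrum is split into
#' contiguous above-zero regions, each region is subdivided at internal
#' minima between its local maxima, and every sub-region is collapsed to an
#' intensity-weighted m/z centroid carrying the apex intensity. Spectra
#' already flagged centroided are returned unchanged, making the operation
#' idempotent.
#'
#' @param spec a \linkS4class{Spectrum}
#' @return a centroided \linkS4class{Spectrum}
#' @export
centroidSpectrum <- function(spec) {
  stopifnot(is(spec, "Spectrum"))
  if (spec@centroided) return(spec)
  p <- spec@peaks
  keep <- p[, 2L] > 0
  if (!any(keep))
    return(spectrum(numeric(0), numeric(0), spec@rt, spec@scanId,
                    spec@msLevel, centroided = TRUE))
  # contiguous above-zero regions
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  outMz <- numeric(0); outInt <- numeric(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    y <- p[idx, 2L]
    n <- length(y)
    if (n <= 2L) {
      sub <- list(seq_len(n))
    } else {
      # split at internal minima between local maxima
      isMin <- c(FALSE, y[2:(n - 1L)] < y[1:(n - 2L)] & y[2:(n - 1L)] <= y[3:n], FALSE)
      cuts <- which(isMin)
      bounds <- c(1L, cuts, n)
      sub <- lapply(seq_len(length(cuts) + 1L), function(i)
        bounds[i]:bounds[i + 1L])
    }
    for (s in sub) {
      ii <- idx[s]
      w <- p[ii, 2L]
      outMz <- c(outMz, sum(p[ii, 1L] * w) / sum(w))
      outInt <- c(outInt, max(w))
    }
  }
  o <- order(outMz)
  dup <- duplicated(outMz[o])
  spectrum(outMz[o][!dup], outInt[o][!dup], spec@rt, spec@scanId,
           spec@msLevel, centroided = TRUE)
}

#' Derive the charge of a peak from isotope spacing
#'
#' Looks for a companion peak at \code{mz + 1.00335/z}; among charges with a
#' companion within tolerance the largest is returned (a z = 2 envelope also
#' matches the z = 1 spacing test at twice the gap, so the denser spacing is
#' the more specific explanation). \code{NA} when no companion is found.
#'
#' @param spec a centroided \linkS4class{Spectrum}
#' @param mz the m/z of the peak whose charge is sought
#' @param maxCharge maximum charge considered (1..10)
#' @param tol absolute tolerance in Th for the companion search
#' @return integer charge, or \code{NA} if undetermined
#' @export
deriveCharge <- function(spec, mz, maxCharge = 3L, tol = 0.01) {
  stopifnot(is(spec, "Spectrum"))
  if (maxCharge < 1L || maxCharge > 10L) stop("maxCharge must be in 1..10")
  mzs <- spec@peaks[, 1L]
  for (z in seq(maxCharge, 1L)) {
    target <- mz + .NEUTRON / z
    if (length(mzs) && min(abs(mzs - target)) <= tol) return(as.integer(z))
  }
  NA_integer_
}

#' Build a bucket index over the MS1 peaks of a run
#'
#' Peaks are hashed into m/z buckets of fixed width so a tolerance query
#' inspects only the buckets overlapping the query window (at most 3 when
#' the width is at least the tolerance) rather than every peak.
#'
#' @param run an \linkS4class{MSRun}
#' @param bucketWidth bucket width in Th; the natural choice is the search
#'   tolerance in Th at the top of the m/z range
#' @return a \linkS4class{BucketIndex}
#' @export
buildPeakIndex <- function(run, bucketWidth = 0.05) {
  stopifnot(is(run, "MSRun"))
  if (bucketWidth <= 0) stop("bucketWidth must be positive")
  idx <- ms1Indices(run)
  tabs <- lapply(idx, function(i) {
    s <- run@spectra[[i]]
    if (nrow(s@peaks) == 0L) return(NULL)
    data.frame(mz = s@peaks[, 1L], intensity = s@peaks[, 2L],
               scan = i, rt = s@rt, scanId = s@scanId,
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, c(tabs, list(NULL)))
  if (is.null(peaks))
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                        scan = integer(0), rt = numeric(0),
                        scanId = character(0), stringsAsFactors = FALSE)
  keys <- as.character(floor(peaks$mz / bucketWidth))
  buckets <- split(seq_len(nrow(peaks)), keys)
  new("BucketIndex", bucketWidth = bucketWidth, peaks = peaks,
      buckets = buckets)
}

#' Query a bucket index
#'
#' Returns exactly the indexed peaks with \code{|mz - m| <= tol}, identical
#' to a linear scan over all peaks.
#'
#' @param index a \linkS4class{BucketIndex}
#' @param m query m/z (Th)
#' @param tol absolute tolerance (Th), >= 0
#' @return data.frame with columns mz, intensity, scan, rt, scanId
#' @export
queryPeakIndex <- function(index, m, tol) {
  stopifnot(is(index, "BucketIndex"), tol >= 0)
  w <- index@bucketWidth
  keys <- as.character(seq(floor((m - tol) / w), floor((m + tol) / w)))
  rows <- unlist(index@buckets[keys], use.names = FALSE)
  if (is.null(rows) || length(rows) == 0L)
    return(index@peaks[0, , drop = FALSE])
  hit <- rows[abs(index@peaks$mz[rows] - m) <= tol]
  index@peaks[hit[order(index@peaks$mz[hit])], , drop = FALSE]
}

setMethod("show", "BucketIndex", function(object) {
  cat("BucketIndex:", nrow(object@peaks), "peaks in",
      length(object@buckets), "buckets of width", object@bucketWidth, "Th\n")
})

# ppm tolerance -> absolute Th at a given m/z
.ppmTol <- function(mz, ppm) mz * ppm * 1e-6
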