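# Dextrin-ladder detection and glucose-unit sequence resolution.
#
# The spiked permethylated dextrin ladder elutes in strict glucose-unit (GU)
# order, but at any one retention time several putative rungs can match
# within tolerance (noise, overlapping envelopes). A dynamic program over
# (scan, GU) resolves the most likely elution sequence under the
# order constraint, accumulating matched-peak intensity.

#' Extract dextrin-ladder candidate observations
#'
#' For every GU in the configured range, the m/z of its most abundant
#' isotopic ion is computed for each putative charge and adduct and searched
#' against all MS1 peaks of the run within the ppm tolerance. Per spectrum
#' and GU at most one observation is kept: the matched peak of maximum
#' intensity across charges and adducts.
#'
#' @param run an \linkS4class{MSRun}
#' @param index a \linkS4class{BucketIndex} built over \code{run}
#' @param config a \code{\link{guConfig}} (gu range, tolerance, charges,
#'   adducts)
#' @return data.frame with columns gu, scan, scanId, rt, mz, intensity,
#'   charge, adduct — the DP input
#' @export
extractLadderCandidates <- function(run, index, config = guConfig()) {
  stopifnot(is(run, "MSRun"), is(index, "BucketIndex"))
  out <- list()
  for (gu in config$guRange) {
    env <- isotopeEnvelope(dextrinFormula(gu), config$nIsotopePeaks)
    anchorMass <- env@masses[env@mostAbundant]
    best <- NULL
    for (adduct in config$adducts) {
      for (z in seq_len(config$maxCharge)) {
        m <- ionMz(anchorMass, z, adduct)
        hits <- queryPeakIndex(index, m, .ppmTol(m, config$tolerancePpm))
        if (nrow(hits) == 0L) next
        hits$charge <- z
        hits$adduct <- adduct
        best <- rbind(best, hits)
      }
    }
    if (is.null(best)) next
    # one observation per spectrum: the most intense matched peak
    keep <- unlist(lapply(split(seq_len(nrow(best)), best$scan),
                          function(i) i[which.max(best$intensity[i])]))
    best <- best[keep, , drop = FALSE]
    best$gu <- gu
    out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0L)
    return(data.frame(gu = integer(0), scan = integer(0),
                      scanId = character(0), rt = numeric(0), mz = numeric(0),
                      intensity = numeric(0), charge = integer(0),
                      adduct = character(0), stringsAsFactors = FALSE))
  obs <- do.call(rbind, out)
  obs <- obs[obs$intensity >= config$ladderIntensityFloor, , drop = FALSE]
  obs <- obs[order(obs$rt, obs$gu), c("gu", "scan", "scanId", "rt", "mz",
                                      "intensity", "charge", "adduct")]
  rownames(obs) <- NULL
  obs
}

# Core recursion over the intensity matrix I[scan, gu]:
#   score[i][u] = I[i, u] + max(score[i-1][u], max_{j <= u} score[i-1][j])
# with traceback preferring the same-GU predecessor on ties (contiguous
# elution blocks). Returns the per-scan GU path and the optimal total.
.ladderDP <- function(I) {
  nS <- nrow(I); nU <- ncol(I)
  score <- matrix(-Inf, nS, nU)
  pred <- matrix(NA_integer_, nS, nU)
  score[1L, ] <- I[1L, ]
  if (nS > 1L) {
    for (i in 2:nS) {
      best <- cummax(score[i - 1L, ])           # max over j <= u
      bestArg <- seq_len(nU)
      for (u in seq_len(nU))
        bestArg[u] <- if (score[i - 1L, u] >= best[u]) u else
          which(score[i - 1L, seq_len(u)] == best[u])[1L]
      score[i, ] <- I[i, ] + best
      pred[i, ] <- bestArg
    }
  }
  u <- which.max(score[nS, ])   # lowest GU on ties
  optimum <- score[nS, u]
  path <- integer(nS)
  path[nS] <- u
  if (nS > 1L) for (i in seq(nS, 2L)) {
    u <- pred[i, u]
    path[i - 1L] <- u
  }
  list(path = path, optimum = optimum, score = score)
}

# optimal order-respecting total intensity (used by oracle-equivalence tests)
.ladderOptimum <- function(I) .ladderDP(I)$optimum

#' Resolve the glucose-unit elution sequence by dynamic programming
#'
#' Scores every (scan, GU) state as
#' \code{score[i][u] = intensity(i,u) + max(score[i-1][u],
#' max_{j <= u} score[i-1][j])}, exploiting that higher glucose units always
#' elute later and that true rung peaks are typically more intense than
#' false matches. Traceback yields one assigned rung per scan,
#' non-decreasing over time; ties prefer staying on the current rung, giving
#' contiguous elution blocks. The reported retention time of each GU is the
#' scan of highest matched intensity among the scans assigned to it.
#'
#' @param observations candidate data.frame from
#'   \code{\link{extractLadderCandidates}}
#' @param guRange integer GU range in play (defaults to the observed range)
#' @return a \linkS4class{LadderAssignment}; GUs with no supporting
#'   observation are omitted with a warning
#' @export
assignLadder <- function(observations, guRange = NULL) {
  if (nrow(observations) == 0L) stop("no ladder observations to assign")
  if (is.null(guRange))
    guRange <- seq(min(observations$gu), max(observations$gu))
  gus <- sort(unique(as.integer(guRange)))
  scans <- sort(unique(observations$scan))
  nS <- length(scans); nU <- length(gus)

  # intensity(i, u); 0 where the GU is unobserved in that scan
  I <- matrix(0, nS, nU)
  si <- match(observations$scan, scans)
  ui <- match(observations$gu, gus)
  ok <- !is.na(ui)
  I[cbind(si[ok], ui[ok])] <- observations$intensity[ok]

  dp <- .ladderDP(I)
  path <- dp$path

  scanRt <- observations$rt[match(scans, observations$scan)]
  rows <- lapply(seq_len(nU), function(k) {
    supp <- which(path == k & I[, k] > 0)
    if (length(supp) == 0L) return(NULL)
    bestScan <- supp[which.max(I[supp, k])]
    o <- observations[observations$scan == scans[bestScan] &
                        observations$gu == gus[k], , drop = FALSE][1L, ]
    data.frame(gu = gus[k], rt = o$rt, intensity = o$intensity,
               scanId = o$scanId, charge = o$charge,
               stringsAsFactors = FALSE)
  })
  missing <- gus[vapply(rows, is.null, logical(1))]
  if (length(missing))
    warning("no supporting observation for GU ", paste(missing, collapse = ", "),
            "; omitted from the assignment")
  assignment <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(assignment)) stop("no glucose unit could be assigned")
  rownames(assignment) <- NULL
  new("LadderAssignment", assignment = assignment, observations = observations)
}

#' @describeIn assignLadder the per-GU assignment table
#' @param x a \linkS4class{LadderAssignment}
#' @export
ladderAssignment <- function(x) x@assignment

setMethod("show", "LadderAssignment", function(object) {
  cat("LadderAssignment:", nrow(object@assignment), "glucose units from",
      nrow(object@observations), "candidate observations\n")
  print(object@assignment, row.names = FALSE)
})
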