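# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, convolution, brute force) kept separate from
# the package's own algorithms.

# Full aggregated isotope distribution by element-wise convolution, with
# mass-moment tracking; the independent check on the BRAIN recursion.
oracleEnvelope <- function(formula, nPeaks = 10L, maxLen = 40L) {
  counts <- structure(formula@.Data, names = names(formula))
  counts <- counts[counts > 0L]
  tabs <- glycoGU:::.ISOTOPES[names(counts)]
  prob <- 1
  massMoment <- 0   # sum over isotopologues of P * mass, per offset
  for (i in seq_along(counts)) {
    a <- tabs[[i]]$abundance
    m <- tabs[[i]]$mass
    for (k in seq_len(counts[[i]])) {
      newProb <- numeric(min(length(prob) + length(a) - 1L, maxLen))
      newMom <- numeric(length(newProb))
      for (j in seq_along(a)) {
        idx <- seq_along(prob) + j - 1L
        keep <- idx <= maxLen
        newProb[idx[keep]] <- newProb[idx[keep]] + prob[keep] * a[j]
        newMom[idx[keep]] <- newMom[idx[keep]] +
          massMoment[keep] * a[j] + prob[keep] * a[j] * m[j]
      }
      prob <- newProb
      massMoment <- newMom
    }
  }
  n <- min(nPeaks, length(prob))
  list(probabilities = prob[seq_len(n)],
       masses = ifelse(prob[seq_len(n)] > 0,
                       massMoment[seq_len(n)] / prob[seq_len(n)], NA_real_))
}

# random CHNO formula with a bounded total atom count
randomFormula <- function(maxAtoms = 200L) {
  repeat {
    n <- c(C = sample(0:80, 1), H = sample(0:120, 1),
           N = sample(0:20, 1), O = sample(0:40, 1))
    if (sum(n) >= 1 && sum(n) <= maxAtoms) break
  }
  do.call(elementalFormula, as.list(n))
}

# Exhaustive maximum-score order-respecting ladder assignment: enumerates
# every non-decreasing GU sequence over the scans and maximizes summed
# matched intensity. Returns the best total score.
oracleLadderScore <- function(I) {
  nS <- nrow(I); nU <- ncol(I)
  best <- -Inf
  rec <- function(i, uMin, acc) {
    if (i > nS) {
      best <<- max(best, acc)
      return(invisible())
    }
    for (u in uMin:nU) rec(i + 1L, u, acc + I[i, u])
  }
  rec(1L, 1L, 0)
  best
}

# Linear-scan reference for the bucket index
oracleQuery <- function(peaks, m, tol) {
  hit <- which(abs(peaks$mz - m) <= tol)
  peaks[hit[order(peaks$mz[hit])], , drop = FALSE]
}

# Brute-force composition enumeration under the biosynthesis filter
oracleEnumerate <- function(maxHexNAc, maxHex, maxFuc, maxNeuAc) {
  out <- character(0)
  for (hn in 0:maxHexNAc) for (hx in 0:maxHex)
    for (fc in 0:maxFuc) for (na in 0:maxNeuAc)
      if (hn >= 2 && hx >= 3 && fc <= hn && na <= max(0, hn - 2))
        out <- c(out, paste0("HexNAc", hn, "Hex", hx, "Fuc", fc, "NeuAc", na))
  sort(out)
}

# small helper: a one-species synthetic run with standard glycan settings
glycanRow <- function(composition, gui = NA_real_, rt = NA_real_,
                      charge = 1L, adduct = "proton", height = 1e5,
                      sigma = 0.15) {
  data.frame(composition = composition, charge = as.integer(charge),
             adduct = adduct, gui = gui, rt = rt, height = height,
             sigma = sigma, stringsAsFactors = FALSE)
}
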