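# Aggregated isotopic distributions by the BRAIN polynomial recursion.
#
# The generating polynomial of the molecule is P(x) = prod_e Q_e(x)^{n_e},
# where Q_e(x) = sum_j a_{e,j} x^j collects element e's isotope abundances by
# nucleon-number offset j. Aggregated probabilities q_j are the coefficients
# of P. Writing P(x) = q_0 prod_i (1 - x/r_i) over its roots r_i gives the
# Newton-Girard recursion
#     q_j = -(1/j) * sum_{m=1}^{j} psi_m * q_{j-m},
# with power sums psi_m = sum_i r_i^{-m} that decompose per element, so only
# the roots of the small per-element polynomials are ever needed. Centroid
# masses come from the companion series U(x) = P(x) * S(x) with
# S(x) = sum_e n_e Q'^m_e(x)/Q_e(x) (mass-weighted numerators), because the
# molecular mass is additive over atoms; centroid_j = U_j / q_j.

# Inverse-root power sums of one element's abundance polynomial, m = 1..n.
.elementPowerSums <- function(abundance, n) {
  k <- length(abundance) - 1L
  if (k == 0L) return(numeric(n))          # monoisotopic element: no roots
  if (k == 1L) {
    # linear: single root r = -a0/a1, r^-m = (-a1/a0)^m
    ratio <- -abundance[2L] / abundance[1L]
    return(ratio^seq_len(n))
  }
  r <- polyroot(abundance)
  vapply(seq_len(n), function(m) sum(Re(r^(-m))), numeric(1))
}

# Truncated power series of Qm(x)/Q(x), where Qm has coefficients
# abundance * mass. Plain long division.
.massSeries <- function(abundance, mass, n) {
  num <- abundance * mass
  a <- abundance
  d <- numeric(n)
  for (j in seq_len(n)) {
    jj <- j - 1L
    acc <- if (jj < length(num)) num[j] else 0
    for (i in seq_len(min(jj, length(a) - 1L))) acc <- acc - a[i + 1L] * d[j - i]
    d[j] <- acc / a[1L]
  }
  d
}

#' Aggregated isotope envelope of a formula
#'
#' Computes the first \code{nPeaks} aggregated isotopic probabilities of an
#' elemental formula by the BRAIN polynomial recursion (Newton-Girard power
#' sums of the per-element abundance-polynomial roots), together with
#' probability-weighted centroid masses per aggregated peak.
#'
#' @param formula an \linkS4class{ElementalFormula}
#' @param nPeaks number of aggregated peaks to compute (default 10, which
#'   truncates below 1e-6 for the largest default glycan composition)
#' @return an \linkS4class{IsotopeEnvelope}
#' @examples
#' isotopeEnvelope(elementalFormula(C = 1))  # carbon isotope abundances
#' @export
isotopeEnvelope <- function(formula, nPeaks = 10L) {
  stopifnot(is(formula, "ElementalFormula"))
  if (nPeaks < 1L) stop("nPeaks must be >= 1")
  nPeaks <- as.integer(nPeaks)
  counts <- structure(formula@.Data, names = names(formula))
  counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    return(new("IsotopeEnvelope", probabilities = 1, masses = 0,
               mostAbundant = 1L, formula = formula))

  tabs <- .ISOTOPES[names(counts)]
  q0 <- prod(vapply(tabs, function(t) t$abundance[1L], numeric(1))^counts)

  psi <- numeric(nPeaks - 1L)
  if (nPeaks > 1L)
    for (i in seq_along(counts))
      psi <- psi + counts[[i]] *
        .elementPowerSums(tabs[[i]]$abundance, nPeaks - 1L)

  q <- numeric(nPeaks)
  q[1L] <- q0
  for (j in seq_len(nPeaks - 1L))
    q[j + 1L] <- -sum(psi[seq_len(j)] * q[j:1L]) / j
  q <- pmax(q, 0)                          # guard tiny negative round-off

  # companion mass series
  s <- numeric(nPeaks)
  for (i in seq_along(counts))
    s <- s + counts[[i]] * .massSeries(tabs[[i]]$abundance, tabs[[i]]$mass, nPeaks)
  u <- vapply(seq_len(nPeaks), function(j) sum(q[seq_len(j)] * s[j:1L]), numeric(1))

  mono <- monoMass(formula)
  masses <- ifelse(q > 1e-300, u / q, mono + (seq_len(nPeaks) - 1L) * .NEUTRON)
  new("IsotopeEnvelope", probabilities = q, masses = masses,
      mostAbundant = which.max(q), formula = formula)
}

setMethod("show", "IsotopeEnvelope", function(object) {
  cat("IsotopeEnvelope:", length(object@probabilities), "aggregated peaks\n")
  print(data.frame(offset = seq_along(object@probabilities) - 1L,
                   mass = round(object@masses, 4),
                   probability = signif(object@probabilities, 4)),
        row.names = FALSE)
})

#' @describeIn isotopeEnvelope the aggregated probabilities
#' @param envelope an \linkS4class{IsotopeEnvelope}
#' @export
envelopeProbabilities <- function(envelope) envelope@probabilities

#' @describeIn isotopeEnvelope the centroid masses (Da)
#' @export
envelopeMasses <- function(envelope) envelope@masses

#' m/z of the most abundant isotopic ion
#'
#' The aggregated envelope peak with maximal probability, charge-adjusted.
#' This is the anchor searched first during annotation because it is the
#' most likely peak to be observed when the ion is present.
#'
#' @param comp a \linkS4class{GlycanComposition} or
#'   \linkS4class{ElementalFormula}
#' @param charge positive integer charge
#' @param adduct "proton" or "sodium"
#' @param derivatization passed to \code{\link{glycanFormula}} when
#'   \code{comp} is a composition
#' @param nPeaks envelope length
#' @return m/z in Th
#' @export
mostAbundantMz <- function(comp, charge = 1L, adduct = c("proton", "sodium"),
                           derivatization = "permethylated", nPeaks = 10L) {
  adduct <- match.arg(adduct)
  formula <- if (is(comp, "GlycanComposition"))
    glycanFormula(comp, derivatization) else comp
  env <- isotopeEnvelope(formula, nPeaks)
  ionMz(env@masses[env@mostAbundant], charge, adduct)
}

# Theoretical peaks covering >= `coverage` cumulative probability (minimum
# `minPeaks`), used as the scoring envelope length.
.envelopeLength <- function(envelope, coverage = 0.999, minPeaks = 3L) {
  cum <- cumsum(envelope@probabilities)
  hit <- which(cum >= coverage)
  n <- if (length(hit)) hit[1L] else length(cum)
  min(max(minPeaks, n), length(cum))
}
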