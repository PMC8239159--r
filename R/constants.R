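# Physical constants for mass calculations.
#
# Monoisotopic masses and isotopic abundances: IUPAC/CODATA compilation
# (Meija et al. 2016, Pure Appl. Chem.; AME2020 atomic masses), truncated to
# the precision relevant at ppm-level mass tolerances.

#' @keywords internal
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.9720707300,
  Na = 22.9897692820
)

# Per-element aggregated isotope tables: nucleon-number offset from the
# lightest isotope, exact mass, and natural abundance.
#' @keywords internal
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017780),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99632, 0.00368)),
  O = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.9720707300, 32.9714585430, 33.9678668400, 35.9670808800),
           abundance = c(0.9493, 0.0076, 0.0429, 0.0002)),
  Na = list(mass = 22.9897692820, abundance = 1.0)
)

# Cation masses used for ionization (atomic mass minus one electron); the
# residual electron bookkeeping (< 0.0006 Da) is far below working tolerance.
#' @keywords internal
.ADDUCT_MASS <- c(proton = 1.0072764669, sodium = 22.9892207100)

# Aggregated-peak spacing: mass difference 13C - 12C, the dominant +1 step
# in CHNO molecules.
#' @keywords internal
.NEUTRON <- 1.0033548378
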