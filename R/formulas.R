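#' Construct an elemental formula
#'
#' @param ... element counts, e.g. \code{elementalFormula(C = 6, H = 12, O = 6)}.
#'   Supported elements: C, H, N, O, S, Na.
#' @return an \linkS4class{ElementalFormula}
#' @examples
#' glc <- elementalFormula(C = 6, H = 12, O = 6)
#' monoMass(glc)
#' @export
elementalFormula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0L) return(new("ElementalFormula", integer(0)))
  if (is.null(names(counts))) stop("element counts must be named")
  counts <- vapply(counts, function(x) {
    if (abs(x - round(x)) > 1e-9) stop("element counts must be integers")
    as.integer(round(x))
  }, integer(1))
  new("ElementalFormula", counts)
}

.formulaOp <- function(e1, e2, op) {
  els <- union(names(e1), names(e2))
  a <- structure(integer(length(els)), names = els)
  b <- a
  a[names(e1)] <- e1@.Data
  b[names(e2)] <- e2@.Data
  r <- op(a, b)
  new("ElementalFormula", r[r != 0L | els %in% names(e1)])
}

#' @describeIn elementalFormula element-wise formula arithmetic; \code{*}
#'   takes a non-negative integer scalar on either side
#' @param e1,e2 operands
#' @export
setMethod("Arith", signature("ElementalFormula", "ElementalFormula"),
  function(e1, e2) {
    switch(.Generic,
      "+" = .formulaOp(e1, e2, `+`),
      "-" = .formulaOp(e1, e2, `-`),
      stop("operation '", .Generic, "' not defined for formulas"))
  })

#' @export
setMethod("Arith", signature("ElementalFormula", "numeric"), function(e1, e2) {
  if (.Generic != "*") stop("operation '", .Generic, "' not defined for formulas")
  new("ElementalFormula", structure(as.integer(e1@.Data * e2), names = names(e1)))
})

#' @export
setMethod("Arith", signature("numeric", "ElementalFormula"), function(e1, e2) e2 * e1)

setMethod("show", "ElementalFormula", function(object) {
  n <- object@.Data[object@.Data > 0L]
  cat("ElementalFormula:",
      if (length(n)) paste0(names(n), n, collapse = "") else "(empty)", "\n")
})

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the lightest isotope.
#'
#' @param formula an \linkS4class{ElementalFormula}
#' @return mass in Da
#' @export
monoMass <- function(formula) {
  stopifnot(is(formula, "ElementalFormula"))
  sum(.MONOISOTOPIC[names(formula)] * formula@.Data)
}

#' Formula of a permethylated dextrin ladder rung
#'
#' The fully permethylated linear glucan of \code{gu} glucose units with a
#' free (permethylated) reducing end: the base glucan C(6g)H(10g+2)O(5g+1)
#' gains one CH2 per free hydroxyl (3g + 2 of them), giving
#' C(9g+2) H(16g+6) O(5g+1).
#'
#' @param gu number of glucose units (>= 1)
#' @return an \linkS4class{ElementalFormula}
#' @examples
#' monoMass(dextrinFormula(2))  # 454.2414
#' @export
dextrinFormula <- function(gu) {
  if (length(gu) != 1L || gu < 1 || gu != round(gu))
    stop("gu must be a single integer >= 1")
  g <- as.integer(gu)
  elementalFormula(C = 9L * g + 2L, H = 16L * g + 6L, O = 5L * g + 1L)
}

# Residue increments (residue = monosaccharide minus water), per
# derivatization. Permethylated values include the methyl on every freed
# hydroxyl/amide of the residue.
.RESIDUES <- list(
  permethylated = list(
    hexnac = c(C = 11L, H = 19L, N = 1L, O = 5L),
    hex    = c(C = 9L,  H = 16L, O = 5L),
    fuc    = c(C = 7L,  H = 12L, O = 4L),
    neuac  = c(C = 16L, H = 27L, N = 1L, O = 7L),
    water  = c(C = 2L,  H = 6L,  O = 1L)   # methylated termini
  ),
  native = list(
    hexnac = c(C = 8L,  H = 13L, N = 1L, O = 5L),
    hex    = c(C = 6L,  H = 10L, O = 5L),
    fuc    = c(C = 6L,  H = 10L, O = 4L),
    neuac  = c(C = 11L, H = 17L, N = 1L, O = 8L),
    water  = c(H = 2L, O = 1L)
  )
)

#' Construct a glycan composition
#'
#' @param hexnac,hex,fuc,neuac non-negative monosaccharide counts
#' @return a \linkS4class{GlycanComposition}
#' @examples
#' glycanComposition(2, 3)           # the Man3GlcNAc2 N-glycan core
#' @export
glycanComposition <- function(hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L) {
  new("GlycanComposition", hexnac = as.integer(hexnac), hex = as.integer(hex),
      fuc = as.integer(fuc), neuac = as.integer(neuac))
}

#' @describeIn glycanComposition render as text, zero counts included
#'   (e.g. "HexNAc2Hex3Fuc0NeuAc0")
#' @param comp a \linkS4class{GlycanComposition}
#' @export
compositionString <- function(comp) {
  stopifnot(is(comp, "GlycanComposition"))
  paste0("HexNAc", comp@hexnac, "Hex", comp@hex,
         "Fuc", comp@fuc, "NeuAc", comp@neuac)
}

#' @describeIn glycanComposition parse a composition string back to an object
#' @param x a composition string as produced by \code{compositionString}
#' @export
parseComposition <- function(x) {
  m <- regmatches(x, regexec("^HexNAc(\\d+)Hex(\\d+)Fuc(\\d+)NeuAc(\\d+)$", x))[[1L]]
  if (length(m) != 5L) stop("not a composition string: ", x)
  glycanComposition(as.integer(m[2L]), as.integer(m[3L]),
                    as.integer(m[4L]), as.integer(m[5L]))
}

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition:", compositionString(object), "\n")
})

#' Elemental formula of a glycan composition
#'
#' Residue increments plus the (derivatization-dependent) terminal water:
#' permethylated residues Hex C9H16O5, HexNAc C11H19NO5, Fuc C7H12O4,
#' NeuAc C16H27NO7 with terminus C2H6O; native residues Hex C6H10O5,
#' HexNAc C8H13NO5, Fuc C6H10O4, NeuAc C11H17NO8 with terminus H2O.
#'
#' @param comp a \linkS4class{GlycanComposition}
#' @param derivatization "permethylated" (default) or "native"
#' @return an \linkS4class{ElementalFormula}
#' @examples
#' monoMass(glycanFormula(glycanComposition(2, 3), "native"))  # 910.3278
#' @export
glycanFormula <- function(comp, derivatization = c("permethylated", "native")) {
  stopifnot(is(comp, "GlycanComposition"))
  derivatization <- match.arg(derivatization)
  res <- .RESIDUES[[derivatization]]
  counts <- c(hexnac = comp@hexnac, hex = comp@hex, fuc = comp@fuc, neuac = comp@neuac)
  f <- do.call(elementalFormula, as.list(res$water))
  for (r in names(counts))
    if (counts[[r]] > 0L)
      f <- f + do.call(elementalFormula, as.list(res[[r]])) * counts[[r]]
  f
}

#' m/z of an ion
#'
#' \code{(M + z * adductMass) / z} with cation masses proton = 1.00728 Da
#' and Na+ = 22.98922 Da (electron mass already accounted for in the cation
#' mass).
#'
#' @param mass neutral monoisotopic mass in Da, or an
#'   \linkS4class{ElementalFormula}
#' @param charge positive integer charge
#' @param adduct "proton" or "sodium"
#' @return m/z in Th
#' @export
ionMz <- function(mass, charge = 1L, adduct = c("proton", "sodium")) {
  adduct <- match.arg(adduct)
  if (is(mass, "ElementalFormula")) mass <- monoMass(mass)
  if (charge < 1 || charge != round(charge)) stop("charge must be a positive integer")
  (mass + charge * .ADDUCT_MASS[[adduct]]) / charge
}

#' Enumerate biosynthetically plausible N-glycan compositions
#'
#' All compositions within the per-residue maxima that pass the
#' N-glycosylation biosynthesis filter: (a) at least the trimannosyl-chitobiose
#' core (HexNAc >= 2, Hex >= 3); (b) fucose count bounded by available GlcNAc
#' attachment sites (Fuc <= HexNAc); (c) sialic acids bounded by antennary
#' GlcNAc (NeuAc <= max(0, HexNAc - 2)). Output is in lexicographic order of
#' (HexNAc, Hex, Fuc, NeuAc).
#'
#' @param maxHexNAc,maxHex,maxFuc,maxNeuAc per-residue maxima; the defaults
#'   are the standard search space for permethylated serum N-glycomes
#' @param filter the biosynthesis predicate; a function of four integer
#'   vectors returning logical. Replace to change the rule set.
#' @return list of \linkS4class{GlycanComposition}
#' @export
enumerateGlycans <- function(maxHexNAc = 12L, maxHex = 12L, maxFuc = 5L,
                             maxNeuAc = 4L, filter = biosynthesisFilter) {
  grid <- expand.grid(neuac = 0:maxNeuAc, fuc = 0:maxFuc, hex = 0:maxHex,
                      hexnac = 0:maxHexNAc)
  keep <- filter(grid$hexnac, grid$hex, grid$fuc, grid$neuac)
  grid <- grid[keep, , drop = FALSE]
  grid <- grid[order(grid$hexnac, grid$hex, grid$fuc, grid$neuac), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    glycanComposition(grid$hexnac[i], grid$hex[i], grid$fuc[i], grid$neuac[i]))
}

#' @describeIn enumerateGlycans the default biosynthesis predicate
#' @param hexnac,hex,fuc,neuac integer vectors of candidate counts
#' @export
biosynthesisFilter <- function(hexnac, hex, fuc, neuac) {
  hexnac >= 2L & hex >= 3L & fuc <= hexnac & neuac <= pmax(0L, hexnac - 2L)
}
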