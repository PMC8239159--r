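---
title: "Glucose-unit indexing of permethylated N-glycans: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucose-unit indexing of permethylated N-glycans: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoGU)
```

# The method

Retention-time calibration against a co-injected dextrin ladder converts
instrument-specific elution times into Glucose Unit Index (GUI) values that
are stable across columns, gradients and laboratories. `glycoGU` implements
the complete chain — ladder detection, calibration, envelope-based
annotation, per-isomer quantification — for permethylated N-glycans
measured by LC-MS in positive mode. This vignette explains each model, its
assumptions, the tunables that matter, and the design choices made where
the design was genuinely open.

## Chemistry layer

A permethylated dextrin of $g$ glucose units has the closed-form formula
$\mathrm{C}_{9g+2}\mathrm{H}_{16g+6}\mathrm{O}_{5g+1}$: the underlying
glucan $\mathrm{C}_{6g}\mathrm{H}_{10g+2}\mathrm{O}_{5g+1}$ carries $3g+2$
free hydroxyls, each gaining one $\mathrm{CH_2}$ on methylation. Glycan
compositions are sums of permethylated residue increments (Hex
$\mathrm{C_9H_{16}O_5}$, HexNAc $\mathrm{C_{11}H_{19}NO_5}$, Fuc
$\mathrm{C_7H_{12}O_4}$, NeuAc $\mathrm{C_{16}H_{27}NO_7}$) plus a
methylated terminus $\mathrm{C_2H_6O}$; the native convention (residues
Hex $\mathrm{C_6H_{10}O_5}$ etc., terminus $\mathrm{H_2O}$) is available
through `derivatization = "native"`. The permethylation model assumes a
free, fully methylated reducing end, matching the ladder chemistry of the
standard spiking protocol; reduced-end variants are out of scope.

Ion m/z is $(M + z\,m_a)/z$ with cation masses $m_a$ = 1.00728 Da (proton)
or 22.98922 Da (Na$^+$); the sub-0.0006 Da electron bookkeeping is ignored,
far below the 10 ppm working tolerance.

Candidate N-glycan compositions are enumerated inside the bounds
HexNAc ≤ 12, Hex ≤ 12, Fuc ≤ 5, NeuAc ≤ 4 under a three-clause
biosynthesis filter: (a) HexNAc ≥ 2 and Hex ≥ 3 (every N-glycan contains
the trimannosyl-chitobiose core), (b) Fuc ≤ HexNAc (each fucose needs a
GlcNAc attachment site), (c) NeuAc ≤ max(0, HexNAc − 2) (sialylation is
capped by antennary GlcNAc). Biosynthesis rule sets differ between tools;
ours is deliberately a single replaceable predicate
(`biosynthesisFilter`), so a laboratory with different conventions swaps
one function rather than editing the enumeration.

## Aggregated isotope envelopes

Envelopes are computed by the BRAIN polynomial recursion. Writing the
molecule's abundance generating polynomial as
$P(x)=\prod_e Q_e(x)^{n_e}$ and $P(x)=q_0\prod_i(1-x/r_i)$, the aggregated
probabilities obey the Newton–Girard recursion
$q_j=-\tfrac1j\sum_{m=1}^{j}\psi_m\,q_{j-m}$ with inverse-root power sums
$\psi_m$ that decompose per element, so only the roots of the per-element
polynomials (degree ≤ 3 for CHNOS) are needed. Centroid masses come from
the companion series $U(x)=P(x)\sum_e n_e Q_e^m(x)/Q_e(x)$ (mass-weighted
numerators), exact because molecular mass is additive over atoms. The test
suite pins the recursion against an independent brute-force convolution to
below $10^{-10}$ per aggregated peak.

Ten aggregated peaks are computed per species. At that depth a typical
serum glycan (e.g. HexNAc4Hex5Fuc1NeuAc1) retains all but $\sim10^{-4}$ of
its probability mass; the single largest composition in the default search
space (HexNAc12Hex12Fuc5NeuAc4, ~470 carbons) truncates ~2.5%, which is
irrelevant in practice because scoring only uses the peaks covering 99.9%
of cumulative probability (minimum 3) and anchor selection is unaffected.
Isotope masses and abundances (IUPAC/CODATA) are embedded as constants —
no runtime lookups.

## Ladder detection and the elution-order dynamic program

Each rung's most abundant isotopic ion is searched over all MS1 spectra at
every putative charge (default up to +3) and adduct (default proton)
within the ppm tolerance; per spectrum and rung only the most intense match
is kept. Because noise and overlapping envelopes can make several rungs
match in one spectrum, the rung sequence is resolved globally by a dynamic
program over (scan $i$, rung $u$):

$$\mathrm{score}[i][u] = I(i,u) + \max\bigl(\mathrm{score}[i-1][u],\;
\max_{j\le u}\mathrm{score}[i-1][j]\bigr)$$

where $I(i,u)$ is the matched intensity (0 if unobserved). The recursion
encodes two assumptions: higher glucose units always elute later, and true
rung peaks are more intense than false matches. The intensity term
$I(i,u)$ is essential: an order-only recurrence without it scores every
admissible assignment identically and cannot discriminate true rungs from
decoys. Ties in the maximum prefer the same-rung
predecessor, yielding contiguous elution blocks; one rung is assigned per
scan. Each rung's final retention time is the scan of highest matched
intensity among the scans assigned to it, and the DP is pinned against
exhaustive enumeration over all order-respecting assignments in the tests.
An optional absolute intensity floor (`ladderIntensityFloor`, default off)
suppresses baseline pickups for the weak high-GU rungs.

## Calibration

GUI is regressed on retention time (GUI on the left-hand side):
polynomial $y=\beta_0+\beta_1x+\dots+\beta_nx^n$, default cubic, or
logarithmic $y=\beta_0+\beta_1\log x$. Both kinds are always available —
published practice is split between them and both reach $R^2>0.99$ on real
ladders — but one kind must be used consistently across samples that are
compared. The solution is the normal-equations estimator
$\vec\beta=(X^TX)^{-1}X^T\vec y$ solved by Gaussian elimination, the
reference semantics of the method; since a raw minute-scale cubic
Vandermonde matrix is ill-conditioned, the regressor is mean-centred and
scaled internally and coefficients are back-transformed, and the tests pin
the result against R's QR solver to $10^{-8}$. Evaluation outside the
fitted rt range is permitted but flagged as extrapolation.

## Annotation scoring

The anchor-first rule — no match unless the most abundant isotopic ion is
observed — reflects that the anchor is the likeliest peak to survive
detection if the glycan is present at all. Matched envelopes are scored by
the standard Pearson correlation between theoretical and observed
intensities, with cutoff 0.9 on
the signed value and no clipping of negative correlations. Pearson is
preferred over cosine similarity because it is invariant to *affine*
transformation of the observed intensities — detector gain and constant
offset both drop out. Matches with zero variance in either vector are
undefined and rejected. Annotations at different charges/adducts of one
composition are reported separately; merging happens in quantification.

## Quantification

XICs combine the nearest in-tolerance intensities at the **three most
probable** theoretical isotope m/z values per scan (the alternative
reading, the first three peaks, loses signal for large glycans whose
monoisotopic peak is minor). Peak detection is apex-first: boundary walk
outward while intensity ≥ 50% of apex (ties inclusive), then extension to
the nearest local minimum; the covered span is retired and the search
repeats. Integration is trapezoidal over retention time with inclusive
bounds: excluding the boundary points would discard real signal at
half-height, and intensity×time units are required for
injection-to-injection comparability. A raw point-intensity summation
mode (`areaMethod = "sum"`) is provided for compatibility with tools that
report unit-free sums. Isomer peaks within 0.2 min of apex across charge
states are merged with areas summed — 0.2 min is four scan intervals at
the default grid and roughly one chromatographic sigma, wide enough to
absorb apex quantization and narrow enough not to fuse resolved isomers.
A `minApex` floor (default off) exists for noisy data.

## The synthetic generator

`generateRun` emulates the spiked-serum experiment the method was designed
for: ladder rungs GU 2–12 placed on a fixed monotone cubic GU-elution
curve spanning ~10–55 min, each species contributing its full aggregated
envelope scaled by a Gaussian elution profile (σ = 0.15 min) on a 0.05-min
scan grid; rung heights decay geometrically (×0.75 per GU) so high rungs
are weak, as on real instruments; decoys are uniform in m/z with
log-normal intensities, with the default median placed at one tenth of the
weakest rung — the regime in which baseline peaks sit clearly below the
internal standard, which is the operating assumption of the intensity-based
DP. Runs are bit-reproducible under a fixed seed and carry a ground-truth
manifest (planted rts, heights, analytic areas
$h\,\sigma\sqrt{2\pi}\times$ top-3 fraction) used by every end-to-end
test.

What the generator does **not** model: chemical noise with structure
(chimeric envelopes, co-eluting near-isobars), detector saturation,
peak tailing/fronting, retention drift within a run, and MS2 spectra.
Passing tests therefore demonstrate algorithmic correctness and the
stated noise robustness, not performance on adversarial real-world
interference — on real data the Pearson cutoff and the GUI library
cross-check remain the operator's guard rails.

## Numerical choices and degenerate inputs

* Charge derivation prefers the largest charge whose isotope-spacing
  companion exists: a z = 2 envelope also passes the z = 1 test at twice
  the gap, so the denser spacing is the more specific explanation.
* Bucket width defaults to 0.05 Th so a 10 ppm query touches at most 3
  buckets up to m/z ≈ 5000; queries are exactly equivalent to a linear
  scan (tested on randomized runs).
* Centroiding splits contiguous above-zero profile regions at internal
  minima between local maxima and reports intensity-weighted m/z centroids
  carrying the apex intensity; it is idempotent.
* An all-zero XIC yields zero peaks; a zero-width integration span has
  zero area; inverted bounds are an error.
* A rung with no supporting observation is dropped from the assignment
  with a warning; the pipeline fails at the calibration stage, with an
  actionable message, when fewer than order + 1 rungs survive.
* $R^2$ of a flat response (zero total sum of squares) is reported as 1,
  the fit being exact.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated
data: runs of ~500–1000 scans, composition search spaces up to bounds
(4, 6, 1, 1), 50-seed perturbation ensembles and 100-trace detection
ensembles. These sizes exercise every code path at comfortable margins;
the algorithms scale linearly in scans × compositions and have been run
unchanged on the full default bounds (2,600 compositions).

## Known limitations

Compositions only — no linkage or topology, no O-glycan rules, no MS2
verification, no FDR estimate, no cross-run alignment or normalization.
The biosynthesis filter is a documented convention, not a claim of
identity with any other tool's rule set; annotation counts are therefore
not comparable across tools with different filters. mzML is the only
input format; vendor files must be converted upstream.
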