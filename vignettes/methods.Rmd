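---
title: "Methods: rule-based identification and composition analysis of intact phospholipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based identification and composition analysis of intact phospholipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krillipids)
```

## Scope and model

`krillipids` implements a dual-polarity identification scheme for diacyl
glycerophospholipids of seven head-group classes (PC, PE, PME, PDME, PI,
PG, PS), followed by internal-standard quantification and compositional
season/organ statistics. Lyso- and ether lipids are outside the model:
every species is assumed to carry exactly two ester-bound acyl chains, so
a sum composition `class(C:D)` (total acyl carbons, total double-bond
equivalents) determines a unique neutral formula per class. Double-bond
positions, cis/trans geometry and glycerol stereochemistry are not
modelled; the *sn*-2 assignment is an intensity heuristic, not a
structural determination.

All mass arithmetic runs on a single pinned table of monoisotopic atomic
masses (C, H, D, N, O, P) with electron-mass correction on every ion m/z.
The correction matters at the reported precision: the phosphocholine
fragment is 184.0733 with it and 184.0739 without. Deuterium is carried as
its own element symbol for the d70-PC(36:0) internal standard
(`C44H18D70NO8P`, +70 x (m(2H) - m(1H)) relative to PC(36:0)).

### Adduct conventions

Positive mode: `[M+H]+` for PC, PE, PME, PDME, PS; `[M+NH4]+` for PI and
PG. The ammonium adducts follow from the head-group neutral-loss masses of
the acidic classes (277.0563 = inositol phosphate + NH3; 189.0402 =
glycerophosphate + NH3), which are only consistent with ammoniated
precursors in ammonium-acetate buffer — the same reasoning applies whether
PG also forms minor `[M+H]+`; the package commits to the ammonium adduct
and exposes an override in `precursor_mz()`. Negative mode: `[M+HCOO]-`
for PC, `[M-H]-` otherwise.

### The confirmation gate

`confirm_species()` accepts a cross-polarity feature pair only when every
stage passes:

1. a positive-mode class-diagnostic MS2 signal (fragment ion for PC,
   head-group neutral loss otherwise);
2. a sum composition within the MS1 tolerance of the positive-mode
   precursor, found by exhaustive scan of the (C, D) grid;
3. the negative-mode precursor at the class's negative adduct within the
   MS1 tolerance;
4. the negative-mode class diagnostic where the class has one (methyl
   formate loss for PC, the 259.0224 fragment for PI, the 87.0320 loss for
   PS) — PE, PME, PDME and PG have no negative-mode diagnostic and confirm
   on precursor plus acyl evidence;
5. at least one acyl pair from the search space whose carbon and DBE sums
   match the composition and whose carboxylate anions are both present in
   ESI- MS2.

Rejections are data: every failed pair carries a machine-readable reason
(the deepest stage any candidate class reached). Species at one retention
time with the same label are combined into a single entry listing all acyl
pairs, mirroring combined integration of co-eluting isomers. A species
passing stages 1–4 but not 5 can optionally (`require_pairs = FALSE`) be
kept as "sum-composition only"; such species count toward species-level
statistics but are excluded (and counted) in all fatty-acid-level
statistics, since their chains are unresolved.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ms1_tol_ppm` | 5 | ppm | typical external-calibration Orbitrap accuracy |
| `ms2_tol_ppm` | 10 | ppm | HCD fragment accuracy, looser at low m/z |
| `rt_tol_min` | 0.1 | min | cross-polarity co-elution window |
| `c_total_range` | 20–70 | C | covers 12:0 + 12:0 up to VLCPUFA pairs |
| `dbe_total_range` | 0–16 | DBE | up to two highly unsaturated chains |
| `fa_carbon_range` | 12–40 | C | observed chain range 12:0–36:8 plus margin |
| `fa_dbe_range` | 0–10 | DBE | covers 28:8/36:8 |
| `grubbs_alpha` | 0.05 | — | conventional outlier significance |
| `n_cal_levels` | 5 | — | local calibration window |

The source workflow integrated peaks in vendor software and states no
matching tolerances; the three tolerances above are engineering defaults
and deliberately configurable. The acyl feasibility guard
`DBE <= C - 2` is relaxable (`fa_check_feasible`) because rings cannot be
excluded in unusual chains.

## Quantification

Replicate area ratios at each calibration level pass an iterative
two-sided Grubbs test (`G = max|x - mean|/sd` against
`((N-1)/sqrt(N)) sqrt(t^2/(N-2+t^2))`, `t` the upper `alpha/(2N)` t-quantile
with `N-2` df; one removal per pass, never below three values), then
average into a per-level mean. For each sample ratio the five levels whose
means are nearest are selected — contiguous windows over the
concentration-ordered levels, preferring a window that brackets the ratio,
ties toward lower concentrations, extremes flagged as extrapolation — and
an ordinary least-squares line through those five points is inverted.
Negative predictions floor at zero with a flag. A weighted (1/x) local fit
is the natural alternative if heteroscedastic calibrations dominate; the
unweighted line is the minimal faithful reading of a "five chosen levels"
scheme and is what the package commits to.

Two power facts worth knowing, both verified in the test suite: (i) at
quadruplicates the two-sided Grubbs statistic cannot exceed
`(N-1)/sqrt(N) = 1.5` while the 0.05-level critical value is 1.481, so the
screen has essentially no power against noise-scale deviations — it
reliably removes only gross errors (the simulator plants 5-fold
multiplicative errors, e.g. a dilution mistake, which are removed in well
over 95% of trials); (ii) on clean quadruplicates the false-removal rate
stays near the nominal 5%.

Blank subtraction removes the mean process-blank concentration per
species, flooring at zero and dropping fully blanked species. Because
sample weighing is not part of the workflow, all downstream statistics use
within-sample percentage distributions; every percentage table produced by
the package sums to 100 within 1e-9 by construction, and this is asserted
in the tests.

## Composition statistics

* **Grouping** (`derive_grouping`): within each class, species are binned
  LMW/MMW/HMW by neutral mass and LDU/MDU/HDU by total DBE at the tertiles
  of the distinct per-class values. The original study's grouping
  boundaries live in supplementary tables that are not machine-readable
  here, so tertiles are the default and explicit breakpoints are
  injectable per class. Degenerate classes (fewer than three distinct
  values, or tertiles that coincide) collapse to a single bin with a
  warning.
* **PCA** (`pca_scores`): column-centred `stats::prcomp` on the grouped
  percentage matrix; scaling is off by default because all columns share
  the percentage scale.
* **Seasonal ratios** (`seasonal_ratios`): per species, the mean
  percentage across samples of month set A over the mean across set B,
  with a species absent from a sample counting as zero in that sample's
  mean. Means over samples (not pooled totals) are used; the reciprocal
  property `ratios(A,B) = 1/ratios(B,A)` then holds exactly and is tested.
  One-sided species are flagged, never imputed.
* **Ternary SFA/MUFA/PUFA** (`fa_saturation_ternary`): each species splits
  its percentage equally over its two acyl positions; species with several
  consistent pairs split across pairs proportionally to the intensity of
  each pair's more abundant acyl fragment. Chains bin as saturated (0
  DBE), monounsaturated (1) and polyunsaturated (>= 2).
* **Indices** (`pufa_indices`): the weighted mean unsaturation per fatty
  acid is the abundance-weighted mean of `DBE_total/2` over the class; the
  EPA/DHA indices are the within-class percentage of species carrying at
  least one 20:5 / 22:6 chain, multi-pair species counted by the
  apportioned fraction of pairs containing the chain.
* **Reference overlap** (`reference_overlap`): per class, sum-formula
  counts, intersection and the summed within-class abundance of
  intersecting formulas on each side, for a user-supplied reference table.
  No external reference dataset ships with the package; the analysis
  driver demonstrates the operation on a synthetic reference and labels it
  as such.

## The simulator

`simulate_study()` emulates the study design the statistics expect: months
Jan/Mar (Antarctic summer) and May (autumn), the three digestive organs at
eight replicates each plus three organ-free tissue replicates per month,
three process blanks, and quadruplicate calibration series over nine
log-spaced levels (1e-4 to 10 ug/mL within the workflow's 0.1 pg/mL–10
ug/mL envelope). The lipidome is drawn with class weights proportional to
the class diversity reported for krill digestive organs
(59:27:13:11:7:6:4 for PC:PE:PDME:PI:PME:PG:PS) and an acyl pool dominated
by 16:0, 18:1, 20:5 and 22:6 with a VLCPUFA tail (26:6, 28:8, 36:8);
baseline concentrations are log-normal (median 0.05 ug/mL, sdlog 1). The
planted condition effect doubles (`effect_factor = 2`) the concentration
of species in the top tertile of both total carbons and total DBE in
summer digestive-gland samples — the direction, not the magnitude, of the
seasonal shift is what downstream tests assert.

**Mass error model.** Each rendered run draws one calibration bias shared
by every ion in both polarities — truncated normal with the configured
sigma (`ppm_sd`, default 2 ppm) and a 2.5 sigma bound, reading the
parameter as an instrument mass-accuracy specification — plus per-scan
scatter of sigma/8. This reflects how Orbitrap mass error actually
behaves: calibration drift is systematic across a run, scan-to-scan
scatter at high signal is a fraction of a ppm. Under this model a 2 ppm
error against 5 ppm tolerances loses essentially nothing (the recovery
tests require 100% noiseless and >= 99% at 2 ppm over 20 seeds), while
20 ppm error collapses recovery — both are asserted. An iid-per-peak error
model at the same sigma would instead lose ~8% of species at the
cross-polarity pairing gate alone, which mis-states instrument physics and
was rejected for that reason.

Area noise is multiplicative log-normal (mean 1, default CV 10%); the
internal standard renders at a fixed nominal area. Retention times sit on
class-level means inside the 3.5–9 min window with Gaussian jitter.
Optional decoy features draw uniform m/z kept at least three tolerance
widths from every theoretical signal, so false-positive tests are sharp.
Isomers (same class and sum composition) co-elute by construction and
render as one combined feature whose ESI- MS2 carries all acyl anions,
with the *sn*-2 chain of each pair at double intensity.

What the simulator does **not** emulate: profile-mode peak shapes,
isotope envelopes, chromatographic drift and alignment, in-source
fragmentation, matrix suppression, shared fragments between co-isolated
precursors, and biological covariance between species. Passing tests
therefore demonstrate the correctness of the rule logic, the calibration
arithmetic and the statistics on idealized peak lists — not robustness to
raw-data artefacts upstream of peak integration.

## Numerical choices and degenerate inputs

* Tolerance windows are relative (ppm) everywhere; matching takes the most
  intense in-window peak.
* Pair enumeration orders results by *sn*-2 fragment intensity, then
  lexicographically; candidate classes by diagnostic-fragment intensity;
  level-window ties toward lower concentration — all outputs are
  deterministic, and equal seeds reproduce study directories and result
  tables byte for byte (asserted).
* Empty compositions, infeasible formulas (non-positive hydrogen counts),
  subtraction below zero, unknown elements, missing internal standards,
  all-zero samples and empty references raise errors naming the problem;
  empty feature tables and missing blanks warn and continue.
* Problem sizes in the tests are chosen for determinism and speed: 200
  random cases against the brute-force pair oracle, 20 seeds for recovery,
  200 trials for outlier removal, and a 27-sample study for the planted
  seasonal-shift recovery; the analysis drivers run the full 81-sample
  design.

## Known limitations

* Identification is gate-based; there is no score or FDR, so a decoy
  passing every gate (wrong species at matching mass, RT and fragments) is
  undetectable by design — acceptable at 5 ppm with this class system, but
  worth revisiting for richer lipidomes.
* The five-level local calibration inherits the noise of its window;
  heteroscedastic series would benefit from the 1/x weighting option.
* Tertile grouping boundaries are a stand-in for expert-chosen ones;
  injected breakpoints should be preferred when available.
* The EPA/DHA indices and the ternary apportionment depend on resolved
  pairs; lipidomes with many sum-composition-only species lose those
  species from fatty-acid-level statistics.
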