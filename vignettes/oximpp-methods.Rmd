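---
title: "Methods and design of the oximpp workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the oximpp workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oximpp)
```

This vignette documents the models and conventions behind `oximpp`, the
parameters that matter, the design choices made where several reasonable
options existed, and what the synthetic-data tests do and do not demonstrate
about real instrument data.

## Derivatization mass model

AMPP (*N*-(4-aminomethylphenyl)pyridinium) reacts with the carboxylic acid of
an oxylipin to form an amide. The resulting cation carries the head-group
atoms C12H13N2 and has lost one water:

$$ m([M^+]) = m(\mathrm{acid}) + m(\mathrm{C_{12}H_{13}N_2}) - m(\mathrm{H_2O}) $$

Two conventions needed a decision:

- **Electron mass.** The tabulated reference [M⁺] values are reproduced to
  within 7·10⁻⁵ Da only when the cation mass is a plain atom sum, i.e. when no
  electron mass (0.00055 Da) is subtracted. `derivatized_mz()` therefore
  defaults to the atom-sum convention and exposes
  `electron_correction = TRUE` for the physically exact cation mass. The two
  conventions differ by roughly 1 ppm at *m/z* 500, within the 10 ppm matching
  tolerances used downstream, so the choice does not affect matching — only
  agreement with the reference table at the 0.0005 Da level.
- **Diagnostic fragments.** The head-group cleavage ions are stored at the
  nominal printed precision (169.0 / 183.1 light; 174.0 / 188.1 heavy), not as
  theoretical exact masses, because the non-targeted filter operates at 0.1 Da
  around exactly these nominal values. The heavy values are the light values
  plus the nominal 5 Da deuterium shift; the exact precursor-level shift is
  5 × (m(²H) − m(¹H)) = 5.03138 Da.

The head-group composition C12H13N2 is not stated anywhere as a formula; it is
inferred from the AMPP structure and validated by the agreement of all 52
library precursor masses.

## Reference library

The packaged library (`load_reference_library()`) stores one record per
analyte: class family (hydroxy / dihydroxy / epoxy), precursor PUFA (LA, ALA,
ARA, EPA, DHA), functional-group position, acid formula, [M⁺], quantifier
fragment, retention time (min), drift time (ms), CCS (Å²), LOD/LLOQ/ULOQ (nM)
and calibration R². Conventions:

- Quantifier fragment *m/z* values are empirical and never recomputed from
  structure — simple amide-fragment arithmetic does not reproduce them.
- LLOQ/ULOQ cells that are the lowest/highest calibration point rather than a
  determined limit carry provenance flags (`lloq_at_cal_limit`,
  `uloq_at_cal_limit`).
- Positions of vicinal diols and epoxides use the **lower carbon index**
  (14 for the 14,15-diol), so regioisomer trend series are well defined; the
  convention is visible in the `position` column rather than configurable at
  call sites.
- 8-HEPE and 12-HEPE cannot be separated chromatographically or by mobility;
  the pair is cross-flagged in `unresolved_with`, and targeted results for
  either should be read as a combined measurement.

`ccs_trend()` projects a family × PUFA series onto (position, CCS) pairs. The
derivatized regioisomer series show a CCS maximum in the mid-chain (C10–C12)
region — consistent with the functional group interacting with the charged
head group when located further down the chain, compacting the ion.

## Single-field CCS calibration

Drift time in a single-field drift tube is linear in the product of the
Mason–Schamp reduced-mass factor and the collision cross section:

$$ t_D = \beta\, \gamma(m/z)\, \Omega + t_{fix}, \qquad
   \gamma = \frac{1}{z}\sqrt{\frac{m\,M_{gas}}{m + M_{gas}}} $$

The instrument constants β (drift efficiency) and t_fix (field-free transit
time) are not published with the reference data, so `fit_single_field()`
estimates them by least squares from the 52 (m/z, t_D, Ω) triples
(`stats::lm` behind the module surface). This reproduces the table almost
exactly: RMS residual 0.03 Å² expressed in CCS units (residual drift divided
by β·γ), and leave-one-out prediction of any held-out analyte within
0.06 Å² — far inside the 0.5 Å² acceptance bound, which in turn bounds any
unmodeled mass-dependent correction the instrument software might apply.
Defaults: N₂ drift gas (28.00615 Da), charge +1. Degenerate designs (fewer
than 2 points, or all γ·Ω equal) are rejected rather than extrapolated, and
`ccs_from_drift()` refuses drift times at or below t_fix as unphysical.

## Non-targeted consensus workflow

The workflow mirrors the published funnel: vendor pre-filter → diagnostic
fragment filter → cross-sample consensus.

- **Pre-filter** (`prefilter_features()`): RT window 2.0–25.0 min, charge +1,
  q-score ≥ 40, intensity ≥ 100 counts. All thresholds are inclusive,
  matching the ≥ notation of the source rules. The q-score is treated as an
  opaque pass/fail number. The vendor alignment tolerances (± 0.3 min RT,
  1.5 % drift, 10 ppm mass) belong to feature extraction, not to this filter;
  only the 10 ppm mass tolerance reappears as the default precursor matching
  tolerance.
- **Diagnostic filter** (`ampp_fragment_filter()`): a feature is kept when its
  spectrum has peaks within 0.1 Da of both head-group ions (`mode = "both"`,
  the default — the published description names both ions conjunctively;
  `"either"` is available because the wording is ambiguous). Features without
  spectra are excluded and counted in a report rather than raising an error.
- **Fragment overlap** (`fragment_overlap()`): both spectra are truncated to
  their 25 most abundant peaks (ties: lower *m/z* first), peaks are paired
  one-to-one within 0.1 Da, and the matched count is divided by the smaller
  truncated size, which handles features with fewer than 25 fragments. The
  pairing is computed by an ascending-*m/z* greedy pass (each peak matched to
  the smallest unused partner within tolerance). For threshold matching of
  points on a line this greedy attains the maximum possible number of pairs —
  a closest-pair-first greedy does not, which is why the implementation sorts
  by *m/z* rather than by pair distance. The tests verify equality with an
  exhaustive matching oracle on small spectra.
- **Consensus matching** (`match_across_samples()`): anchored to a designated
  reference sample rather than all-pairs. The worked three-replicate example
  that motivated this choice has an RT spread of 0.21 min across members —
  violating a 0.2 min all-pairs rule — while every member is within 0.2 min
  of the anchor. Candidate selection is deterministic (highest overlap, then
  smallest precursor error, then lowest feature id), each feature joins at
  most one consensus, and a consensus is emitted only when every sample
  contributes a member. The overlap threshold is ≥ 0.80 by default
  (`strict_overlap = TRUE` switches to >), since the source rules state both
  "> 80 %" and "80 % or more".

A caveat on the worked example: published per-replicate fragment lists are
curated structural subsets, not full top-25 spectra — replicates 1 and 2
share only 6 of 11 listed peaks. The example therefore validates the
diagnostic filter and the precursor/CCS/RT criteria; the 80 % overlap rule is
validated on synthetic spectra instead, and the example is run with the
overlap threshold relaxed to 0.5.

## Targeted quantification

`fit_calibration()` fits a weighted least-squares line with 1/x weighting by
default (conventional for calibrations spanning > 1 decade; `none` and
`1/x^2` available). Per-level accuracy is back-calculated/nominal; the
accepted band is 0.75–1.25 — the published criterion states only the lower
bound, and the band is made symmetric here. Because a saturating top level
distorts the whole weighted fit (it can even back-calculate within the band
while pushing low levels out), any band breach triggers exclusion of the
highest retained level and a refit, until all retained levels pass; the ULOQ
is the highest surviving level. LOD and LLOQ follow the s/n > 3 and s/n > 9
rules on instrument-supplied per-level signal-to-noise values, reported at
measured levels by default, with optional log-linear interpolation between
the bracketing levels. `quantify()` inverts the curve, floors results at zero
and flags values outside [LLOQ, ULOQ]; internal-standard normalization
(response ratio) makes results exactly invariant to any global response
scale. `per_cell_normalize()` converts nM to pmol per 10⁶ cells via
1 nM = 1 pmol/mL.

## Isotope-pair relative quantification

In a mixed run of an AMPP-derivatized control and a ²H₅-AMPP-derivatized
treated sample, every acid appears as a twin spaced by 5.03138 Da.
`pair_light_heavy()` pairs features at this exact spacing with defaults
mz_tol 0.01 Da (the published description gives only the nominal 5 Da
spacing), rt_tol 0.1 min (tighter than the 0.2 min cross-sample rule, since
both channels share one run) and a 0.5 % relative drift tolerance (the heavy
derivative's CCS shift is negligible). Pairing is greedy by ascending mass
error with deterministic tie-breaks. `relative_ratio()` divides each raw
heavy/light ratio by the internal-standard pair's raw ratio, which cancels
any global heavy-channel gain exactly; the orientation (heavy/light =
treated/control) is stated in the report. Pairing is MS1-based; fragment
confirmation can be layered on by filtering the mixed set per channel first.

## Synthetic data: what it emulates, and what it does not

`simulate_samples()` produces replicate feature sets with complete ground
truth: planted analytes get m/z from the derivatization arithmetic, RT and
CCS from the library or an ad-hoc panel, drift times synthesized through the
library-fitted single-field calibration, log-normal intensities, and spectra
containing the diagnostic pair, a quantifier fragment and Poisson-count
(mean 15) uniform background peaks in [150 Da, precursor − 10 Da]. Decoys
lack diagnostic ions and keep ≥ 0.05 Da away from planted precursors. Jitter
defaults: 5 ppm m/z, 0.05 min RT, 0.05 ms drift, 0.02 Da fragments.

Two generator conventions keep the planted truth unambiguous:

- **Bounded within-run jitter.** Each error is a shared analyte-level offset
  plus a per-sample deviation bounded at half the corresponding matching
  tolerance. The shared offset emulates systematic calibration error
  reproduced across runs; only the bounded scatter separates replicates. The
  total error SD still equals the configured value (verified empirically in
  the tests), while anchor-member deltas can never exceed the matching
  tolerance — with unbounded 5 ppm errors, replicate precursor deltas would
  exceed the 10 ppm tolerance about 15 % of the time and no generator
  setting could honestly promise complete recovery.
- **Shared fragment sets.** An analyte's background fragments are drawn once
  per analyte and jittered per sample, reflecting that all-ion fragmentation
  spectra of the same compound are reproducible across runs. Per-sample
  contaminant peaks are available (`unique_background_mean`) but default to
  0; independent per-sample backgrounds would push the top-25 overlap of
  true replicates below the 0.8 threshold by construction.

What passing synthetic tests shows: the filtering, matching, calibration and
ratio arithmetic are correct, deterministic and tolerant to the configured
noise. What it does not show: robustness to chromatographic peak-shape
artifacts, isotopologue envelope overlap, co-eluting isobars sharing
fragments, ion suppression, or vendor alignment failures — none of which the
generator models. The real-data feature funnel (thousands of raw features →
roughly a third with diagnostic ions → a few hundred consensus features) is
emulated only structurally, with 285 planted acids and 500 decoys per sample
in the acceptance-scale runs; property tests use 4–50 analytes to keep the
suite fast.

## Numerical choices and degenerate inputs

- Ties everywhere break deterministically (intensity ties by *m/z*, candidate
  ties by precursor error then feature id, pairing ties by mass error then
  id), so identical inputs and seeds give byte-identical outputs.
- Empty spectra yield overlap 0 with a warning; features without spectra are
  counted, not fatal. Empty feature sets round-trip as header-only files.
- Inclusive comparisons are used at every published threshold (≥ 100 counts,
  ≥ 0.80 overlap, ≤ 2.5 Å², ≤ 0.2 min), and range flags in quantification use
  a 10⁻⁹ relative epsilon so boundary responses are not spuriously flagged.
- The generator's truncated normals are drawn by inverse-CDF, so a zero SD
  yields exact zeros and seeds reproduce bit-identically.

## Known limitations

- Raw-data processing (peak picking, IM demultiplexing, feature alignment) is
  out of scope; the package starts from exported feature tables and MGF
  spectra.
- Quantifier fragments are empirical library values; no fragment prediction.
- The isotope-pair module handles two channels only and does not deconvolve
  overlapping light/heavy isotope envelopes.
- Stepped-field CCS determination, drift-gas mixtures and
  temperature/pressure corrections are not modeled; the single-field
  constants absorb them to the extent the reference data allow.
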