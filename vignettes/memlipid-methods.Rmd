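---
title: "memlipid: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memlipid: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlipid)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generators emulate, and the numerical choices made where the underlying
methodology left the design open.

# Shotgun lipid annotation and quantification

## Species chemistry

A lipid species is described at *sum level* (`PC 34:1`: total acyl carbons :
total double bonds) or *sn-resolved* (`PC 16:0/18:1`, sn-1 written first).
Sphingolipids carry a third index for total hydroxyls (`Cer 44:0:3`). The
elemental composition of a glycerolipid is assembled as

    head-group core  +  Σ fatty acids (CnH2n−2dO2)  −  one H2O per ester bond

where the per-class core formulas (glycerophosphocholine for PC, and so on)
are hard-coded in `lipid_classes()` / the internal head-group table, because
published methodology states only that m/z values were matched to "elemental
composition constraints" without listing formulas. The table is validated two
ways in the test suite: frozen manual-assembly examples (PC 34:1 =
C42H82NO8P at 759.5778 Da; PI 28:0 = C37H71O13P) and a brute-force
atomic-summation oracle with an independently typed mass table, applied to
500 random database entries at 1e-4 Da.

Ceramides use the closed formula C_n H_{2n+1−2d} N O_{h+1}; IPC adds an
inositol-phosphate (C6H11O8P) and MIPC additionally a hexose (C6H10O5).

## Matching and quantification

* `tol_ppm` (default **3 ppm**, inclusive boundary): the annotation mass
  tolerance. All candidates within tolerance are reported; isobaric
  ambiguity is flagged and peak intensity is split equally among candidates
  unless MS2 evidence resolves them.
* Adducts (configurable per class): [M+H]+ for PC/LPC, [M+NH4]+ for
  DG/TG/EE (ammonium chloride additive in positive mode), [M−H]− for all
  negative-mode classes (DMF additive). Singly charged ions only.
* Quantification is single-point against one spiked class standard:
  `amount = intensity / intensity(standard) × spiked pmol`, i.e. response
  factors are assumed 1. `mol_percent_polar` normalizes over
  GPL + sphingolipid species; DG/TG/EE are storage lipids and excluded from
  the denominator.

Known limitations: no type-II isotope correction (overlap of the M+2 peak of
a more-saturated isobar), no response-factor calibration, and no
sphingolipid fragmentation rules.

# sn-regiochemistry and acyl asymmetry

Diacyl GPLs fragment in negative mode by losing either the free acid
([M−H−RCOOH]⁻) or the ketene ([M−H−R'CH=C=O]⁻) of each chain; both losses
are more abundant from the sn-2 position (the *intensity rule*).
`assign_sn_positions` enumerates the chain decompositions consistent with a
candidate sum composition (candidate chains default to C8–C26, 0–3 double
bonds), sums acid + ketene intensities per chain, selects the decomposition
with the most matched intensity, and places the higher-loss chain at sn-2.

* `min_ratio` (default **7**): the sn-2/sn-1 ratio at or above which the
  call is `assigned` rather than `ambiguous`. The default is the empirical
  floor reported for diacyl GPL spectra; it is exposed because the rule
  itself is qualitative ("more abundant"). The boundary is inclusive.
* The two loss channels are summed per chain. Whether the original analysis
  summed or took the maximum is unknown; the sum is used because it is what
  the spectrum generator plants and the ratio is channel-independent either
  way.
* Species with identical chains are reported `assigned` regardless of the
  ratio — regiochemistry is trivial for them.

`pla2_digest` implements the complementary biochemical check: PLA2
hydrolyses the sn-2 ester, so the post-digest lipid-bound fatty-acid profile
contains only sn-1 chains (a C10:0 chain esterified exclusively at sn-2
vanishes from it). Mass conservation (parent + water = lyso + acid) is an
invariant of the test suite.

`asymmetry_metrics` calls a species asymmetrical when its chains differ by
at least `threshold = 6` carbons, covering the 6–8 carbon range of the
short-chain species of interest (e.g. 18:0/10:0 differs by 8). Sum-level
species can be promoted with an explicit `sn2_carbons` assumption, which is
how a class-wide PLA2 result is applied to species without MS2 coverage.

# GUV flicker spectroscopy

## Model

A quasi-spherical vesicle of mean radius R fluctuates thermally; the
equatorial contour's normalized radial deviation u(φ) = (r(φ) − r̄)/r̄ has
Fourier mode variances

$$\langle|u_q|^2\rangle \;=\; \frac{k_BT}{\kappa} \sum_{l=q}^{l_{\max}}
\frac{2l+1}{4\pi}\,\frac{(l-q)!}{(l+q)!}\,[P_l^q(0)]^2\,
\frac{1}{(l-1)(l+2)\,[\,l(l+1)+\bar\sigma\,]}$$

with κ the bending rigidity (in k_BT), σ̄ = σR²/κ the reduced tension, and
P_l^q the associated Legendre function (only l + q even contributes at the
equator). Modes q = 0, 1 are dilation/translation and excluded. The sum is
evaluated in log-Gamma space for stability; the high-q tail falls as q⁻³,
which the tests verify numerically as an independent check of the
implementation.

## Parameters and numerics

* Fit range `q_min = 6`, `q_max = 20`: low modes are tension- and
  shape-sensitive and high modes noise-limited; the default range matches
  the established protocol and is configurable.
* `l_max = 100`: truncation of the Legendre sum; `helfrich_truncation_check`
  doubles `l_max` until all mode variances change by < 0.1%.
* Fitting: weighted least squares (weights 1/SE² from per-mode standard
  errors) via Levenberg–Marquardt, parameterized in log κ (positivity, and a
  delta-method standard error on κ). κ is initialized from the
  tension-insensitive scaling of the measured spectrum at σ̄ = 0. A negative
  fitted σ̄ triggers a warning and a clamped refit at σ̄ = 0.
* Contour processing: the vesicle centre is the polygon area centroid
  (falling back to the vertex mean for degenerate areas); r(φ) is linearly
  interpolated at 512 uniform angles with periodic wrap-around; the mode
  power is (A_q² + B_q²)/2 so its expectation equals the model variance. A
  contour is rejected as non-star-shaped unless it winds exactly once about
  the centroid with monotone polar angle (backward steps > 0.05 rad reject;
  smaller ones are tolerated as digitisation noise).
* An optional constant `noise_floor` can be subtracted from the averaged
  spectrum (camera noise); none is applied by default.

`gp_map` computes the generalized polarization
GP = (I_ord − I_dis)/(I_ord + I_dis) per pixel (bounded in [−1, 1],
zero-denominator pixels masked), with region means over user masks.
`phase_area_ratio` segments a closed equatorial intensity profile with a
two-class variance-minimizing (Otsu) threshold — chosen because the source
protocol states only "areas of distinct intensities" — and reports the
bright/dim arc-length ratio; profiles whose two class means differ by less
than `min_contrast = 0.1` (Michelson) are flagged single-phase.

# ¹³C isotopologue correction

The correction matrix entry [i, j] is the probability of observing mass
shift i given j tracer-labeled skeleton carbons, with the remaining
`n_total − j` carbons (including `derivatization_carbons`, e.g. the FAME
methyl, which can carry natural ¹³C but never tracer) binomial at
`p_natural = 0.0107`. The matrix is truncated at M+n, so columns sum to
≤ 1. `correct_mid` solves the linear system by **non-negative least
squares** (robust to counting noise, unlike direct inversion) and
renormalizes; `fraction_labeled` reports 100 × (1 − M+0). Only carbon is
corrected; O/H/Si isotopes of the derivatized analyte are a documented
limitation relative to full multi-element GC-MS correction.

# Comparative transmembrane helices

`predict_tmh_hydropathy` is a deliberate stand-in for external profile-HMM
predictors so the pipeline runs on synthetic proteomes: Kyte–Doolittle
window means (window 19, threshold 1.6) assigned to window centres, runs
merged across gaps < 3 residues. Segment boundaries are therefore
conservative — sharp hydrophobic blocks are reported up to ~(window−1)/2
shorter than planted — which cancels in between-species comparisons and is
stated here so absolute lengths are not over-interpreted. Real analyses can
substitute external predictions through the TSV annotation interface.

* `filter_by_median`: the median helix length m is computed over the
  **pooled** segment set (per-species medians are not separable in the
  published protocol, and the pooled median reproduces its single stated
  value); the discard cutoff is the smallest integer ≥ `median_fraction × m`
  (0.5 × 23 → 12) and the discard boundary is inclusive (deviation ≥ cutoff
  is removed). Filtering an already-filtered set at the same median is a
  no-op (test invariant).
* `single_span_orthologs` keys on the reference-species member (exactly one
  kept helix); members without annotations are treated as zero-helix with a
  warning.
* `length_comparison`: two-sided Wilcoxon rank-sum; exact null for combined
  n ≤ 25 without ties, otherwise the tie-corrected normal approximation
  *without* continuity correction — on heavily tied integer lengths the
  corrected statistic is conservative, and the plain z test keeps the type-I
  error at its nominal level (checked against a 1,000-run null simulation
  in the acceptance suite, and against full enumeration for all small
  tie-free configurations).
* `residue_class_composition` classes default to small non-polar
  {G, A, S, C, P}, large non-polar {V, L, I, M, F, W, Y}, polar
  {N, Q, T, H}, charged {D, E, K, R}; the table is an argument because the
  source analysis never defines its classes.

# Synthetic data: what is and is not emulated

All generators are deterministic under a fixed seed and return ground truth
next to the data.

* `gen_lipidome`: peaks at exact adduct m/z with log-normal intensity noise
  (`intensity_cv`) and Gaussian m/z jitter (`ppm_jitter`), plus the
  class-standard peaks (deuterated d31-16:0/18:1 species for diacyl GPLs,
  odd/defined species otherwise, at the conventional spike amounts: 71 pmol
  PC, 50 PE, 43 PI, 24 PS, 5 PA, 1 PG, 1 CL, 4 Cer, 7 DG, 5 TG). The default
  palette is a short-chain-rich yeast lipidome: per-class asymmetric
  fractions PC 0.55, PE 0.45, **PI 0.90**, PS 0.35 split between 16:0/10:0
  and 18:0/10:0, the remainder in conventional 34:x/36:x species; class
  weights PC 0.36, PE 0.22, PI 0.25, PS 0.08 with minor PA/PG/CL/Cer and
  storage DG/TG. Log-normal intensity noise and Gaussian ppm jitter are
  conventional defaults — the source describes no noise model. Not emulated:
  isotope envelopes, chemical noise, in-source fragmentation, chromatographic
  effects; passing round-trip tests therefore shows correctness of the
  annotation/quantification arithmetic under the stated noise, not robustness
  to real matrix effects. A run whose class standard is jittered outside the
  3-ppm window fails quantification QC with an error, mirroring instrument
  practice where a lost standard voids the run.
* `gen_ms2`: diagnostic fragments at exact m/z, sn-2 losses `sn2_factor` ×
  sn-1 losses before noise. No isobaric fragment interference.
* `gen_guv_contours`: per frame, independent complex Gaussian mode
  coefficients with the model variances (quasi-static approximation —
  temporal correlation between frames is not simulated, matching the
  assumption that analysed contours are independent), defaults R = 15 µm,
  4,000 frames, 512 points. Optional radial pixel noise.
* `gen_mids`: binomial mixture of tracer-labeled (purity 0.99) and unlabeled
  molecules, multinomial counting at depth 1e5, truncated at M+n.
* `gen_ortholog_proteomes`: strictly hydrophilic backgrounds with planted
  hydrophobic helices; species-specific length distributions (baseline mean
  27 aa, SD 3, *japonicus* shifted −4 aa by default), optional helix dropout
  and per-species helix residue weights. Background weights are chosen so
  the stand-in predictor finds exactly the planted helices; real proteomes
  have soft hydropathy boundaries the generator does not model.

# Problem sizes

The test and acceptance runs use the study-scale conditions where they are
cheap (4,000 contours per rigidity fit across the 3 × 3 (κ, σ̄) grid; 1e5
ion counts per isotopologue vector; 200 ortholog groups; 1,000 null
simulations for the Wilcoxon calibration) and a ~4,200-entry species
database (all 17 classes, C 24–72, DB 0–4) for annotation.
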