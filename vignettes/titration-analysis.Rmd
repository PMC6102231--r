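---
title: "Methods: per-residue HSQC titration analysis and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue HSQC titration analysis and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the statistics computed per residue, the binding models,
the synthetic-data generator, and the numerical and design choices
made where more than one defensible option existed.

## Setting

The analysis targets protein-observed ¹H–¹⁵N HSQC titrations of an
intrinsically disordered protein — the motivating system is a
140-residue chain with the classic three-segment architecture
(amphipathic N-terminal region, residues 1–60; aggregation-prone NAC
region, 61–95; acidic C-terminal region, 96–140) — against a
small-molecule ligand added at 10–1000 µM over a 20 µM protein
background. Assignment transfer is assumed done upstream: peaks are
matched across conditions by residue index only, never by proximity in
shift space. Prolines and unassigned residues are absent rows, never
zero-filled.

## Per-residue statistics

**Chemical shift perturbation.** For a residue assigned in both the
apo reference and a ligand condition,

$$\Delta\delta_{NH} \;=\; \sqrt{\frac{(\Delta\delta H)^2 +
(\Delta\delta N)^2/s}{2}},$$

with the nitrogen scaling factor $s = 25$ by default
(`compute_csp(..., scale_n = )`). The factor compensates the roughly
five-fold wider dispersion of amide ¹⁵N shifts; because both
differences enter squared, the statistic is symmetric in the order of
the two spectra. Signed $\Delta\delta H$ and $\Delta\delta N$
(condition minus reference) are retained alongside.

**Intensity attenuation.** Per residue,
$|\,(I^\circ - I^L)/I^\circ\,| \times 100$, where $I^\circ$ is the apo
intensity. The absolute value is part of the definition: exchange and
relaxation effects can transiently raise an intensity, and the
statistic measures the magnitude of change. Residues with $I^\circ=0$
are excluded and reported. Intensities are used as raw heights; no
internal-standard normalization is applied by default because the
per-residue ratio is already self-normalizing within a residue.

**Significance thresholds.** Two lines must both be exceeded
(strictly) for a residue to count as significant:

* the *black line*: mean + 1 SD of the statistic over residues whose
  peaks are still observable (`status == "ok"`). Broadened residues
  are a disjoint categorical outcome and are never folded into this
  mean — including them (as zeros or otherwise) would deflate the
  threshold exactly when broadening is strongest.
* the *orange line*: the maximum of the same statistic computed
  between every pair of apo spectra when replicate apo lists exist
  (`replicate_variability()`), i.e. an empirical ceiling on what
  sample-to-sample variability alone can produce. Without replicates a
  configured floor stands in: 0.005 ppm for CSP and 10% for intensity.
  The floors are deliberately conservative round numbers of the order
  of digital resolution (CSP) and typical peak-height scatter between
  repeated HSQCs of the same construct (intensity); both are exposed
  as `orange_floor_csp` / `orange_floor_intensity`. The replicate
  maximum is computed globally rather than per residue: with the small
  number of apo replicates typically available, a per-residue maximum
  is too noisy to be a stable ceiling (a per-residue variant can be
  assembled from `replicate_variability()` output if desired).

**Broadened beyond detection.** A residue observable in the reference
is `broadened` in a condition when its peak is missing there or its
intensity falls below `noise_floor`. No numeric criterion beyond
"missing" is universal, so the floor defaults to 0 (missing-only) in
the low-level function, and the conventional choice is
$3\sigma_{\text{noise}}$ with a user-supplied noise estimate. Counts
are tallied per region; tallies always sum to the total broadened
count. Residues appearing only in the condition are flagged
`absent_in_reference` and take no part in thresholds or tallies.

**Line widths.** $\Delta LW$ = LW(condition) − LW(reference) in Hz,
positive for broadening. The dead band around zero defaults to 0 Hz
(raw differences are reported; classification into
narrowing/unchanged/broadening honours `dead_band` when set).
N-terminal narrowing upon C-terminal binding or truncation is the
signature of released long-range contacts between the chain termini;
C-terminal broadening reports the binding event itself.

**WaterLOGSY.** Ratios are intensity-with-protein over
intensity-without per matched 1D signal; unmatched signals and
non-positive denominators are excluded and reported.

## Binding models

**Kd from C-terminal intensities.** The response at each ligand
concentration is the mean apo C-terminal intensity minus the mean
condition C-terminal intensity (a non-negative, saturating attenuation
measure; the sign convention makes the saturation model directly
applicable). Broadened residues contribute zero intensity in the
condition — they are maximally attenuated observations, and dropping
them instead would bias the response toward zero exactly at high
ligand (an exclusion variant is available via
`broadened_zero = FALSE`). The curve is fitted with
$y(L) = B_{max} L/(K_d+L)$ by *unweighted* least squares on the
per-concentration means; the per-concentration SEMs are carried for
reporting, and inverse-variance weighting is available behind
`weighted = TRUE`. Whenever any broadened residue contributed, the fit
carries a `lower_limit` flag: zero-substitution and cooperativity both
push the apparent midpoint up, so the Kd bounds the affinity from
below rather than estimating it.

**Cooperativity.** Reporter residues' ¹⁵N shifts (ppm, as recorded;
an analysis in Hz would only rescale the amplitude) are fitted with

$$\delta(L) = \delta_0 + \Delta\delta_{max}\,
\frac{L^{\,n}}{K^{\,n} + L^{\,n}},$$

independently per residue, and the exponents are combined by a plain
arithmetic mean (`average_hill()`); an inverse-variance weighted mean
was considered and rejected because with two reporter residues the
per-fit variance estimates are themselves too unstable to serve as
weights. `run_pipeline()` picks reporters automatically: the
C-terminal residues with the largest CSP at the top of the titration
that remain observable at every point (the apo point at $L=0$ is
included in the fit, since $\delta(0)=\delta_0$ is a measured
quantity).

## Numerical choices

* Optimizer: bounded Levenberg–Marquardt (`minpack.lm::nlsLM`),
  `ftol = ptol = 1e-8`, at most 10,000 function evaluations.
* Initialization: $K_d$/$K$ at the median concentration,
  $B_{max}$/$\Delta\delta_{max}$ at the observed range, $\delta_0$ at
  the minimum shift, $n = 1$. Bounds: all structural parameters
  non-negative, $n \in [0.1, 20]$.
* Restarts: up to 20 jittered restarts (each start parameter rescaled
  by a uniform factor in $[0.2, 5]$, clamped to the bounds), applied
  *only while the optimizer fails*. A best-of-many-starts global
  search is deliberately not used: with few concentrations the Hill
  least-squares surface develops a nearly flat shelf at very large
  $n$ (step-like curves fit marginally better), and a global-minimum
  policy chases that shelf, returning boundary estimates with huge
  standard errors. Path-following from the standard start stays in
  the well-determined basin and is what the reported estimates mean.
* A fit that never converges is returned flagged
  (`converged = FALSE`), never thrown; `average_hill()` refuses
  flagged fits explicitly.
* Degenerate inputs are hard errors with named offenders: all-equal
  responses, fewer than 3 (saturation) or 4 (Hill) concentrations,
  empty residue overlap, fewer than 2 observable residues for
  thresholds.
* JSON output is serialized at 9 significant digits so that reruns
  with identical inputs and seed are byte-identical.

## The synthetic-data generator

`simulate_titration()` emulates the study conditions the analysis
assumes, so every stage is testable without instrument data. Its
defaults *are* those conditions and are not tuning knobs: 140
residues, 20 µM protein, ligand at
$\{10, 20, 40, 100, 200, 400, 600, 1000\}$ µM, occupancy midpoint
292 µM, Hill exponent 5.

Occupancy is phenomenological, $f(L)=L^n/(K^n+L^n)$ — a deliberate
simplification of an explicit multi-ligand sequential binding scheme,
matching what the analysis estimates rather than a mechanism the data
cannot resolve. Each residue draws a susceptibility
$g_r \sim U(0.5, 1]$ once per simulation; regional scales are 1
(C-terminal), 0.3 (NAC) and 0.15 (N-terminal) — the two smaller values
are qualitative placeholders (the source observations are only ordinal:
C-terminus first and strongest, NAC intermediate, N-terminus weakest)
and are exposed as `nac_scale` / `nterm_scale`. The noiseless
condition then has combined CSP $= 0.03\,f g_r s_r$ ppm (split 1:5
between ¹H and ¹⁵N so the combined value is exact), intensity
$I^\circ(1 - f g_r s_r)$, N-terminal line widths reduced by
$5 f$ Hz and C-terminal line widths increased by $8 f g_r$ Hz
(`cterm_lw_broadening`; the C-terminal broadening term accompanies the
narrowing term so the line-width stage sees the
narrowing-at-N/broadening-at-C pattern it is built to classify). A
peak whose noiseless attenuation exceeds `broadening_cutoff` (default
0.85) is deleted — broadened beyond detection; because the decision
uses the noiseless attenuation and $f$ is increasing, deletions are
nested across concentrations. Finally additive Gaussian noise is
applied: SD 0.001 ppm on ¹H shifts (0.005 ppm on ¹⁵N), 5% of the
reference intensity on intensities (clamped at zero). The amplitude
choices (0.03 ppm CSP at saturation, full attenuation, ~20 Hz baseline
line widths with single-digit Hz modulation) are realistic magnitudes
for a weak-binding disordered system at these field strengths.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: peak overlap and mis-assignment,
$J$-coupling and temperature drifts between spectra, correlated
(non-independent) noise across residues, exchange-regime line shapes
(attenuation and broadening are imposed directly rather than derived
from exchange rates), ligand micellization above its critical micelle
concentration, and protein aggregation over the titration time course.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic
data at the scale of the study design: 140-residue peak lists, 8-point
titrations, 100-replicate recovery simulations for the saturation
estimator, two reporter-residue fits for the cooperativity estimate,
and 1,000 randomized ≤ 10-residue fixtures for the invariant checks
(CSP symmetry, threshold consistency, tally conservation) with a
brute-force spreadsheet-style oracle agreeing to $10^{-9}$ on a
subset. These sizes were chosen as the natural scale of the design.

## Known limitations

* The Kd estimator inherits every caveat of intensity-based affinity
  estimation on a cooperative system: it is reported, and should be
  read, as a lower limit whenever broadening contributed.
* With an 8-point design and a steep transition, the Hill exponent of
  a *single* residue is a high-variance estimate (few points sit on
  the transition); averaging reporter residues helps but does not
  remove this. The per-fit standard errors are reported for exactly
  this reason.
* Peak matching by residue index presumes correct assignment transfer;
  there is no shift-space tracking safeguard.
* The orange-line floors used without apo replicates are conventions,
  not measurements; supply replicate apo lists whenever available.
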