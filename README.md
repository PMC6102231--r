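# nmrtitr

Per-residue analysis of protein-observed ¹H–¹⁵N HSQC titrations of
intrinsically disordered proteins against small-molecule ligands, built
around the case of a cationic glycosphingolipid binding the acidic
C-terminus of a 140-residue disordered protein (α-synuclein-like
architecture: N-terminal region 1–60, NAC region 61–95, C-terminal
region 96–140).

Protein-observed titrations of disordered proteins rarely yield clean
two-state shift trajectories: weak, cooperative binding shows up as a
mixture of small chemical shift perturbations, progressive intensity
attenuation, and signals broadened beyond detection. This package
implements the corresponding analysis stages as composable,
tibble-in/tibble-out functions:

- **Chemical shift perturbation (CSP).** For each residue assigned in
  both the apo and the ligand spectrum,

  Δδ_NH = sqrt( ( (ΔδH)² + (ΔδN)²/25 ) / 2 ),

  with 25 the conventional scaling factor that brings ¹⁵N shift changes
  onto the proton scale (`compute_csp()`, `scale_n` configurable).
- **Intensity attenuation.** |(I° − I_L)/I°| × 100 per residue
  (`compute_intensity_change()`).
- **Significance thresholds.** A residue responds significantly when
  its statistic exceeds both the mean-plus-one-SD "black line" over
  observable residues and the "orange line" of spectral variability
  between replicate apo samples (maximum apo-to-apo statistic, or a
  configured floor when replicates are unavailable)
  (`compute_thresholds()`, `replicate_variability()`).
- **Broadening beyond detection.** A peak present in the apo spectrum
  but missing — or below a 3σ-style detection floor — with ligand is
  classed broadened; counts are tallied per region
  (`classify_broadened()`, `tally_broadened()`).
- **Line-width differences.** ΔLW = LW(condition) − LW(reference) in
  Hz, classifying narrowing (increased local mobility, e.g. release of
  long-range N-/C-terminal contacts) versus broadening (binding or
  intermediate exchange) (`compute_linewidth_diff()`).
- **Kd estimation.** The mean C-terminal intensity difference versus
  ligand concentration is fitted with the single-site saturation model
  y(L) = Bmax·L/(Kd + L) by bounded nonlinear least squares
  (`cterm_intensity_response()`, `fit_saturation()`). When broadened
  residues contributed (counted as fully attenuated), the fit is
  flagged: the Kd is then a lower limit.
- **Cooperativity.** Per-residue ¹⁵N shift titrations are fitted with
  the Hill model δ(L) = δ0 + Δδmax·Lⁿ/(Kⁿ + Lⁿ) and the exponents of
  the reporter residues are averaged (`fit_hill()`, `average_hill()`);
  n > 1 indicates several ligand copies binding one chain.
- **WaterLOGSY ratios.** Ligand-observed 1D intensities with/without
  protein (`waterlogsy_ratio()`).
- **Synthetic data.** `sim_config()` + `simulate_titration()` generate
  a full titration series (8-point, 10–1000 µM ligand against 20 µM
  protein by default) with cooperative, C-terminus-localized
  perturbation and broadening, N-terminal line narrowing, and Gaussian
  noise — so the entire pipeline is testable without instrument data.

Fitted objects support `tidy()`, `glance()`, `coef()`, `predict()` and
`autoplot()`; per-residue results plot with `plot_perturbation()` and
`plot_linewidth()`; `run_pipeline()` ties everything together and
writes per-residue TSVs plus a versioned JSON summary. A thin CLI lives
at `inst/scripts/nmr-titration.R`.

## Worked example

```r
library(nmrtitr)

cfg    <- sim_config(seed = 42)      # defaults: Kd 292 uM, Hill n 5
series <- simulate_titration(cfg)
series
#> <titration_series> 8 condition(s) at 10, 20, 40, 100, 200, 400, 600, 1000 uM ligand, 0 replicate apo list(s)

prof <- perturbation_profile(series$reference, series$conditions[[8]])
attr(prof, "broadened_tally")
#> # A tibble: 3 x 2
#>   region     n_broadened
#> 1 N-terminal           0
#> 2 NAC                  0
#> 3 C-terminal          16
attr(prof, "thresholds")$csp
#> $black_line  0.0149   # ppm, mean + 1 SD over observable residues
#> $orange_line 0.005    # ppm, replicate-variability floor

resp <- cterm_intensity_response(series)
resp
#> # A tibble: 8 x 5   (response = mean apo minus mean ligand C-terminal intensity)
#>   ligand_conc response     sem n_residues n_broadened
#> 1          10  0.0107  0.00686         45           0
#> ...
#> 8        1000  0.767   0.0276          45          16

fit_saturation(resp)
#> <binding_fit: saturation_single_site>
#>   bmax          1.93508  (se 1.391)
#>   kd            1254.08  (se 1389)
#>   note: broadened residues contributed zero intensities;
#>   the dissociation constant is a lower limit.
```

Reading the output: at the top of the titration all broadened signals
sit in the C-terminal region, and 29 C-terminal residues clear both CSP
significance lines — the binding site maps to the C-terminus. The
saturation Kd fitted to this cooperative series is large and has a
large standard error: a single-site hyperbola laid over a sigmoidal
response can only bound the affinity from below, which is exactly why
the fit carries the lower-limit flag. The cooperativity itself is
estimated from the reporter-residue Hill fits
(`run_pipeline()` selects the strongest-shifting C-terminal residues
and reports their averaged exponent).

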