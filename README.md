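# nucshuttle

Quantitative analysis of nucleocytoplasmic shuttling kinetics from
photobleaching experiments, for cell biologists studying transcriptional
regulators (such as YAP1) whose localization is set by the balance of
nuclear import, export and chromatin binding.

Steady-state images cannot distinguish faster import from slower export
from tighter chromatin binding. Photobleaching can:

* **FRAP** (fluorescence recovery after photobleaching) — bleach a spot
  once and watch it refill. When diffusion is fast relative to the frame
  rate, the recovery reports the dissociation rate `km1` from the
  chromatin-bound state (mean residence time = `1/km1`).
* **FLIP** (fluorescence loss in photobleaching) — bleach one nuclear spot
  repeatedly and watch the whole cell drain. The spatio-temporal loss
  pattern reports import `km2`, export `k2` and association `k1`.

## What the package implements

* Postbleach-profile analysis: the radial median profile is fitted with
  `exp(-K exp(-2 r^2 / r_e^2))` for bleach depth `K` and effective radius
  `r_e`; the recovery curve's first point is inverted for its own bleach
  depth through the disc-average or Gaussian-detection (incomplete-gamma)
  relation (`radial_median_profile`, `fit_profile`,
  `bleach_depth_from_curve`).
* Four recovery models — series diffusion, numerical axisymmetric
  reaction–diffusion, single and double exponential reaction
  `sum_i A_i (1 - exp(-k_off_i (t - t0)))` — fitted under a time-weighted
  SSE that up-weights early frames, screened by plausibility bounds
  (diffusion ≤ 60 µm²/s, rates ≤ 25 s⁻¹, dissociation ≥ 0.01 s⁻¹), and
  compared by Akaike weights plus a nested F-test between the reaction
  models (`fit_frap_curve`, `select_model`, `summarize_cohort`).
* A compartmentalized reaction–diffusion model of FLIP on a coarse grid
  matched to the bleach ROI: diffusion within nucleus and cytoplasm,
  chromatin binding in the nucleus, import/export as flux boundary
  conditions, a bleach sink on the schedule of the acquisition. The linear
  system is propagated exactly by matrix exponentials and fitted to
  gridded movies under equal-thirds spatial weighting
  (`discretize`, `solve_flip_forward`, `build_weights`, `fit_flip`,
  `sensitivity_sweep`).
* Steady-state distribution calculus and in-silico rate swapping
  (`distribution_from_rates`, `substitute_rates`), cell tracking on label
  movies with morphology and N/C-ratio readouts (`track_cells`,
  `morphology`), normalized auto/cross-correlation analysis
  (`correlate_tracks`, `pearson_matrix`), and the validation checks:
  the zero-import/export assumption quantification
  (`zero_transport_check`) and residual reports (`frap_residuals`,
  `flip_residuals`).
* Forward simulators for every input type — postbleach frames, recovery
  curves under each model, FLIP movies from the compartment model, label
  movies with ground-truth tracks (`simulate_postbleach_profile`,
  `simulate_frap_curve`, `simulate_flip_movie`,
  `simulate_tracking_movie`) — so the whole pipeline is testable by
  parameter recovery.

See the methods vignette (`vignettes/nucshuttle-methods.Rmd`) for the
models, conventions and numerical choices in full.

## Worked example

Simulate a noisy nuclear FRAP curve at the activated-fibroblast
dissociation median (0.39 s⁻¹), fit all four models and select among them;
then simulate a FLIP movie at the activated-fibroblast medians and recover
the rates:

```r
library(nucshuttle)

truth <- ground_truth(model_id = "single_reaction", km1 = 0.39, K = 1,
                      r_e = 1.8, noise_sd = 0.02, seed = 42)
curve <- simulate_frap_curve(truth)
sel <- fit_frap_curve(curve, r_e = 1.8, r_n = 0.995)
sel$selected
#> [1] "single_reaction"
sel$fits[[sel$selected]]
#> FitResult [single_reaction] wSSE=0.0002884 AIC=-4163 w=0.881
#>   A1 = 0.51417
#>   k_off1 = 0.38284 1/s
#>   t0 = 0.03605 s

g <- make_geometry(geometry_spec(), seed = 2)
m <- simulate_flip_movie(ground_truth(k1 = 0.235, km1 = 0.40, k2 = 0.018,
                                      km2 = 0.017, eta = 1.5, C0 = 1,
                                      D = 19, noise_sd = 0.02, seed = 7), g)
fit <- fit_flip(m, g, fixed = list(D = 19, km1 = 0.40))
fit$fit
#> FitResult [flip_pde] wSSE=1.406e-07 AIC=NA w=NA
#>   k1 =  0.23480 1/s
#>   k2 =  0.01800 1/s
#>   km2 =  0.01701 1/s
#>   eta =  1.50002 1/s
#>   C0 =  1.00012 a.u.
#>   D = 19.00000 um^2/s
#>   km1 =  0.40000 1/s

distribution_from_rates(0.235, 0.40, fit$fit$parameters[["k2"]],
                        fit$fit$parameters[["km2"]])
#> Distribution: cytoplasmic 40.0%, nuclear mobile 37.8%, nuclear bound 22.2%
#>   (nuclear total 60.0%) [CAF-like]
```

The FRAP selection recovers the single-reaction model with the generating
rate (0.383 vs 0.39 s⁻¹ under 2% noise); the FLIP fit recovers all five
free parameters from a single noisy movie; and the recovered rates imply
an activated-fibroblast-like steady state (~60% nuclear, ~22%
chromatin-bound). `rate_set()` / `yap_rates()` provide the published
median rates per condition for swaps and comparisons.

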