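---
title: "Models and methods: photobleaching kinetics of nucleocytoplasmic shuttling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: photobleaching kinetics of nucleocytoplasmic shuttling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nucshuttle)
```

# The problem

Transcriptional regulators such as YAP1 shuttle between the nucleus and the
cytoplasm, and inside the nucleus they exchange between a freely diffusing
pool and a chromatin-bound pool (for YAP1, binding is mediated largely by
TEAD transcription factors). Steady-state localization images cannot tell
whether nuclear enrichment comes from faster import, slower export, or
tighter chromatin binding. Photobleaching experiments can: FRAP (bleach a
spot once, watch it recover) reports the release rate from the bound state,
while FLIP (bleach one spot repeatedly, watch the whole cell drain) reports
the exchange between compartments. `nucshuttle` implements the quantitative
machinery for both, together with forward simulators that generate every
input type from known ground truth, so the full pipeline is verifiable end
to end by parameter recovery.

Throughout, rates are written `k1` (pseudo-first-order chromatin
association, i.e. the bimolecular rate times the partner concentration),
`km1` (dissociation; its reciprocal is the mean residence time on
chromatin), `k2` (nuclear export), `km2` (nuclear import), `eta` (bleach
sink), `D` (diffusion), `C0` (initial cytoplasmic concentration).

# FRAP

## Postbleach profile

The first postbleach frame carries a radially symmetric intensity dip that
is well described by an exponential of a Gaussian,

$$C(r, 0) = \exp\left[-K\,e^{-2r^2/r_e^2}\right],$$

with bleach depth $K$ and effective radius $r_e$ (generally larger than the
nominal ROI radius $r_n$ because bleaching spreads during the ~3 s bleach).
`radial_median_profile()` re-centres the frame on the bleach mid-point,
interpolates over the polar angle on a uniform 360-point grid (compensating
the sparse sampling near the centre), takes per-annulus medians inside the
nucleus-minus-nucleoli mask, and `fit_profile()` recovers $(K_{PB}, r_e)$ by
least squares after a coarse grid scan that guards against local minima.
Nucleoli are excluded everywhere: the protein is excluded from them and
their dense packing distorts diffusion.

## Bleach depth from the recovery curve

The first postbleach value $S(0)$ of the normalized recovery curve also
determines a bleach depth, $K_{RC}$, given $\nu_0 = r_e^2/r_n^2$. Two
conventions for the $S(0)$–$K$ relation are implemented
(`frap_s0(method=)`):

* `"disc"` — the exact average of the profile over the nominal disc
  $r \le r_n$. We evaluate it in closed form through exponential integrals,
  $S(0) = \tfrac{\nu_0}{2}\left[E_1(K e^{-2/\nu_0}) - E_1(K)\right]$, which
  we verified against direct numerical quadrature to better than $10^{-10}$.
* `"series"` — $S(0) = \nu_0\,\gamma(\nu_0, K)/K^{\nu_0}$ (lower incomplete
  gamma), equivalently $\sum_m \frac{(-K)^m}{m!}\frac{\nu_0}{\nu_0+m}$.

The two differ by a few percent. The series form is *exactly* the $t = 0$
value of the series diffusion recovery model below; working out the
integrals shows it corresponds to reading the recovery out with a Gaussian
detection weight $\propto e^{-2r^2/r_n^2}$ rather than a hard disc average —
the natural convention for a confocal spot readout. We therefore expose
both: the disc average is the defining relation for the profile itself, and
the series convention is used wherever consistency with the diffusion
recovery model matters (the high-level `fit_frap_curve()` defaults to it).
`bleach_depth_from_curve()` inverts either relation by a bracketed root
search; the relation is strictly decreasing in $S(0)$, so the root is
unique.

## Recovery models

Four candidate models are fitted to the normalized postbleach curve
$S(t)$:

* **Diffusion** (`fit_diffusion()`):
  $Q_D(t) = \sum_m \frac{(-K_{RC})^m}{m!}
  \frac{r_e^2}{r_e^2 + m(8 D_e t + r_n^2)}$, truncated adaptively at a term
  magnitude of $10^{-10}$ (cap 200 terms). One free parameter, $D_e$,
  initial guess 19 µm²/s (interpolated from measured nuclear mobilities of
  GFP multimers of comparable mass).
* **Reaction–diffusion** (`fit_reaction_diffusion()`): free molecules
  diffuse at `D1` and bind at `k_on` to immobile sites; bound molecules are
  stationary (`D2 = 0`, supported by histone FRAP) and release at `k_off`.
  The forward model is solved numerically: an axisymmetric conservative
  finite-volume discretization on a radially stretched grid (fine near the
  bleach centre), integrated with a stiff method-of-lines solver. The
  default domain radius grows with $\sqrt{8 D_1 t_{max}}$ so the zero-flux
  outer boundary never influences the readout; in the `k_on -> 0` limit the
  forward curve matches the series diffusion model to better than 1%, and
  in the fast-diffusion limit it collapses onto the single-reaction model —
  both limits are enforced as tests.
* **Single / double reaction** (`fit_reaction()`):
  $Q_{Rn}(t) = \sum_{i=1}^{n} A_i\left(1 - e^{-k_{off,i}(t - t_0)}\right)$,
  on top of the baseline $f_0$ fixed at the first postbleach sample; $t_0$
  absorbs timing noise in the first frame. Initial guesses come from a
  single-exponential pre-fit seeded from a coarse grid around amplitude 0.3
  and rate 0.5 s⁻¹; for the double reaction the fast rate is seeded from
  the first 30% of the recovery and the slow rate from the final 30%, read
  off the smooth single-reaction fit. Three deterministic jittered restarts
  guard against local minima.

All fits minimize the time-weighted sum of squares
$$\mathrm{SSE} = \int_0^\tau
\frac{(S(\psi)-Q(\psi))^2}{\psi + \int_0^\tau S(\phi)\,d\phi}\,d\psi,$$
evaluated by the trapezoid rule on the frame grid: early times — which carry
the information about fast rates — weigh more, and the integral in the
denominator removes the $t = 0$ singularity.

## Plausibility and model selection

Fits with physically unrealistic parameters are discarded before
comparison: diffusion above 60 µm²/s (at or beyond the mobility of a single
GFP, a quarter the size of the tagged construct), binding rates above
25 s⁻¹ (unresolvable at the 60 ms frame interval), dissociation below
0.01 s⁻¹ (0.001 s⁻¹ in the slow `"tead"` mode), which would reflect
spurious linear trends. Among the surviving fits,
$\mathrm{AIC} = n\ln(\mathrm{SSE}_w/n) + 2(p+1)$ under a least-squares
likelihood, converted to Akaike weights. When the diffusion-containing
models are ruled out, the single and double reaction are additionally
compared by the nested F-test
$F = \frac{(\mathrm{SSE}_1-\mathrm{SSE}_2)/(df_1-df_2)}{\mathrm{SSE}_2/df_2}$;
the double reaction is accepted only if $p \le 0.05$ *and* its Akaike
weight exceeds the single reaction's. Cells on which every model fails are
flagged noisy and enter cohort summaries at the arbitrary placeholder rate
of 3.5 s⁻¹ (`summarize_cohort()` also reports the median over fitted cells
only). A half-time helper is provided for descriptive parity but never used
for inference — half-times conflate diffusion, binding and geometry.

# FLIP

## Model

The cell is modelled as two compartments. In the nucleus, mobile protein
$N_M$ diffuses, binds chromatin partners at `k1` and is released at `km1`;
bound protein $N_I$ is stationary. The cytoplasmic pool $C$ diffuses.
Exchange across the nuclear envelope is a flux boundary condition: export
proportional to `k2` times the nuclear-side mobile concentration, import
proportional to `km2` times the cytoplasmic-side concentration. The
repeatedly bleached spot acts as a sink of rate `eta` on both nuclear
states. Nucleoli and the cell boundary are zero-flux.

## Discretization and solver

Following the acquisition geometry, the frame is divided into square grid
points with the same dimensions as the 8×8 px (≈4.46 µm²) bleach ROI, with
the lattice aligned so one grid point coincides with the bleach region. A
grid point is nuclear or cytoplasmic when at least 50% of it is covered by
the corresponding mask; gridded intensities are means over in-mask pixels
only. The coarse lattice is robust to imperfectly drawn boundaries and
keeps the state dimension small; `discretize(refine=)` halves the spacing
for convergence checks.

Boundary exchange terms are scaled by (shared interface length)/(grid-cell
area) = $1/h$ per full edge. The scaling was chosen because it makes the
total boundary flux independent of the grid spacing, so fitted rates are
grid-convergent — halving the fitting grid moves fitted import/export by a
few percent (enforced as a test).

The discretized system is linear with piecewise-constant coefficients (the
sink switches with the bleach schedule), so each interval is propagated
*exactly* by a matrix exponential; the two propagators (bleach on / off)
are computed once and reused across all 150 frames. This is faster and
more robust than generic stiff integration, which remains available
(`solve_flip_forward(method = "lsoda")`) and agrees to solver tolerance.
With `eta = 0` the area-weighted total is conserved to machine precision.
With the default protocol — 150 frames every 2 s, bleached 2 s between
frames — the sink duty cycle is effectively continuous; the schedule
machinery matters for protocols with a shorter bleach than frame interval.

The prebleach steady state eliminates two initial concentrations:
$N_{M0} = k_{-2} C_0 / k_2$ and $N_{I0} = k_1 N_{M0} / k_{-1}$, leaving
five free parameters `(k1, k2, km2, eta, C0)`. Diffusion is fixed at
19 µm²/s and dissociation at the FRAP cohort median for the cell state
(defaults 0.55 s⁻¹ for normal and 0.40 s⁻¹ for activated fibroblasts).

## Weighting and fitting

The weighted SSE extends the FRAP time weighting over space: each grid
point's weight is normalized by its own integrated signal (so bright and
dim points count equally within a compartment) and the three regions —
bleach point, remainder of the nucleus, cytoplasm — are rescaled to
contribute equal thirds, preventing the large cytoplasm from dominating the
fit. Dark grid points get zero weight. Starting guesses: `C0` from the
median cytoplasmic intensity, `k1` from the FRAP median dissociation,
import/export/decay from a two-compartment ODE pre-fit
(`ode_prefit()`), falling back to defaults (import/export 0.002–0.005 s⁻¹
with the N/C ratio deciding which is larger; `eta` 1.5 s⁻¹) when the
pre-fit fails. Bounds: rates in $[10^{-6}, 50]$ s⁻¹, `C0` below twice the
observed maximum — generous, but excluding the degenerate `k2 = 0` steady
state.

`flip_sse_grid()` exposes the weighted-SSE surface around a fit: the
association/export surface has its global minimum at the fitted point, and
the import/export surface shows the expected shallow near-linear valley
(import and export co-vary along the N/C-ratio constraint; only the full
spatio-temporal data pins the global minimum). `sensitivity_sweep()`
re-fits while sliding the fixed dissociation or diffusion value: varying
dissociation by ±50% moves import and export only marginally, with the
association rate absorbing the change.

# Steady-state distributions

`distribution_from_rates()` converts a rate set into the three-pool
steady-state split (cytoplasmic / nuclear mobile / nuclear bound) using the
same balance relations; fractions are computed from amounts, i.e.
concentration × effective compartment volume, with `volume_ratio`
defaulting to 1 (the convention under which the published fractions are
reproduced; how compartment volumes should enter is not specified by the
source data, so the ratio is exposed as a parameter).
`substitute_rates()` swaps named rates between two conditions — swapping
only the export rate converts a normal-fibroblast-like distribution
(~40% nuclear, ~12% bound) into an activated-fibroblast-like one
(~60% nuclear, ~22% bound) and vice versa, and
`classify_distribution()` labels the result.

```{r steady-state}
nf <- rate_set("NF1_WT")
caf <- rate_set("CAF1_WT")
distribution_from_rates(nf$k1, nf$km1, nf$k2, nf$km2)
substitute_rates(nf, caf, "k2")
```

The association medians for the two conditions are not published as
numbers (only the 0.15–0.5 s⁻¹ range); the packaged defaults (0.25 and
0.235 s⁻¹) are back-calculated so the published steady-state fractions are
reproduced, and they sit inside the published range. They are recorded as
package choices in `yap_rates()` documentation.

# Validation modules

## The zero-transport check

The FRAP fits assume import/export is negligible over the ~15 s recovery.
`zero_transport_check()` quantifies the cost of that assumption: a
no-bleach variant of the FLIP model with rapid diffusion (1000 µm²/s, so
the recovery is purely reactive) simulates the bleach-point recovery on a
typical synthetic cell — uniform nuclear concentration 1 carrying the
postbleach dip (nominal radius 1.232 µm), the uniform mobile pool capped by
the dip minimum (any excess free protein would refill the spot diffusively
rather than reactively), cytoplasm at its steady-state level — once with
transport and once without, and fits the single-reaction model to both
traces. With wild-type median rates the relative difference in the fitted
dissociation rate is below 1%, comfortably inside the 5% bound, and it
grows with the dissociation rate (fast-turnover mutants are the worst
case). The typical-cell inputs the source data do not publish are fixed
here as package defaults: nuclear area 180 µm², eccentricity 0.75,
cytoplasm/nucleus area ratio 1.5, profile averages $K = 1.0$,
$r_e = 1.8$ µm. One published secondary observation — a *smaller* error for
bleach spots near the nuclear boundary — does not reproduce under these
defaults (we find a marginally larger error, by a few hundredths of a
percentage point); the tests assert only the robust claims.

## Residual analysis

`frap_residuals()` / `cohort_median_residuals()` and `flip_residuals()`
report observed-minus-predicted summaries. On well-specified synthetic
data the selected model's residuals carry no time trend (runs test).
Fitting pure diffusion to reaction-type curves that contain a fast
component and a partially immobile pool reproduces the diagnostic
misfit signature: the diffusion model underestimates the short-time
recovery and overestimates the long-time recovery. FLIP residuals are
grouped by bleach point / nucleus / cytoplasm to expose compartment-level
systematic error (none on well-specified data).

# Synthetic data

The simulators define the study conditions and default to the acquisition
protocols: FRAP frames every 60 ms for 18 s after a 2.9 s bleach with three
prebleach frames, circular nuclear ROIs around 3.1–6.9 µm²; FLIP with an
8×8 px square (≈4.4 µm², 0.264 µm/px) bleached 2 s between each of 150
frames taken every 2 s; 128×128 px frames. Noise is additive Gaussian on
normalized intensity with sd 0.02 by default — the acquisition noise
statistics are not published, and this choice (2% of the prebleach level)
is recorded in output metadata. Intensity-dependent (shot) noise,
photophysics and 3-D effects are deliberately out of scope, so passing
recovery tests demonstrate correctness of the estimators under the model's
own assumptions, not robustness to every property of real movies (cell
movement during the 5-minute FLIP acquisition, for instance, is known to
smear compartment boundaries and is not simulated).

Cell geometries are elliptical nuclei with nucleoli discs and a scaled
cytoplasmic shell (`make_geometry()`), deterministic per seed.
`simulate_tracking_movie()` builds label movies with known identities,
touching events, border exits and divisions for exercising the tracker.

Numerical problem sizes used in the shipped tests — e.g. 100-frame FLIP
movies for recovery checks, five replicate seeds for the noise-recovery
property, six curves for the model-selection property — were chosen as the
smallest sizes at which the corresponding statistics are stable; the
acceptance script uses the full 150-frame protocol and 100 FRAP curves.

# Tracking and correlation

`track_cells()` consumes label movies (segmentation of raw fluorescence is
out of scope): per frame it removes sub-threshold objects, splits
cytoplasmic objects overlapping several nuclei by propagation from the
nuclei (covering touching cells and divisions), and drops nucleus-less and
border-touching objects; frames are then joined by pixel overlap with
largest-overlap precedence, and only tracks at least 24 consecutive frames
long (two hours at the 5-minute frame interval) are kept. Morphology uses
the Vossepoel–Smeulders chain-code perimeter, nearly unbiased on discs;
circularity $4\pi A/P^2$ can slightly exceed 1 for round digital shapes
and is deliberately not clipped. `xcorr_norm()`/`correlate_tracks()`
mean-subtract per track and normalize so the autocorrelation is exactly 1
at zero lag; signals of different lengths are linearly interpolated, and
derivatives use central differences. `pearson_matrix()` gives the
correlation matrix with two-sided t-tests of zero correlation for static
per-cell quantities.

# Known limitations

* The reaction–diffusion recovery model is solved numerically rather than
  through the closed Laplace-domain form of the prior literature; the two
  agree in the tested limits but the numerical route is slower (seconds per
  fit).
* FLIP rate estimates inherit the coarse-grid convention; absolute export
  and import values are tied to the interface-length flux scaling described
  above, which is also the convention the simulators use, so recovery tests
  are internally consistent by construction.
* The tracker is intentionally minimal (overlap joining with
  nucleus-seeded splitting); it is a fixture-grade reimplementation, not a
  general segmentation pipeline.
* Association `k1` is the least identifiable FLIP parameter (it trades off
  against the fixed dissociation and diffusion); recovery tolerances
  reflect that (25% versus 10% for import/export).
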