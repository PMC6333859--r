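---
title: "Kinetic asymmetry analysis of dynamic FDG-PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic asymmetry analysis of dynamic FDG-PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epikinet)
```

## The problem

Interictal FDG-PET localizes epileptic foci as regions of reduced glucose
metabolism. The conventional readout is the activity concentration of a
single late static scan; a dynamic scan additionally supports compartmental
kinetic modelling, separating capillary tracer exchange (influx `K1`,
efflux `k2`) from hexokinase phosphorylation (`k3`) and the net metabolic
flux `Ki = K1*k3/(k2+k3)`. Comparing side-to-side asymmetry of these
parameters against the asymmetry of static activity concentration asks
*which step of glucose metabolism drives the hypometabolism* of the focus,
and whether kinetic maps can lateralize a focus as well as the static scan.

`epikinet` implements this analysis end to end for volume-of-interest
(VOI) data: frame-schedule handling, an image-derived input function (IDIF)
with partial-volume correction, irreversible two-tissue-compartment (2TCM)
fitting, asymmetry indices, and the rank-based group statistics — together
with a synthetic-cohort generator so that every stage is testable without
patient data (none are publicly deposited for this design).

## The kinetic model

The irreversible 2TCM has a free compartment `C1` and a trapped
(phosphorylated) compartment `C2`:

$$\frac{dC_1}{dt} = K_1 C_p(t) - (k_2 + k_3)\,C_1,\qquad
  \frac{dC_2}{dt} = k_3\,C_1,\qquad C_1(0)=C_2(0)=0,$$

with model concentration
$C_\mathrm{model} = (1-v_B)(C_1+C_2) + v_B\,C_p$. Units follow the tracer
kinetics convention: `K1` in mL·min⁻¹·mL⁻¹, `k2`, `k3` in min⁻¹, times in
minutes for kinetics and in seconds for frame schedules, with explicit
converters (`s_to_min()`, `min_to_s()`). All curves are assumed
decay-corrected to injection time; the model contains no decay term.
`k4 = 0` throughout: dephosphorylation is neglected on the scan time scale.

**Numerical scheme.** The plasma input is declared piecewise-linear (zero
before its first sample). On each linear segment of the input the ODE
system has a closed-form solution, so the state is propagated exactly on
the union grid of input sample times and frame boundaries, and the
per-frame integrals of `C1`, `C2` (hence the frame-averaged model) are
also closed-form. The only numerics are `phi`-functions
(`(1-e^{-x})/x` and its higher analogues) evaluated by series below
small-`x` thresholds to avoid cancellation; the scheme is exact to
floating point for the declared input contract and degrades nowhere as
`k2 + k3 -> 0`. Tests confirm agreement with an independent stiff ODE
integrator to better than 1e-5 relative on all frames over a seeded
parameter grid.

**Fitting.** `fit_2tcm()` minimizes the weighted residual sum of squares
over `(K1, k2, k3)` — optionally `vB` — by bounded Levenberg–Marquardt
(\pkg{minpack.lm}) with 5 seeded multi-starts (one fixed physiological
start plus uniform draws inside the bounds). Defaults:

| parameter | bounds | rationale |
|---|---|---|
| `K1` | [0, 1] mL·min⁻¹·mL⁻¹ | physiological FDG brain range |
| `k2` | [0, 2] min⁻¹ | idem |
| `k3` | [0, 1] min⁻¹ | idem |
| `vB` | fixed at 0 (optionally free in [0, 0.2]) | the plain two-tissue model statement carries no blood term |

Frame weights default to frame duration (a uniform-variance-rate
approximation); `duration^2/value` and uniform weights are selectable.
Commercial kinetic software does not publish its weighting, so fits on
real data may differ in detail; the package's claims are therefore
validated as parameter recovery on synthetic data, not as equivalence
with any specific tool. Degenerate inputs are explicit: an all-zero TAC
returns a flagged boundary estimate; non-convergence after all restarts
is flagged, never silent; if `k2 + k3` underflows, `Ki` is defined as 0.

Noisy-fit behaviour is as expected for this model: the macro-parameter
`Ki` is far better identified than the micro-parameter `k3` (the test
suite records median relative errors under 3% frame noise of roughly
1.4% for `Ki` vs 5.5% for `k3`).

## Frame schedules

`make_frame_schedule()` lays (count, duration) groups end-to-end from
t = 0. The bundled clinical protocol is 12×5 s, 6×10 s, 6×30 s, 6×120 s,
10×300 s. Clinical write-ups quote this protocol as "39 frames" over a
"60-min" scan, but the printed groups sum to **40 frames and 4020 s
(67 min)**; the constructor is faithful to the printed groups and the
discrepancy is documented rather than silently resolved (a 9×300 s final
group would match both quoted figures, but substituting it would invent a
number). Frame averaging of arbitrary curves uses adaptive quadrature with
a 64-point Gauss–Legendre fallback; the kinetic forward model never needs
it (its frame averages are closed-form).

## Image-derived input function

The carotid ROI signal follows the partial-volume observation model
`Cmeas(t) = RC·Cinput(t) + SP·Cbkgd(t)`, with recovery coefficient `RC`
and spill-in factor `SP`; `correct_idif()` inverts it pointwise, clipping
(and counting) negative early-frame samples. No blood scaling is applied
anywhere: the asymmetry index is invariant to a common positive scaling of
both hemispheres, which is exactly why an uncalibrated IDIF is admissible
for this analysis.

`estimate_rc_sp()` derives the coefficients from the scanner point-spread
function: an infinite cylinder (default diameter 6 mm, an adult common
carotid) is blurred by an isotropic Gaussian at the reconstructed
resolution (default FWHM 5.4 mm) on a fine 2D cross-section grid
(pitch ≤ 0.5 mm; the geometry is translation-invariant along the vessel),
and `RC`/`SP` are the ROI means of the vessel-only and background-only
probes (default ROI: a 2 mm-radius central core). By linearity of the
normalized blur, `RC + SP = 1` for this geometry — the signal-conservation
property the tests assert — and `RC` decreases while `SP` increases with
FWHM. Per-subject ROI size/shape variation exists in practice; the
simulator exposes the geometry knobs but makes no attempt to reproduce
subject-specific coefficients.

## Asymmetry index and statistics

For each parameter and homologous region pair,

$$\mathrm{ASYM} = \frac{(\text{contralateral} - \text{ipsilateral})\cdot 2}
                       {\text{contralateral} + \text{ipsilateral}},$$

positive for a hypometabolic focus, bounded in [−2, 2], antisymmetric
under side swap, and scale-invariant. Patients contribute the *signed*
index of the epileptogenic region; controls, who have no focus side,
contribute the absolute left/right index averaged over the six evaluation
regions (`control_mean_abs_asym()`). A zero ipsi+contra sum is an explicit
error, never a silent 0.

"Wilcoxon rank test" is ambiguous between data layouts, so the package
uses the rank-sum (Mann–Whitney) form for between-group comparisons
(patients vs controls) and the signed-rank form for within-patient
comparisons of ASYM across parameters — each matching the structure of
the data it tests. Two-sided p-values come from exact enumeration of the
permutation distribution (midranks, ties handled) when the combined
sample size is ≤ 12, else from the normal approximation with tie
correction; both branches are checked against brute-force enumeration and
`stats::wilcox.test`. Spearman correlations use midranks with the
t-approximation for p (documented as approximate at n < 20). No multiple
testing correction is applied by default, matching the convention of
reporting uncorrected rank tests; a Holm option exists
(`stats = list(holm = TRUE)`). Correlation matrices are emitted fully
symmetric.

## The synthetic cohort

`simulate_cohort()` generates the study the analysis assumes, with every
"truth" recorded for recovery testing:

* **Input function** — a Feng-type tri-exponential bolus
  `A1·(t−τ)e^{−λ1(t−τ)} + A2·e^{−λ2(t−τ)} + A3·e^{−λ3(t−τ)}` (τ = 0.5 min,
  peak inside 2 min), densely sampled; per-subject log-normal amplitude
  jitter (sd 0.1) and ±6 s delay jitter emulate dose/delivery variability.
  Any smooth nonnegative bolus would do; the form and parameters are
  config-exposed.
* **Kinetic truth** — contralateral `(K1, k2, k3)` drawn uniformly from
  grey-matter FDG ranges (K1 ∈ [0.08, 0.12] mL·min⁻¹·mL⁻¹,
  k2 ∈ [0.10, 0.18], k3 ∈ [0.04, 0.08] min⁻¹), independently per region.
  The epileptogenic region of each patient receives a true per-parameter
  asymmetry `a ~ N(mean, sd)` truncated to (−2, 2) — defaults: means
  (0.12, 0.14, 0.21) for (K1, k2, k3), the reported patient-cohort means,
  sd 0.05 (inter-patient spread is not reported; this is a modelling
  choice) — and the ipsilateral value is `contra·(2−a)/(2+a)`, the exact
  inverse of the index. Controls and non-epileptogenic regions get
  `a ~ N(0, 0.01)` residual biological jitter. **Ki and static-AC
  asymmetry are never injected**: they emerge from the micro-parameter
  kinetics, preserving the causal structure (phosphorylation drives
  hypometabolism) and making the Ki-consistency check a real test.
* **Noise** — per-frame Gaussian with
  `sd = CV·value·sqrt(duration_ref/duration_f)`, the count-statistics
  scaling (longer frames less noisy). `duration_ref` defaults to the
  protocol's shortest frame, so `CV` (default 3%) is the *worst* per-frame
  coefficient of variation; anchoring it at the longest frame would make
  the short early frames ~23% noisy and cohort-mean asymmetry recovery to
  ±0.02 statistically impossible at n = 17, which is not the regime this
  design describes. True Poisson/sinogram physics, attenuation, scatter,
  motion and dispersion are out of scope.
* **Carotid measurement** — `mix_carotid()` combines the true input with a
  background curve (the subject's average noiseless tissue curve) using
  the configured RC/SP truth (by default the phantom-derived values for
  the 5.4 mm/6 mm/2 mm geometry, so generator and analysis are
  coherent). The measurement is point-sampled on the input's own time
  base: the CV = 0 contract (IDIF correction recovers the true input
  exactly) cannot hold for frame-averaged carotids, and frame-averaged
  extraction remains available through the regions module.
* **Static scan** — emulated as the late-window ([45, 60] min) average of
  the noiseless model plus noise at the reference CV; the real static
  acquisition follows the dynamic scan and its window is unstated, and the
  asymmetry index is scale-invariant, so raw (non-SUV) concentration is
  used.
* **Cohort structure** — defaults 17 patients / 8 controls; six
  evaluation region pairs named for the clinical VOI types, with the
  epileptogenic focus distributed across patients at the clinical
  frequencies (11 hippocampus, 2 inferior occipital, 1 each elsewhere).
  One master seed; per-subject child streams recorded in the manifest;
  identical seeds give bit-identical cohorts.

What passing tests on this generator do **not** show: performance under
real image texture, registration error, atlas–anatomy mismatch,
subject-specific carotid geometry, or non-Gaussian count noise. The
generator validates the *estimator chain*, not the acquisition physics.

## Regions module

Atlas-agnostic VOI extraction: any integer label volume on the image grid
plus a TSV lookup (`label_id`, `name`, `hemisphere`, `homolog_id`) is
accepted; the canonical 90-region anatomical template is deliberately not
bundled. Hemisphere comes from the lookup, never from voxel coordinates
(robust to orientation); the homolog map must be an involution; merged
multi-label VOIs pool voxels (volume-weighted). Extraction is the exact
voxel mean, linear in intensity, and round-trips bit-for-bit against the
painter used in tests. Spatial normalization is a precondition, not an
operation.

## Pipeline and reproducibility

`run_pipeline()` orchestrates simulate (or load) → IDIF → fit → ASYM →
statistics → report into a run directory (`manifest.json`, data tables,
`fits/`, `asym.csv`, `stats/`, `report.md`), deterministic given
config + seed, with `resume = TRUE` reusing a completed identical run
untouched. Configs are YAML/JSON, validated before any computation;
every reported number is computed from a written table. A thin
command-line front-end (`exec/epikinet`, subcommands `simulate` and
`run`; exit codes 0/2/3/4 for success/config/data/convergence errors)
wraps the same functions.

Problem sizes used by the shipped checks, chosen to exercise every code
path at desk scale: the cohort-mean recovery run uses the full 17-patient
cohort (epileptogenic pairs only, 34 fits); per-fit noiseless recovery
uses a 4-patient/2-control, 2-region cohort (24 fits); the ODE oracle a
20-point parameter grid; the noisy-replicate study 50 fits.

## Known limitations

* VOI-level only — no voxelwise parametric imaging, no reversible
  (`k4 > 0`) or reference-tissue models.
* The IDIF is uncalibrated by design; absolute quantification across
  subjects is out of scope (the asymmetry index does not need it).
* Small-sample Spearman p-values use the t-approximation.
* The Wilcoxon enumeration limit (combined n ≤ 12) is a computational
  choice; beyond it the tie-corrected normal approximation is standard
  but approximate.
* The generator's inter-subject asymmetry sd (0.05) and jitter sd (0.01)
  are modelling choices, not reported quantities.
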