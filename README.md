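# epikinet

Kinetic modelling and side-to-side asymmetry statistics for dynamic
FDG-PET lateralization of epileptic foci.

## The problem

Interictal FDG-PET shows an epileptic focus as a hypometabolic region,
conventionally read from the activity concentration (AC) of a late static
scan. A dynamic scan additionally supports compartmental modelling, which
separates the steps of glucose metabolism: capillary influx and efflux
(`K1`, `k2`), hexokinase phosphorylation (`k3`), and the net metabolic
flux

```
Ki = K1 * k3 / (k2 + k3)
```

`epikinet` is for researchers who want to ask, at the volume-of-interest
level, whether kinetic parameters lateralize a focus as well as static AC
and which metabolic step drives the hypometabolism. It implements:

* the irreversible two-tissue compartment model (2TCM, `k4 = 0`):
  `dC1/dt = K1*Cp − (k2+k3)*C1`, `dC2/dt = k3*C1`, with the model curve
  `(1−vB)(C1+C2) + vB*Cp`, forward-simulated exactly (closed-form
  propagation for piecewise-linear inputs) and fitted by bounded
  multi-start weighted nonlinear least squares;
* a carotid image-derived input function (IDIF) using the partial-volume
  model `Cmeas(t) = RC*Cinput(t) + SP*Cbkgd(t)`, with the recovery
  coefficient RC and spill-in factor SP estimated by blurring a cylinder
  phantom with the scanner point-spread function — no blood sampling, no
  blood scaling;
* the side-to-side asymmetry index
  `ASYM = (contralateral − ipsilateral) * 2 / (contralateral + ipsilateral)`
  (positive for a hypometabolic focus, scale-invariant — which is what
  makes an uncalibrated IDIF admissible);
* Wilcoxon rank tests (exact enumeration at small n, tie-corrected normal
  approximation otherwise) and Spearman correlation matrices over
  per-subject ASYM values;
* atlas-agnostic VOI extraction from labelled NIfTI volumes with
  homologous left/right region pairing;
* a fully synthetic cohort generator (bolus input functions, kinetic
  ground truth with controllable asymmetry, frame-duration-scaled noise,
  carotid mixing, late-window static scans) so the entire pipeline is
  testable without patient data.

## Worked example

Simulate a small study (6 patients with true epileptogenic asymmetry
injected into the micro-parameters, 4 symmetric controls, 3% frame
noise), run IDIF correction, 2TCM fitting and the asymmetry statistics:

```r
library(epikinet)

default_frame_schedule()
#> frame_schedule: 40 frames, 0-4020 s (67.0 min)

estimate_rc_sp(fwhm_mm = 5.4, vessel_diameter_mm = 6, roi_radius_mm = 2)
#> PVC coefficients: RC = 0.5060, SP = 0.4940

cfg <- run_config(
  seed = 11,
  simulate = list(n_patients = 6, n_controls = 4, cv = 0.03,
                  asym_sd = c(K1 = 0.02, k2 = 0.02, k3 = 0.02),
                  regions = c("Hippocampus", "Insula"), epi_weights = c(1, 1)),
  fit_scope = "focus")
res <- run_pipeline(cfg, file.path(tempdir(), "demo"))

res$stats$means
#>   parameter patients_epileptogenic_mean controls_mean_abs
#> 1        K1                   0.1184613        0.01651540
#> 2        k2                   0.1247312        0.02220309
#> 3        k3                   0.1985471        0.02290933
#> 4        Ki                   0.1717640        0.01543420
#> 5  staticAC                   0.1357571        0.04616136

res$stats$group_tests[, c("parameter", "test", "p_value")]
#>   parameter              test    p_value
#> 1        K1 Wilcoxon rank-sum 0.00952381
#> 2        k2 Wilcoxon rank-sum 0.00952381
#> 3        k3 Wilcoxon rank-sum 0.00952381
#> 4        Ki Wilcoxon rank-sum 0.00952381
#> 5  staticAC Wilcoxon rank-sum 0.01904762
```

Reading the output: the patients' epileptogenic regions carry the
injected mean asymmetry (about 0.12/0.14/0.21 for `K1`/`k2`/`k3`, here
estimated from only 6 subjects), the derived `Ki` and static-AC
asymmetries emerge from the kinetics without being injected, and the
controls' mean absolute left/right asymmetry stays near the noise floor;
every exact rank-sum test separates patients from controls. The run
directory (`manifest.json`, `data/`, `fits/`, `asym.csv`, `stats/`,
`report.md`) is reproducible byte-for-byte from config + seed, and
`run_pipeline(cfg, dir, resume = TRUE)` reuses a completed run untouched.

Individual fits are available too:

```r
res$fits[1, ]
#>   subject_id      voi_id          side         K1        k2         k3 vB
#> 1        C01 Hippocampus contralateral 0.07931937 0.1229073 0.07347867  0
#>           Ki      wrss converged
#> 1 0.02967769 0.3193042      TRUE
```

A thin CLI over the same functions lives at `exec/epikinet`
(`epikinet simulate|run -c config.yaml -o out_dir --seed N`).

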