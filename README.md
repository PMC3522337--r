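# airtrapcad

Computer-aided detection and severity scoring of COPD air trapping from
paired inspiration/expiration thoracic CT.

## The problem

Chronic obstructive pulmonary disease obstructs expiratory airflow, so air
stays trapped in the lung at end-expiration. On paired breath-hold CT this
appears as a *reduced decrease* of lung area and volume from full
inspiration to full expiration. `airtrapcad` measures that decrease
automatically and classifies subjects, for researchers building or
evaluating quantitative-CT COPD pipelines who need a complete, testable
reference implementation that runs without patient data.

The pipeline:

1. **Segmentation** — per-slice parametric active contours (snakes)
   minimizing E = Σ α‖xᵢ₊₁−xᵢ‖² + β‖xᵢ₊₁−2xᵢ+xᵢ₋₁‖² − κ Σ M(xᵢ), with
   M = |∇(G_σ ∗ I)|² the normalized edge map, seeded from air-density
   thresholding; the tracked airway lumen is excluded.
2. **Carina detection** — the tracheal air column is tracked from the apex;
   the carina is the first slice where it splits into two persistent
   bronchi, anchoring cross-phase slice correspondence.
3. **Features** — normalized area variation at the carina slice,
   ΔS_N = (S_insp − S_exp)/S_insp, and normalized total volume variation
   from every 17th slice, ΔV_N = (V_insp − V_exp)/V_insp.
4. **Classification** — two-class univariate Gaussian Bayes rule: assign
   normal iff l_r(x) = p(x|ω₁)/p(x|ω₂) > p(ω₂)/p(ω₁), with closed-form
   decision thresholds and per-class least-squares severity lines
   ΔV_N = a·ΔS_N + b.
5. **Evaluation** — Welch t-tests, confusion matrix, sensitivity /
   specificity / PPV / NPV / accuracy.

A synthetic thoracic phantom generator (torso, two ellipsoidal lungs with a
controllable expiratory shrink, bifurcating trachea, noise) provides
analytic ground truth for every stage, and a cohort-level simulator draws
feature pairs from class-specific bivariate Gaussians.

## Worked example

Simulate a 12-normal / 25-patient cohort, fit the model, classify, and
evaluate:

```r
library(airtrapcad)
co  <- generate_cohort_features(12, 25, seed = 3)
fit <- airtrap_model(co)
fit
#> Two-class Gaussian Bayes air-trapping model
#>   n = 12 normal, 25 patient; empirical priors (0.324 / 0.676)
#>   area variation: normal 0.3796 (SD 0.0655), patient 0.1350 (SD 0.1993); threshold 0.3007
#>   volume variation: normal 0.4364 (SD 0.0690), patient 0.1667 (SD 0.2058); threshold 0.3513
#>   severity line (normal): dV = 0.901 dS + 0.094  (R^2 = 0.732)
#>   severity line (patient): dV = 0.879 dS + 0.048  (R^2 = 0.725)
#>   decision feature: volume variation
```

Normal lungs lose ~44% of their volume on expiration here, patients only
~17% (with much higher spread): air trapping. The decision threshold
0.3513 is where the two prior-weighted class densities cross. Classify and
score:

```r
ev <- evaluate_predictions(predict(fit, co)$label, co$label)
ev$metrics
#>        metric  fraction percent
#> 1 sensitivity 0.8400000    84.0
#> 2 specificity 0.8333333    83.3
#> 3         ppv 0.9130435    91.3
#> 4         npv 0.7142857    71.4
#> 5    accuracy 0.8378378    83.8

severity_score(data.frame(delta_S_N = 0.15, delta_V_N = 0.20), fit)
#>   delta_V_N z_air_trapping posterior_patient residual_normal residual_patient
#> 1       0.2       3.428361         0.9959485      -0.0295981       0.02008813
```

A subject whose volume variation sits 3.4 normal-class SDs below the
normal mean, with posterior patient probability 0.996: marked air
trapping.

The image pipeline runs the same way from volumes:

```r
ph <- generate_phantom_pair(phantom_spec(s_xy = 0.85, s_z = 0.85))
extract_features(ph$insp, ph$exp)   # ΔS_N ≈ 1 − 0.85², ΔV_N ≈ 1 − 0.85³
```

or from the shell via
`Rscript inst/cli/airtrapcad.R <simulate|segment|carina|features|train|classify|evaluate|run>`.

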