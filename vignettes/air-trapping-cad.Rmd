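---
title: "Quantifying air trapping on paired inspiration/expiration CT"
author: "airtrapcad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying air trapping on paired inspiration/expiration CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtrapcad)
```

## The measurement problem

Chronic obstructive pulmonary disease (COPD) obstructs expiratory airflow:
air that should leave the lung on exhalation stays trapped behind narrowed
airways. On paired breath-hold CT — one volume at full inspiration, one at
full expiration — this shows up as a *reduced decrease* of lung area and
volume between the two phases. `airtrapcad` turns that observation into two
normalized per-subject features and a probabilistic diagnosis:

* **Area variation** $\Delta S_N = (S_{insp} - S_{exp}) / S_{insp}$, where
  $S$ is the lung cross-sectional area at the carina slice of each phase.
  Normalizing by the inspiration value removes subject size (and with it
  much of the age/height/sex variation) from the comparison.
* **Volume variation** $\Delta V_N = (V_{insp} - V_{exp}) / V_{insp}$, with
  $V$ the total lung volume estimated from every 17th axial slice.

Healthy lungs empty well ($\Delta V_N$ around 0.4); obstructed lungs trap
air ($\Delta V_N$ nearer 0.2, with far higher variance). A two-class
univariate Gaussian Bayes classifier separates the groups, and per-class
linear models of $\Delta V_N$ on $\Delta S_N$ support severity reporting.

## Lung segmentation: a per-slice parametric snake

Each axial slice is segmented independently (the classic parametric
active-contour formulation; apical and basal slices differ too much in
topology for a single 3-D surface to be worth its complexity here). A
contour $x_1, \dots, x_n$ evolves to minimize

$$E = \sum_i \alpha\,\|x_{i+1}-x_i\|^2 + \beta\,\|x_{i+1}-2x_i+x_{i-1}\|^2
      \;-\; \kappa \sum_i M(x_i),$$

with $M = |\nabla (G_\sigma * I)|^2$ the squared gradient magnitude of the
Gaussian-smoothed slice, normalized to $[0,1]$ so that $\kappa$ is
independent of the intensity scale. The first two terms penalise stretch
and bending; the external term pulls the contour onto intensity edges.

Numerical scheme and the choices behind it:

* **Initialization.** Air voxels (below `air_threshold`, default −320 HU —
  roughly midway between aerated lung at about −850 HU and soft tissue at
  0 HU) are labelled into connected components; components touching the
  image border are background air and are discarded, as are components
  under 50 mm² (far below any real lung cross-section). The traced boundary
  of each surviving component, resampled uniformly in arc length
  (16–200 points, about one point per 2 px of perimeter), seeds one snake.
* **Evolution.** Internal forces are applied implicitly through a cyclic
  pentadiagonal solve (unconditionally stable in $\alpha,\beta$), the
  external force explicitly with bilinear interpolation of
  $\nabla M$. Whenever a step would *increase* $E$, the step size is halved
  (up to 12 times) before the step is accepted; if no decreasing step
  exists the contour is converged. The energy trace is therefore
  non-increasing by construction — a property the test suite asserts — and
  evolution is fully deterministic.
* **Stopping.** Mean point displacement below `conv_tol` (default 0.1 px)
  or `max_iter` (default 500). The defaults assume boundary-adjacent
  initialization, which thresholding provides; a contour that must first
  cross a flat region (as in the synthetic-disk convergence test) needs a
  finer `conv_tol`, because drift through a force-free region moves points
  slowly.
* **Degenerate contours.** A contour whose enclosed area falls below
  50 mm² during evolution raises a collapse error; the segmenter drops
  that contour with a warning rather than aborting the slice.
* **Defaults** $\alpha = 0.1$, $\beta = 0.1$, $\gamma = 1$, $\kappa = 2$,
  $\sigma = 2$ px are conventional magnitudes for this formulation; they
  are validated solely by the phantom Dice gate (≥ 0.95 against ground
  truth) rather than tuned per-image.

The conducting airway (trachea and main bronchi) is air too, and would
contaminate small-area slices; the tracked lumen, dilated by one in-plane
voxel so no boundary ring survives, is subtracted from the final mask.

## Carina detection

The carina — the ridge where the trachea bifurcates — anchors the choice of
corresponding slices across phases. The tracker seeds on the air component
of plausible tracheal area (50–500 mm²) in the most superior tenth of the
volume and follows components downward by footprint overlap; overlap, not
centroid distance, because at 3 mm slice spacing a centroid can move
several voxels between slices while the lumen footprints still intersect.
The carina is the most superior slice where the track splits into ≥ 2
components that each persist for ≥ 2 further slices; the persistence guard
keeps a single-slice noise split from triggering detection. Components
larger than 800 mm² are not followed, so the track cannot leak into the
lung once a bronchus reaches parenchymal air. The carina slice is detected
independently in each phase: inspiratory and expiratory anatomy sit at
different table positions, so propagating one index across phases would be
wrong at 3 mm spacing.

## Feature computation

All areas and volumes are physical (voxel counts × spacing), never raw
counts, so the two phases may differ in slice count or even grid size.
The subsampled volume estimator weights each sampled slice by
$k\,\mathrm{d}z$ (a Riemann sum — no interpolation between samples),
consistent with "use every 17th slice" and gated by the requirement that
the $k=17$ and $k=1$ estimates of $\Delta V_N$ agree within 0.02 on smooth
phantoms. Negative feature values (expiration apparently larger than
inspiration) are physiologically odd but possible with imperfect
breath-holds; they are kept, flagged with a warning, and classified like
any other value — clamping would distort the Gaussian class models.

## The Bayes classifier

For a feature $x$ and classes $\omega_1$ (normal), $\omega_2$ (patient)
with fitted Gaussians and priors, the minimum-error rule assigns normal
when the likelihood ratio $l_r(x) = p(x|\omega_1)/p(x|\omega_2)$ exceeds
$p(\omega_2)/p(\omega_1)$ — implemented as the exactly equivalent posterior
comparison. Conventions fixed for reproducibility:

* Sample standard deviations use the $n-1$ denominator.
* Priors are empirical class frequencies by default; equal priors are an
  option.
* A tie at the boundary goes to *patient*: in a screening context the
  costlier error is the missed patient.
* The default decision feature is the volume variation — the 3-D feature
  needs no cross-phase slice correspondence — with the area feature
  selectable. The two features are modelled separately; a joint bivariate
  classifier is deliberately out of scope.

The decision boundary solves the quadratic from equating log-posteriors:
up to two real roots for unequal variances, one for equal. Roots are
computed with the cancellation-free quadratic formula and polished with
three Newton steps on the log-posterior difference, so posterior equality
holds at each root to well below $10^{-8}$ even for boundaries far in the
tails; the classification-relevant root (between the class means) is
reported first. When the weighted densities never cross, an empty set is
returned with a warning and classification falls back to posterior
comparison.

`airtrap_model()` packages all of this in the usual R modelling idiom — one
fitting function returning an object with `print`, `summary`, `coef`,
`predict`, `simulate`, `plot` and `residuals` methods — with per-class
ordinary least-squares severity lines ($\Delta V_N$ on $\Delta S_N$) fitted
by `lm()`. No explicit severity scale is defined by the underlying models,
so `severity_score()` reports only quantities they already define: the
volume variation itself, its z-score against the normal class
$(\mu_N - \Delta V_N)/\sigma_N$, the posterior patient probability, and the
residual from each class's severity line.

## Statistical evaluation

Class separation is assessed with Welch's unequal-variance t-test
(`stats::t.test`; the Welch–Satterthwaite degrees of freedom are
fractional, which is the signature of this variant). Diagnostic accuracy
uses the standard five metrics with *patient* as positive; a metric with a
zero denominator is reported as undefined (`NA`), never as 0, and
percentages round half *away from zero* to one decimal — base R's
round-half-to-even would print 83.7 where the conventional presentation of
83.75 is 83.8.

## The phantom: what it emulates and what it does not

The synthetic generator renders an elliptic soft-tissue torso (0 HU) in
background air (−1000 HU), two ellipsoidal lungs (−850 HU at inspiration),
and a tracheal tube (8 mm radius) splitting into two bronchi at a known
slice. Expiration scales each lung about its own centroid by $s_{xy}$
in-plane and $s_z$ axially and renders it 100 HU denser — the real
expiratory attenuation increase — so segmentation is exercised under a
phase-dependent intensity shift. Gaussian noise (default SD 10 HU, a
realistic parenchymal noise level for the modelled dose) is added with a
fixed seed; generation is bit-reproducible. Ground truth is analytic:
$\Delta S_N = 1 - s_{xy}^2$ (the lungs are z-centred on the carina slice,
so the carina cross-section scales exactly in-plane) and
$\Delta V_N = 1 - s_{xy}^2 s_z$.

The default grid is 128 slices of 160 × 160 voxels at (3, 1, 1) mm —
apex-to-adrenal coverage of about 384 mm at a clinical chest-CT voxel
size — with lung semi-axes (110, 48, 28) mm. At this geometry the
every-17th-slice volume estimator stays within 0.02 of the exact ratio
across shrink factors 0.7–1.0; with materially shorter axial coverage the
sampling grid becomes too coarse relative to the lung profile and that
fidelity degrades. Unit tests use a half-size phantom (48 slices of
96 × 96) where full coverage is not needed, and the full grid where it is
(subsampling fidelity, the two-ellipsoid self-consistency check, the
end-to-end recovery suite over shrink factors 0.75–0.95).

What passing phantom tests does **not** show: the phantom has no vessels,
fissures, emphysematous texture, cardiac motion, or scanner noise spectra,
and its lungs are convex ellipsoids with sharp boundaries. Segmentation
accuracy on the phantom is therefore an upper bound, not an estimate, of
accuracy on patient data; the cohort-level simulator
(`generate_cohort_features()`, bivariate Gaussians with configurable
within-subject feature correlation, default 0.8) exists precisely so the
classifier can also be exercised on feature distributions with realistic
overlap.

## Known limitations

* Input is NIfTI only; DICOM series must be converted upstream.
* Axial stacks with slice 1 most superior are assumed; no general
  orientation handling beyond honouring the NIfTI z-direction.
* Per-slice 2-D snakes: no gradient-vector-flow, level-set, or 3-D surface
  variants, and no vessel removal.
* Decision thresholds fitted on small cohorts are descriptive; with 12 and
  25 subjects per class their sampling variability is substantial, and
  thresholds published from summary statistics cannot generally be
  reproduced from rounded moments.
* The pipeline evaluates apparent (resubstitution) accuracy by default,
  matching the historical evaluation style it reimplements; held-out
  evaluation is the caller's responsibility.
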