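---
title: "Approximating the lumbar canal area from two linear measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating the lumbar canal area from two linear measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalarea)
```

## The problem

Manually tracing the cross-sectional area of the bony lumbar spinal canal on
CT is slow and hard to automate, while two linear measurements — the
interpedicular distance (IPD, the maximum transverse distance between the
medial aspects of the pedicles) and the anteroposterior (AP) diameter of the
canal — are fast, reliable, and within reach of automated landmarking. This
package implements and evaluates the idea of replacing the traced area with
a closed-form function of those two diameters, per vertebral level L1–L5.

## The three shape estimators

Treating IPD and AP as the axes of a simple figure gives three candidate
areas, all in mm²:

* **ellipse**: $\hat A = \pi \cdot \frac{IPD}{2} \cdot \frac{AP}{2} = \frac{\pi}{4}\, IPD \cdot AP$
* **triangle** (base IPD, height AP): $\hat A = \frac{1}{2}\, IPD \cdot AP$
* **rectangle**: $\hat A = IPD \cdot AP$

All three are fixed multiples of the diameter product $P = IPD \cdot AP$.
Two consequences drive much of the package's structure:

1. **Collinearity.** Any linear combination of the three estimators equals
   $c \cdot P$ for a single scalar $c$; the family has exactly one effective
   degree of freedom. `fit_second_order()` exploits this.
2. **Correlation invariance.** The Pearson correlation between an estimator
   and the measured area is the same for all three shapes (correlation is
   invariant under positive affine maps), so a report carries one $r$ per
   level.

## Agreement statistics

`evaluate_cohort()` compares each estimator against the manually measured
area per level: group means ± SD, mean difference (estimate − manual) ± SD
of the per-subject differences, a two-sided paired t-test, the Pearson
correlation, and a signed percent error.

**Percent error convention.** The default "aggregate" mode is the
ratio-of-means,
$100\,(\bar{\hat A} - \bar A)/\bar A$, which equals $100 \cdot MD / \bar A$
and is fully determined by the two group means. A per-subject
mean-of-ratios mode is available (`percent_error_mode = "per_subject"`);
on real data the two differ whenever the denominator varies across
subjects. The aggregate mode is the default because it is the convention
that reconstructs a published percent-error table exactly from the
corresponding table of group means.

Other conventions fixed here: sample (n − 1) standard deviations
throughout; two-sided t-tests; p-values below $10^{-3}$ rendered as
`<0.001` at the report boundary only. All computation is double precision;
2-decimal rounding (3 for correlations) happens only when a report is
formatted.

## The second-order approximation

Because the ellipse and rectangle consistently overestimate the traced area
and the triangle consistently underestimates it, a combined estimator can do
better than any fixed shape. By the collinearity argument every such
combination is $k \cdot P$, so the package fits the one free parameter by
least squares through the origin,

$$\hat k \;=\; \frac{\sum_i A_i P_i}{\sum_i P_i^2},$$

which minimises the training RMSE over all shape combinations. For
interpretability `weights_from_factor()` re-expresses $\hat k$ as the
weights of an ellipse/triangle mixture with $w_e + w_t = 1$; weights
outside $[0,1]$ are legal and flagged as extrapolating.

Fitting is per level by default: the effective area-to-product ratio drifts
from about 0.72 at L1 to about 0.68 at L5 (the canal becomes less
elliptical caudally), so a pooled fit (`per_level = FALSE`) blurs a real
anatomical trend; both are exposed because neither choice is canonical.
The loss is squared error — the natural choice for a mean-area calibration
— with a dense grid search used as an independent oracle in the tests.
Honest error estimation uses k-fold cross-validation (default 5 folds,
shuffle driven by an explicit seed, bit-reproducible).

## The synthetic cohort generator

No per-patient data are distributed with the reference summary statistics
the package targets, so `generate_cohort()` simulates cohorts whose
per-level moments and estimator–measurement correlations match published
per-level summaries of a 555-patient young-adult (18–35 y) lumbar CT
series, shipped in `inst/extdata/level_calibration.yaml`:

* manual canal area, mean ± SD per level (e.g. L1: 281.78 ± 48.89 mm²);
* diameter product $P$, mean ± SD per level (identical to the rectangle
  estimator's moments, e.g. L1: 389.06 ± 71.93 mm²);
* the shared estimator–measurement correlation per level (0.905–0.934).

**Generative direction.** The manual area is the latent truth,
$A \sim \mathcal N(\mu_A, \sigma_A^2)$, and the product is regression-linked
to it, $P = \beta A + \alpha + \varepsilon$, with
$\beta = r\,\sigma_P/\sigma_A$, $\alpha = \mu_P - \beta\mu_A$,
$\sigma_\varepsilon = \sigma_P\sqrt{1 - r^2}$, so that the simulated
$(\mu_P, \sigma_P, \mathrm{corr}(P, A))$ hit their targets exactly in
expectation. The reverse direction — independent additive noise on $A$
given $P$ — cannot reproduce the published moments: it would force
$\sigma_A \ge r$-scaled $\sigma_P$ relationships that the printed values
contradict.

**Positivity.** Marginals are truncated at zero by resampling. At the
calibrated coefficients of variation (≤ 0.29) the truncation point lies
more than 3.5 SDs below the mean, so moment distortion is far below the
Monte-Carlo noise at any realistic n. A `reject` policy (redraw the whole
record) is available; the two coincide in distribution up to the joint
truncation set and both abort after $10^6$ redraws.

**The IPD/AP split.** The published summaries report only the product's
moments, never IPD or AP separately. IPD is therefore drawn as an
independent positive size variable (default mean 24 mm, CV 0.08 —
anatomically plausible for the lumbar spine and overridable in the config)
and AP is defined as $P / IPD$, so the product is reproduced to machine
precision. The split affects no downstream statistic; it exists so the
tables carry realistic-looking diameters.

**Demographics** (optional, off by default) are independent truncated
normals at the published cohort moments (height 1.54 ± 0.09 m, weight
80.44 ± 23.42 kg, BMI 28.27 ± 7.2 kg/m², age centred at 27.2 y and
truncated to 18–35, 58.4% female; the age SD, 4.5 y, is chosen since none
is published). They are drawn independently of each other and of the
measurements — BMI is *not* constrained to weight/height² (the published
marginal moments are mutually inconsistent with that identity) — and no
statistic in the pipeline consumes them.

**What the generator does not emulate.** Within-patient correlation across
levels (levels are analysed independently; a shared size factor would
change no per-level statistic), non-Gaussian tails, stenotic or deformed
canals, observer effects, and any IPD–AP dependence beyond the product.
Passing tests on synthetic cohorts therefore demonstrate that the pipeline
recovers the moments and correlations it was calibrated to — not that the
estimators behave identically on clinically abnormal anatomy.

## A worked run

```{r pipeline}
cohort <- generate_cohort(cohort_spec(n_patients = 555, seed = 42))
agreement <- evaluate_cohort(cohort)
fits <- fit_second_order(cohort, folds = 5, seed = 1)
build_report(agreement, fits)
```

At n = 555 the simulated agreement statistics land within Monte-Carlo
noise of their calibration targets (e.g. L1 ellipse mean difference near
23.8 mm², percent error near 8.4%, r near 0.907), and the fitted
second-order factors sit near 0.72 at L1 drifting to 0.68 at L5, with
training RMSE below the best single shape at every level by construction.

## Problem sizes and numerical choices

The test suite exercises calibration recovery at n = 100000 for the tight
tolerances (mean within 0.5%, SD within 1%, r within 0.01) and uses 200
replicate cohorts at the reference size n = 555 for two-standard-error
moment checks; both run in seconds. Degenerate inputs fail loudly rather
than silently: zero-variance differences reject the t-test, zero-variance
series reject the correlation, nonpositive lengths name the offending
field, and fewer rows than folds rejects cross-validation. Ties in the
grid-search oracle are broken by the first minimum, irrelevant at the grid
step (1e-5) used.

## Limitations

The estimators assume a convex, roughly elliptical canal; trefoil and
stenotic geometries violate that and are out of scope. The second-order
factor is calibrated to one population's summaries and should be refitted
before use elsewhere. The aggregate percent error is a property of group
means, not a per-patient accuracy guarantee.
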