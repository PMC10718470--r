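# canalarea

Estimate the cross-sectional area of the lumbar spinal canal (L1–L5) from
two linear CT measurements — the interpedicular distance (IPD) and the
anteroposterior (AP) canal diameter — and quantify how well those estimates
agree with a manually traced canal area. Written for spine morphometry and
method-comparison work, where automated linear landmarks are cheap but a
traced area is the gold standard.

## The method

All three estimators are fixed multiples of the diameter product
`P = IPD × AP` (mm²):

| shape     | area                | factor |
|-----------|---------------------|--------|
| ellipse   | π·(IPD/2)·(AP/2)    | π/4    |
| triangle  | ½·IPD·AP            | 1/2    |
| rectangle | IPD·AP              | 1      |

Agreement with the traced area A is summarised per vertebral level by the
mean difference (estimate − manual) ± SD, a two-sided paired t-test, the
aggregate percent error `100·(mean estimate − mean manual)/mean manual`,
and the Pearson correlation r (identical across the three shapes, since
they differ only by a positive constant).

Because ellipse and rectangle overestimate while the triangle
underestimates, the package also fits a **second-order approximation**
`Â = k̂ · IPD · AP` with `k̂ = Σ A·P / Σ P²` (least squares through the
origin — the unique free parameter any combination of the three shapes
collapses to), reported with an equivalent ellipse/triangle weight
decomposition and k-fold cross-validated RMSE.

A calibrated generator (`generate_cohort()`) simulates cohorts whose
per-level manual-area moments, product moments and estimator–measurement
correlations match published summaries of a 555-patient young-adult lumbar
CT series (packaged in `inst/extdata/level_calibration.yaml`), so the whole
pipeline runs and is tested without patient data.

## Worked example

```r
library(canalarea)

cohort    <- generate_cohort(cohort_spec(n_patients = 555, seed = 42))
agreement <- evaluate_cohort(cohort)
fits      <- fit_second_order(cohort)
build_report(agreement, fits)
```

```
Mean measurements (mm², mean±SD)
Level  Manual        Ellipse       Triangle      Rectangle
L1     281.12±48.17  303.53±57.19  193.23±36.41  386.46±72.81
...
Mean differences vs manual measurement
Level  Shape      Mean difference (mm²)  p-Value  Correlation (r)
L1     Ellipse    22.41±24.43            <0.001   0.906
L1     Triangle   -87.89±21.59           <0.001   0.906
L1     Rectangle  105.34±35.55           <0.001   0.906
...
Percent error vs manual measurement
Level  Ellipse  Triangle  Rectangle
L1     7.97%    -31.26%   37.47%
...
Second-order approximation (area ≈ k_hat · IPD · AP)
Level  k_hat  w_ellipse  w_triangle  RMSE   CV RMSE
L1     0.723  0.782      0.218       22.28  22.30
```

Reading the L1 rows: on this simulated 555-patient cohort the ellipse
overestimates the traced area by 22.4 mm² on average (+8.0%), the triangle
underestimates by 87.9 mm² (−31.3%), the rectangle overestimates by
105.3 mm² (+37.5%); all differences are decisively nonzero at this sample
size, and every estimator correlates 0.906 with the traced area. The
fitted second-order factor 0.723 (a 78/22 ellipse/triangle mixture) brings
the residual RMSE down to 22.3 mm², below any single shape.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/scripts/canalarea`): `simulate`, `evaluate`, `fit-second-order`,
`report`.

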