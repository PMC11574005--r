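# shapestage

Vertex-wise subcortical **shape staging** for Parkinson's disease (PD):
an R implementation of the full analysis stack used to relate local
subcortical surface morphology to ordinal clinical stage — from registered
surface meshes to interpretable stage classifiers — validated end to end
on a synthetic cohort generator that emulates the statistical structure of
large multi-cohort shape studies.

## What it does

Subcortical shape analysis measures, at every vertex of a structure's
surface mesh, the **radial distance** ("thickness") from the surface to a
medial curve fitted through the structure's center. Given thickness for
thousands of registered vertices across seven bilateral structures
(thalamus, caudate, putamen, pallidus, hippocampus, amygdala, accumbens;
27,120 vertices in the default atlas), the package provides:

* **Mass-univariate inference.** Per vertex, the linear mixed model
  `thickness ~ group + age + sex + ICV + (1 | cohort)` (REML via `lme4`),
  with Hoehn–Yahr (HY) stage groups compared against age- and sex-matched
  controls (greedy nearest-neighbour matching), and multiplicity handled
  by **searchlight FDR**: Benjamini–Hochberg at level *q* inside each
  vertex's geodesic neighbourhood.
* **Spin permutation tests.** Spatial similarity *r* between two effect
  maps on a structure, tested against a null of quaternion-uniform random
  rotations of one map on the registration sphere:
  `p = (1 + #{|r_null| >= |r_obs|}) / (1 + N)`.
* **Structured-sparsity classifiers.** Binary logistic regression
  (Logit-TVL1) and its ordinal extension (**Ordit**, a cumulative-logit
  model with one shared weight map and ordered thresholds
  `theta_1 < ... < theta_{K-1}`), both penalized by
  `lambda_l1 ||w||_1 + lambda_tv sum_(i,j) |w_i - w_j|`
  (L1 + anisotropic graph total variation), solved by monotone accelerated
  proximal gradient with an exact dual TV prox, and tuned by nested
  stratified 4-fold cross-validation with the one-standard-error rule.
* **Synthetic data.** A mesh-atlas builder (uv-spheres deformed into
  structure-like shapes, spherical registration retained), and a cohort +
  thickness generator with stage-dependent geodesic-Gaussian effects of
  both signs, nuisance covariate effects, cohort random intercepts, and
  i.i.d. vertex noise.

## Worked example

The demonstration pipeline simulates a four-structure atlas (bilateral
putamen with planted, stage-progressive focal thinning plus an early
focal thickening; bilateral pallidum with no planted effect), a staged
multi-cohort sample of ~400 subjects, and runs the full analysis:

```r
library(shapestage)
run_pipeline(demo_pipeline_config(seed = 7), "demo_out")
read.delim("demo_out/summary_hy45.tsv")
```

```
contrast structure hemisphere pct_significant  peak_beta
    hy45   putamen       left           37.65      -0.35
    hy45  pallidum       left            0.00       0.00
    hy45   putamen      right           33.33      -0.34
    hy45  pallidum      right            0.00       0.00
```

At the most severe stage contrast (HY45 vs matched controls), roughly a
third of putamen vertices are significant at *q* = 0.05 with a peak
coefficient of about −0.35 mm (thinner in patients) — the planted effect —
while the zero-effect pallidum stays clean. The spin test between the HY1
and HY2 putamen maps reports `r = 0.86, p = 0.005` (consecutive-stage
patterns are spatially similar, as planted), nested-CV ROC-AUC for
PD-vs-control is ~1.0 at this demo effect size, and the three-class
ordinal classifier's balanced F1 is ~0.48 against a 1/3 chance level.

A thin CLI wraps the same functions:

```sh
inst/exec/shapestage run --seed 7 --out demo_out
inst/exec/shapestage thickness --mesh putamen_left.ply --sections 12 --out t.tsv
```

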