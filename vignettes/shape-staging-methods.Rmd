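---
title: "Methods: subcortical shape staging with radial-distance morphometry"
author: "shapestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subcortical shape staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`shapestage` implements a complete vertex-wise shape-staging analysis for
subcortical structures in Parkinson's disease (PD): a synthetic registered
mesh atlas, the radial-distance ("thickness") shape feature measured
against a medial curve, mass-univariate linear mixed models with
searchlight false-discovery-rate (FDR) control, spin-permutation tests of
spatial similarity between effect maps, and structured-sparsity (TV-L1)
binary and ordinal classifiers of Hoehn–Yahr (HY) stage. Because the
consortium MRI data behind such analyses cannot be redistributed, the
package ships a generative cohort model that emulates their statistical
structure; all validation is property- and simulation-based against that
generator and against independent numerical oracles.

## The mesh atlas

The atlas holds fourteen structures (seven bilateral: thalamus, caudate
nucleus, putamen, globus pallidus, hippocampus, amygdala, nucleus
accumbens), each a closed genus-0 triangulated surface with a per-vertex
spherical registration. The default configuration uses uv-spheres whose
per-structure vertex counts sum to exactly 27,120 — the scale of the
consortium template — with ellipsoid axes, taper and bend parameters that
give each structure loosely anatomical proportions (a banana-bent caudate,
an elongated bent hippocampus, a small round accumbens). The true
template's per-structure vertex counts and geometry are not public; these
defaults mirror its scale without claiming to match it, and every number
is configurable.

Design choices:

* **Indexing.** Vertices carry R's native 1-based indices, blocked by
  structure so whole-brain feature vectors concatenate structures in a
  fixed order. On disk, PLY faces use the format's 0-based convention; the
  readers and writers convert.
* **Spherical registration.** Each vertex keeps its pre-deformation
  unit-sphere position. This is exactly the parameterization the spin test
  needs, and emulates a template-space registration in which homologous
  vertices share indices across subjects.
* **Adjacency** is derived from shared face edges and never crosses
  structures.

## Radial distance ("thickness")

The shape feature is the distance from each surface vertex to a medial
curve through the structure's center. The fitting procedure is: project
vertices on their first principal axis, slice into `n_sections`
equal-width bins (default 10–12; a bin must hold at least 3 vertices),
take bin centroids, and pass an interpolating natural cubic spline
(`smoothing = 0`) or a smoothing spline with roughness penalty `lambda =
smoothing` through them, parameterized by chord length. Distances are
computed by dense sampling of the curve (at least 512 parameters) followed
by a vectorized golden-section refinement of each vertex's bracketing
interval, to a parameter tolerance of 1e-12. The upstream shape pipelines
that popularized this feature do not publish their exact medial-curve
algorithm; this procedure implements the same concept — a smooth curve
through the approximate center — in a fully specified, testable form, and
no equivalence to any particular pipeline is claimed.

The *medial-curve discrepancy* quality-control statistic is defined here
as the root-mean-square distance between the section centroids and the
fitted curve, normalized by mean thickness: zero when the spline
interpolates, growing as smoothing pulls the curve off the centroids.
This operational definition is the package's own, since the statistic is
used in the field as a QC check without a published formula.

Properties verified in the test suite: unit-sphere thickness is exactly 1
against a centroid-degenerate curve; a capped-cylinder phantom recovers
its radius on the lateral wall to 1%; a bent-tube phantom tracks the
analytic arc centerline within 5% of the tube radius; thickness is
invariant under rigid motion to 1e-9 mm and never increases when the
curve sampling is refined.

## The synthetic cohort

`simulate_cohort()` draws patients and controls with the demographic
structure of a large multi-cohort PD sample: patients 63.7 ± 9.8 years
and 35% female, controls 60.0 ± 12.2 years and 46% female; subjects are
spread over several acquisition cohorts with small cohort-level shifts in
mean age and head size. Clinical scores follow the monotone stage gradient
that motivates ordinal staging — time since diagnosis rises from about
2.5 years at HY1 to about 12.5 at HY5, MoCA falls from 27 to 21, and
MDS-UPDRS3 rises from 20 to 55 — with missingness generated completely at
random at roughly the rates such consortium data show (about half of
patients lack MoCA and UPDRS3). Modified stages 1.5 and 2.5 are generated
and regrouped into stage 2 by `regroup_stage()`, mirroring field practice;
`group_stages()` merges severe stages (HY45 for mass-univariate contrasts,
HY345 for the three-class ordinal classifier).

`simulate_thickness()` is the generative mirror of the fitted model:

```
thickness(i, v) = baseline(v) + beta_age (age_i - 65) + beta_sex sex_i
                + beta_icv (icv_i - 1.5e6) + u_cohort(i)
                + delta_v(stage_i) + eps_iv
```

with `baseline` the atlas template's own radial thickness,
`u_cohort ~ N(0, 0.1^2)` mm, `eps ~ N(0, 0.2^2)` mm i.i.d., and `delta` a
sum of geodesic-Gaussian bumps (amplitude at 3-hop to 6-hop scale,
0.1–0.3 mm — the scale of reported peak vertex effects). The default
effect specification encodes the qualitative staging pattern of the
disease as a generative target: putamen thinning growing from the mildest
stage, caudate and amygdala joining at stage 2, hippocampus, accumbens and
thalamus at stage 3, pallidum only at stages 4–5, plus a focal thalamic
subregion that is *thicker* at stages 1–2 and normalizes later. The
residual SD of 0.2 mm and cohort SD of 0.1 mm are the package's choice of
a realistic vertex-noise regime for subcortical surface data.

What the generator does *not* emulate: scanner- or sequence-specific
effects beyond a cohort intercept, left/right symptom asymmetry, spatially
correlated noise, registration error, or any MRI intensity process.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated model, not that real acquisitions meet
these assumptions.

Control matching is greedy nearest-neighbour without replacement on
standardized covariate distance (age by default), with sex an exact-match
constraint (infinite cross-sex distance) and cases processed hardest-first
(descending distance to the control pool); ratio and caliper are
configurable and a seed breaks exact ties. Propensity-score matching is
deliberately not offered — the covariate-distance variant is the one whose
behavior small-instance enumeration oracles can certify.

## Mass-univariate mixed models and searchlight FDR

Each vertex is fit by restricted maximum likelihood with `lme4`:

```
thickness ~ predictor + age + sex + icv + (1 | cohort)
```

Numeric nuisance covariates are standardized internally (the coefficient
of interest is invariant to affine rescaling of nuisance columns, and
conditioning improves); thickness is analyzed in native millimetres.
Inference is a two-sided Wald test with a normal reference — a deliberate
simplification over Satterthwaite degrees of freedom, whose consequence is
quantified by the type-I simulation in the acceptance suite (empirical
size ~0.05–0.06 at five cohorts, n = 400). When the cohort factor has one
level or the variance estimate hits the zero boundary, the fit reduces to
ordinary least squares, which the tests assert exactly. Each vertex is fit
fresh (no warm starting): warm-started refits were observed to stall at
the singular boundary with a measurably worse REML criterion, breaking
permutation equivariance at the 1e-4 level.

Searchlight FDR applies Benjamini–Hochberg at level `q` within each
vertex's geodesic neighbourhood (default radius 5 edge hops); a vertex is
significant iff its own p-value passes its neighbourhood's BH threshold.
Radius infinity reduces exactly to global BH (verified against `p.adjust`
on random p-vectors), and radius 0 on an isolated vertex degenerates to a
single Bonferroni test. The exact neighbourhood construction of the
original searchlight correction is not published; this rule captures its
local-FDR semantics in an oracle-testable form, and the acceptance suite
confirms empirical FDR control at `q = 0.05 + 2 SE` under 90%-null
simulations.

## Spin permutation tests

Spatial similarity between two effect maps on one structure is the Pearson
correlation over vertices, tested against a null built from uniform random
3-D rotations: a unit quaternion is drawn by normalizing a 4-D standard
Gaussian (Haar-uniform by construction), one map is rotated on the shared
registration sphere, and values are resampled by nearest neighbour
(greatest dot product) so the null maps take exactly the data's value set
— bilinear interpolation is deliberately rejected for that reason. The
p-value is two-sided with the add-one permutation estimator:
`p = (1 + #{|null r| >= |r_obs|}) / (1 + N)`, so the smallest attainable
p at N rotations is `1/(N+1)`. Each structure is tested on its own
spherical parameterization. Unthresholded coefficient maps are the
default input; a masked variant simply passes masked maps.

One reading of the usual verbal definition of this p-value would count how
often the observed correlation *exceeds* the null draws, which would send
the strongest effects toward p = 1; the package implements the
conventional exceedance direction (null at least as extreme as observed),
which is the only direction consistent with reporting large correlations
at small p.

For simulation studies, `spin_permutations()` precomputes the
nearest-neighbour permutation of each rotation so one rotation set can be
shared across many tests on the same sphere; conditional on the rotation
set, tests of independent map pairs are i.i.d., which is what the type-I
simulation in the acceptance suite exploits.

## Structured-sparsity classifiers

The binary classifier (Logit-TVL1) minimizes class-weighted logistic loss
plus `lambda_l1 ||w||_1 + lambda_tv TV(w)`, where
`TV(w) = sum_{(i,j) in edges} |w_i - w_j|` is the anisotropic graph total
variation over the mesh adjacency — the discretization standard for
structured sparsity on graphs, chosen because its prox is computable by
convex duality. The ordinal classifier (Ordit) shares the weight vector
across K ordered classes through a cumulative-logit (proportional-odds)
likelihood, `P(stage <= k | x) = sigmoid(theta_k - w'x)`, with thresholds
kept strictly increasing by a softplus parameterization of their
increments. The proportional-odds form honors "ordered, but no assumed
functional relationship" at the link level while keeping a single
progression direction; an all-threshold loss was rejected for parsimony.
At K = 2 the ordinal objective equals the binary one under
`theta_1 = -intercept`, which the acceptance suite verifies to 1e-6 on
random instances.

**Solver.** Monotone accelerated proximal gradient (FISTA with a
best-iterate safeguard), backtracking line search, and function-value
adaptive restart; the recorded objective trace is non-increasing by
construction. The TV prox is solved on the dual — projected accelerated
gradient on the box-constrained quadratic — warm-started across outer
iterations, with a duality-gap certificate (`gap <= tol^2 / 2` guarantees
infinity-norm accuracy `tol` by strong convexity, floored at float
rounding level). The composite prox of the L1 + TV penalty uses the exact
fused-lasso prox decomposition — soft-thresholding applied to the TV prox
output — rather than approximate alternation between the two proxes; the
decomposition is exact on general graphs and is validated against a
box-QP oracle on all small instances. Convergence is declared by a
windowed stall test (relative objective decrease below `tol` per iteration
averaged over 10 iterations), which is robust to the inexact inner proxes
used during cross-validation.

**Cross-validation.** Nested, stratified, 4-fold outer and inner by
default. The inner grid search runs over L1/TV strengths expressed as
fractions of the data-dependent `lambda_max` (the smallest L1 strength
that zeroes the weights), a 5 x 5 logarithmic grid by default. Selection
uses the one-standard-error rule: among grid points whose mean inner
metric is within one standard error of the best, the most-penalized
(sparsest, smoothest) pair wins. Exact-tie breaking toward the larger
penalty is available as `select = "best"`, but with a saturated metric
(inner AUC near 1) exact ties are seed-unstable, whereas the 1-SE rule is
the canonical choice for interpretable sparse models. Binary tasks use
rank-formula
ROC-AUC (verified against an independent implementation); ordinal tasks
use macro-averaged F1, the package's reading of "balanced F1" — flagged
as an interpretation, since the original criterion is not printed.
Imputation is training-column means only (no test leakage, asserted by a
shifted-distribution test), and class weights `n_total / (K n_c)` are
recomputed inside every training fold. A one-against-all comparator is
available as repeated binary fits. Weight maps are reported in SD units
of the learned weights.

## Pipeline

`run_pipeline()` executes the full sequence from one configuration:
atlas, cohort and thickness simulation; input validation (returning
machine-readable issues, not errors); case-control and per-stage
contrasts against age- and sex-matched controls; clinical-score
correlations; spin tests between consecutive stage maps for every
structure; and the four classification tasks (PD vs control, HY1 vs HY2,
HY2 vs HY345, three-class ordinal). Every random stage derives a named
child seed from the master seed, so re-running a configuration reproduces
every numeric output byte for byte (the log file, which carries
timestamps, is the only exception). Any stage failure aborts with the
stage named and leaves a `FAILED` marker beside the partial outputs. A
thin command-line wrapper (`inst/exec/shapestage`) exposes the same
operations as subcommands; the R functions are the primary interface.

## Problem sizes and numerical defaults

The shipped demonstration configuration uses a four-structure atlas (162
vertices per structure), a cohort of about 400 subjects over four
acquisition cohorts, 200 spin rotations, and a 2 x 2 inner grid — sizes
chosen so the full pipeline runs in a few minutes on one core while still
exhibiting every phenomenon of interest (planted-effect detection at
`q = 0.05`, a null structure staying unflagged, above-chance staging).
The acceptance suite runs the ordinal recovery at the full 27,120-vertex
default atlas with ~425 patients. Solver defaults: outer tolerance 1e-10
(relative, windowed), prox duality-gap certificate for 1e-5 accuracy,
2000 inner dual iterations when run standalone; cross-validation uses
deliberately looser inner settings (prox accuracy 1e-3, 50 warm-started
inner iterations, 150–400 outer iterations), which the reference-solve
test shows costs less than 1e-5 in final objective on small instances.

## Known limitations

* Wald-normal inference is slightly liberal with few cohorts; users with
  very small cohort counts should interpret borderline vertices
  cautiously.
* The medial curve is a 1-D centerline; structures with sheet-like or
  branching medial geometry (thalamus in particular) are summarized more
  coarsely than a full medial-surface method would allow.
* The searchlight FDR rule controls FDR empirically under the simulated
  independent-noise regime; under strong spatial noise correlation its
  behavior, like that of any local FDR rule, is not guaranteed.
* The generator's noise is spatially independent by design, which makes
  planted-signal recovery easier than on real surfaces with correlated
  residuals; classifier performance numbers on synthetic data are not
  comparable to performance on consortium data.
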