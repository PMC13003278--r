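---
title: "Methods: SAR prediction for iron oxide nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAR prediction for iron oxide nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sarqspr)
```

This vignette documents the modelling assumptions, parameter choices and
numerical decisions behind `sarqspr`. The package predicts the specific
absorption rate (SAR, W g⁻¹) of superparamagnetic iron oxide nanoparticles
(SPIONs) under an alternating magnetic field from tabular
physicochemical/magnetic descriptors, and quantifies the uncertainty and the
drivers of those predictions.

## The problem and the data model

Magnetic hyperthermia performance is reported across hundreds of papers with
incompatible conventions: magnetization in emu g⁻¹, emu cm⁻³, Am² kg⁻¹ or
kA m⁻¹; coercivity in Oe or mT; SAR normalized per gram of nanoparticle, of
iron, or of total metal. A pooled regression is meaningful only after
harmonization. The package fixes canonical units (Oe, kHz, mg mL⁻¹, K, nm,
emu g⁻¹, W g⁻¹ nanoparticle) and converts with the composition arithmetic of
doped magnetite M~x~Fe~3−x~O₄ and fixed atomic weights (Zn 65.4, Co 58.9,
Mn 54.9, Mg 24.3, Fe 55.84, O 15.999 g mol⁻¹). Conversion constants:
1 mT ≡ 10 Oe ≡ 0.7958 kA m⁻¹ for fields, 1 Am² kg⁻¹ ≡ 1 emu g⁻¹, and an
average particle density of 5 g cm⁻³ for volume-referenced magnetizations.
"Room temperature" parses to 300 K, a "negligible" remanence to 0 emu g⁻¹.
Maghemite records are rejected at ingest — γ-Fe₂O₃ cannot be expressed in the
M~x~Fe~3−x~O₄ frame — and core diameters are capped at 30 nm, the size regime
where superparamagnetic behaviour is expected.

The predictive matrix has exactly 30 columns: 17 numeric (H, f, C_SPION, T,
d_TEM, std_dTEM, A_core, V_core, A/V ratio, Ms, Mr, Hc, Mr/Ms squareness,
and the four dopant–iron ratios) and 13 binary (five mutually exclusive shape
indicators, five coating descriptors, three medium descriptors).
`validate_schema()` enforces the frozen schema. Two naming/encoding decisions
were genuinely open and are fixed as follows: the squareness feature is
Mr/Ms ∈ [0, 1] (the physically standard remanence ratio), and the
dopant–iron ratio is encoded as the doping fraction x itself, with the molar
ratio x/(3−x) available via `dopant_ratio_features(mode = "molar")`.

## Core geometry models

Five idealized solids map the microscopy diameter d_TEM to surface area and
volume:

* **sphere**: diameter d_TEM;
* **cube**: edge d_TEM;
* **nanoflower**: thirteen identical tangent spheres of radius d_TEM/6 — one
  core and twelve petals placed at icosahedron vertices (distance 2r, the
  unique arrangement in which twelve equal spheres touch a central one
  without overlapping). The *area* descriptor counts the twelve petals only:
  the central sphere is internal to the cluster and not an accessible
  surface. The *volume* counts all thirteen spheres;
* **octahedron**: regular octahedron resting on a face, with the adjacent
  face tilted at an external angle β₁; d_TEM is the projected height, giving
  edge l = d_TEM / (√(3/4)(1 + cos β₁)), A = 2√3 l², V = (√2/3) l³;
* **octopod**: a central cube with a regular tetrahedron on each corner whose
  three base vertices sit on the midpoints of the three cube edges meeting at
  that corner. The tetrahedron edge is then l = cube edge / √2, with
  l = d_TEM / (1 + 2√(3/4) cos β₂) from the projected diameter. Exact union
  arithmetic — each corner tetrahedron shares exactly half its volume with
  the cube corner simplex, and each corner hides three l²/4 right triangles
  of cube face — gives A = 6l² + 6√3 l² and
  V = 2√2 l³ + 8 l³/(6√2) − 2 l³/(3√2) = (7√2/3) l³.

Both model angles default to cos β = 1/3 (≈70.53°, the inter-face geometry of
a regular octahedron) and are configuration parameters because the tilt of a
particle resting on a support is a modelling assumption, not a measurement.

Rather than trusting the composite closed forms, `mc_area_volume_oracle()`
validates them by constructive-solid-geometry sampling: volume by
point-membership sampling in a bounding box, area by sampling points on each
primitive's surface and testing occlusion against the other primitives'
interiors (exact primitive areas, estimated exposed fractions). Both
estimates carry Monte-Carlo standard errors, and the test suite asserts
agreement within three standard errors at 10⁶ points for all five shapes,
plus the exact scale laws A(kd) = k²A(d), V(kd) = k³V(d).

## The synthetic-data generator

The generator is the test bed for the whole pipeline: it emulates the
statistical structure of a literature-curated SPION corpus while providing a
known ground truth. Its defaults are fixed once and define the study
conditions for all tests:

* numeric marginals are truncated log-normals, giving the right-skewed
  distributions typical of curated literature data: H with median 150 Oe
  (log-sd 0.5) truncated to [20, 500] Oe; f median 150 kHz (log-sd 0.55) on
  [40, 800] kHz, so most records sit below 400 kHz; concentration median
  2 mg mL⁻¹ on [0.1, 20]; d_TEM median 12 nm (log-sd 0.3) on [4, 30] nm;
  Ms median 55 emu g⁻¹ on [5, 100]; small squareness Mr/Ms ~ Beta(1, 8)
  (superparamagnetic regime, Mr ≤ Ms by construction);
* categories are dominated by spheres (70%) and coated particles (80%),
  with dopants mostly absent (65% undoped) and doping fractions
  x ~ Beta(1.2, 6), concentrated near zero;
* the ground-truth SAR is
  κ·H^a·f^b·exp(−log²(d/d_opt)/(2w²))·(1 + γ_Co x_Co − γ_Zn max(0, x_Zn−0.1))·exp(−δC)
  with defaults κ = 7·10⁻⁵, a = 2, b = 1, d_opt = 16 nm, w = 0.6,
  γ_Co = 0.5, γ_Zn = 0.8, δ = 0.04 mL mg⁻¹. The form is deliberately
  flavoured like linear-response heating theory — SAR rising as a power law
  in field amplitude and frequency, a bell-shaped optimum in core size, a
  concentration decay from dipolar interactions, cobalt doping helping and
  zinc doping beyond x = 0.1 hurting — so that attribution methods have a
  known ranking to recover (H first, f second) and monotonicity invariants
  are testable. The exponents a = 2, b = 1 make typical SAR values sit mostly
  below 500 W g⁻¹ at the marginals above, matching the curated corpus'
  reported range;
* observed SAR is the noiseless truth times (1 + ε), ε ~ N(0, 0.1): a 10%
  relative measurement error, a realistic calorimetric reproducibility
  figure.

What the generator does **not** emulate: inter-laboratory systematic offsets,
correlated reporting errors, missing-data patterns, label noise in shape
classification, and any dependence of SAR on coating/medium chemistry (those
features are pure distractors in the truth). Passing tests therefore
demonstrate that the pipeline recovers a recoverable signal under realistic
marginals and noise — not that the real literature corpus is this benign.

## Splitting, weights and transforms

The stratification label concatenates shape|dopant|coating. Class weights
follow five steps: reciprocal class counts, division by the minimum,
log1p damping, a second division by the minimum, and per-row assignment — so
the most frequent class has weight exactly 1 and rarer classes monotonically
larger weights (e.g. counts {100, 10} give weights {1, log 11 / log 2 ≈ 3.4594}).

The split is 70/10/10/10 into train/validation/calibration/test, stratified
by label. Labels with fewer than four members are pooled into a "rare"
stratum (a four-way stratified split needs at least four members; the choice
of four is the minimal one). Subset counts use controlled rounding: each
label's counts stay within one record of its exact proportions while the
global totals equal the largest-remainder apportionment of n — a 1000-row
table splits exactly 700/100/100/100. The default seed is 42.

Features are min–max scaled to [−1, 1] on training statistics only; binary
columns pass through the same affine map (0 → −1, 1 → +1), matching blanket
scaling of all 30 features. Zero-range features map to the constant 0 with a
warning. The SAR target is Yeo–Johnson transformed with λ fitted on the
training target by maximum likelihood (via `car::powerTransform`); the
inverse transform is applied before any reported metric, so all headline
numbers are in W g⁻¹.

## Model families and hyperparameter search

Twelve families: L1-, L2- and elastic-net-penalized linear regression
(glmnet), partial least squares (mixOmics), RBF-kernel support vector
regression (e1071), k-nearest neighbours (caret), a decision tree (rpart), a
random forest (ranger), three gradient-boosting variants (xgboost: depth-wise
growth, DART dropout trees, and leaf-wise "lossguide" growth — three distinct
boosting regularization philosophies), and a feed-forward neural network
(nnet; a single hidden layer with searched width 4–64 and weight decay — the
widths, not the architecture, are searched at desk scale). Per-row class
weights are consumed natively by the penalized linear models, tree, forest,
boosting and network fits; for SVR, KNN and PLS the weights enter only the
search objective. A constant training target short-circuits every family to
a constant predictor (several backends reject zero-variance responses).

The search minimizes validation wRMSE (on the transformed target scale, where
the optimization is well conditioned). The sampler is a univariate
tree-structured-Parzen-style estimator written for this package: after 10
random startup trials, trials are split into the best 25% ("good") and the
rest, candidates are drawn from a Gaussian kernel density over the good
values (log-space for log-scaled parameters, Silverman-style bandwidths,
bounded by clamping), and the candidate maximizing the good/bad density ratio
is proposed — independently per parameter, each proposal conditioned on the
full history. The whole search is deterministic under a fixed seed. Search
spaces span standard ranges per family (tree depths 2–12, learning rates
10⁻³–0.3, penalties 10⁻⁴–10, etc.) and are overridable. The desk-scale
default is 100 trials (50 in the end-to-end tests); full-scale studies use
1000.

Boosting trials early-stop when validation wRMSE fails to improve for 20
rounds (depth-wise and DART variants) or 30 rounds (leaf-wise variant),
within a 600-round budget; the final refit uses the same budget and stopping
rule so the selected configuration is refit under the conditions it was
scored under.

Trial selection is gap-based: find the lowest validation wRMSE, keep trials
within 10% of it, and among them pick the smallest overfitting gap
(validation − training wRMSE). The gap is taken in absolute value so that
underfit flukes with large negative gaps are not rewarded; ties resolve to
the earliest trial. An alternative reading — keep the top 10% of trials by
validation rank — is available as `select_best_trial(mode = "top_fraction")`.
For epoch-trained learners, `choose_epochs()` applies the same principle on a
learning curve: within a plateau range, the epoch minimizing |validation −
training| wRMSE, earliest on ties.

## Metrics, conformal intervals, attributions

`compute_metrics()` reports R², MAE, MedAE, RMSE and wRMSE
(√(Σwᵢ(yᵢ−ŷᵢ)²/Σwᵢ)), all on inverse-transformed W g⁻¹ values; wRMSE reduces
exactly to RMSE under uniform weights. The AE-spread statistic is the
population standard deviation of the absolute errors (the definition is a
package choice; the sample/population distinction is immaterial at the n
involved).

Split-conformal intervals use the absolute residual as nonconformity and the
exact finite-sample order statistic: q is the k-th smallest calibration
residual with k = ⌈(n_cal + 1)(1 − α)⌉, capped at the maximum residual.
Intervals are symmetric ŷ ± q, which matches the symmetric ±width reporting
convention for SAR intervals; normalized or quantile-regression conformal
variants are out of scope. Width-by-range analysis recalibrates q on the
calibration rows whose *measured* SAR falls in each expected range (0–1000,
0–500, 0–250, 0–100 W g⁻¹ by default); ranges with fewer than 10 calibration
rows are flagged rather than estimated. Conditioning on calibration rows is
an interpretation — the alternative (keep the global q, report per range) is
available via `condition = "test"`.

Redundancy analysis clusters features by Ward ("minimum variance")
agglomeration on the distance 1 − |ρ| over Spearman correlations, reporting
maximal dendrogram nodes whose members are all pairwise |ρ| ≥ 0.7. The
absolute value makes strongly negative pairs cluster together (a plain 1 − ρ
distance is available via `absolute = FALSE`). Permutation importance is the
mean RMSE increase over ten shuffles of each column.

Shapley attributions are computed by permutation sampling against a
background set (the training subset, subsampled to at most 500 rows): for
each of n_perm (permutation, background-row) pairs — fixed across explained
rows — features are switched one at a time from background to explained
values and the marginal prediction changes are credited to the switched
feature. The telescoping construction makes local accuracy (base +
Σ attributions = prediction) exact to floating point for every row at any
n_perm; the attributions themselves are Monte-Carlo estimates that are exact
for additive predictors and converge as n_perm grows (default 32; the tests
validate against an exhaustive-subset oracle). The explained function is the
*composition* of the fitted model with the inverse target transform, so
attributions are in W g⁻¹ and the impact bands apply: considerable (> 10% of
the total mean |attribution|), moderate (5–10%), weak (1.5–5%), negligible
(< 1.5%), with band boundaries lower-inclusive. Shares of the attribution
total (rather than of predicted SAR magnitude) are the primary criterion,
since the absolute W g⁻¹ bands are only meaningful at a particular corpus
scale.

## Literature screening

Screening scores a title+abstract by summing weights over every occurrence
of mapped word n-grams (n ≤ 3), case-insensitively; occurrences, not distinct
keywords, are counted (the alternative was undocumented in the original
workflow; occurrence counting is the stricter, additive choice). N-grams do
not cross punctuation boundaries, which keeps the score additive over
sentence-separated concatenation. Eligibility detection splits text into
sentences on terminal punctuation + whitespace (a trained sentence tokenizer
is not behaviour-critical here) and emits a hit whenever a sentence contains
a feature synonym and a number immediately followed by one of that feature's
units; numbers parse with decimals and scientific notation, and unicode
minus signs are normalized. Unit tokens that are unambiguous for a feature
(kHz, Oe) may be listed among its synonyms, so "at 300 kHz" attributes to the
field frequency without the word "frequency". The shipped YAML lexicons cover
the eight predictive hyperthermia features plus SAR and are deliberately
replaceable: real screening vocabularies are corpus-specific.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale: synthetic corpora
of 500–2600 rows, 50-trial searches for the end-to-end recovery check,
20-seed coverage studies (n_cal = 200, n_test = 500), 10⁵–10⁶-point geometry
oracles, and 16–32-permutation attribution draws. These sizes were chosen so
the full pipeline exercises every contract in minutes on one CPU; the same
functions scale to the full-study settings (1000 trials) by changing
arguments.

Known limitations: the octopod/octahedron angles and the nanoflower
petal-count are idealizations, not fits to micrographs; the screening
tokenizer is rule-based; PLS, SVR and KNN ignore row weights during fitting;
the DART booster's stochasticity is controlled by seed but its early-stopped
round count can differ across xgboost versions; conformal validity is
marginal, not conditional — the width-by-range analysis is descriptive, not a
conditional-coverage guarantee; and conclusions about feature importance on
synthetic data transfer to real corpora only insofar as the generator's
assumptions hold.
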