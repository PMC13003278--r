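# sarqspr

Machine-learning pipeline for predicting the **specific absorption rate
(SAR)** of superparamagnetic iron oxide nanoparticles (SPIONs) in magnetic
hyperthermia from their physicochemical, magnetic, and field-exposure
properties.

SPIONs heat when driven by an alternating magnetic field; SAR (W g⁻¹) is the
heating power per unit nanoparticle mass, and it depends on the field
amplitude *H* and frequency *f*, the suspension concentration, the core size
and morphology, the doping stoichiometry M<sub>x</sub>Fe<sub>3−x</sub>O₄
(M ∈ {Zn, Mn, Co, Mg}), the magnetic state (M<sub>s</sub>, M<sub>r</sub>,
H<sub>c</sub>), and coating/medium chemistry. Literature reports of these
quantities are heterogeneous in units and normalization, which is the main
obstacle to pooled quantitative structure–property (QSPR) modelling. This
package implements the full analysis chain as tested, reusable R functions:

1. **Literature screening** (`score_record`, `rank_and_select`,
   `detect_feature_sentences`) — keyword n-gram relevance scoring and
   sentence-level detection of (feature synonym, numeric value, unit)
   co-occurrences, with replaceable YAML lexicons.
2. **Harmonization** (`magnetization_to_emu_per_g`, `coercivity_to_oe`,
   `sar_to_w_per_g_np`, `molar_mass`, …) — canonical units (emu g⁻¹, Oe, K,
   W g⁻¹ nanoparticle) via the composition arithmetic of
   M<sub>x</sub>Fe<sub>3−x</sub>O₄ (1 mT ≡ 10 Oe ≡ 0.7958 kA m⁻¹;
   1 Am² kg⁻¹ ≡ 1 emu g⁻¹; SPION density 5 g cm⁻³).
3. **Core geometry** (`core_area_volume`, `mc_area_volume_oracle`) —
   closed-form surface area A<sub>core</sub> and volume V<sub>core</sub> for
   five morphologies (sphere, cube, 13-sphere nanoflower, octahedron,
   octopod), validated against a Monte-Carlo constructive-solid-geometry
   oracle.
4. **Feature table** (`build_feature_table`, `validate_schema`) — the frozen
   30-feature predictive matrix (17 numeric + 13 binary) plus the SAR target.
5. **Split / weights / scaling** (`stratified_split`,
   `compute_class_weights`, `fit_feature_scaler`) — stratified
   70/10/10/10 train/validation/calibration/test split on the
   shape|doping|coating label, five-step log-damped class weights, [−1, 1]
   min–max feature scaling and a Yeo–Johnson target transform fitted on the
   training subset only.
6. **Model search** (`run_search`, `select_best_trial`, `train_final`) —
   twelve regression families tuned by a sequential model-based
   (Parzen-estimator) sampler minimizing validation **wRMSE**
   (√(Σwᵢ(yᵢ−ŷᵢ)²/Σwᵢ)), with early stopping for the boosting families and
   overfitting-gap trial selection: among trials within 10% of the best
   validation wRMSE, pick the one with the smallest |validation − training|
   gap.
7. **Evaluation and uncertainty** (`compute_metrics`, `conformal_calibrate`,
   `width_by_range`) — R², MAE, MedAE, RMSE, wRMSE in original W g⁻¹ units;
   split-conformal symmetric prediction intervals at α = 0.10 with the exact
   finite-sample order statistic q = k-th smallest calibration residual,
   k = ⌈(n+1)(1−α)⌉.
8. **Interpretation** (`spearman_matrix`, `cluster_correlated`,
   `permutation_importance`, `shapley_attributions`, `categorize_impact`) —
   redundancy clustering at |ρ| ≥ 0.7, permutation importance, and
   permutation-sampled Shapley attributions in W g⁻¹ with impact bands
   (considerable > 10%, moderate 5–10%, weak 1.5–5%, negligible < 1.5% of the
   total mean |attribution|).

A synthetic-data generator (`synthetic_config`, `generate_dataset`) emulates
the statistical structure of the curated literature corpus — right-skewed
marginals, dominant spherical/coated categories, dopant fractions near zero —
with a known ground-truth SAR law (power law in *H* and *f*, log-normal size
bell, dopant and concentration modifiers), so every stage is testable without
external data.

## Worked example

```r
library(sarqspr)

pipe <- run_sar_pipeline(config = synthetic_config(n_samples = 2000, seed = 1),
                         family = "gb_depthwise", n_trials = 50, seed = 1)
print(pipe$metrics, digits = 3)
#>        subset    r2  mae medae rmse wrmse ae_sd
#> 1       train 0.971 26.4  10.4 70.9  59.2  65.8
#> 2  validation 0.969 26.8  11.8 53.9  48.1  46.8
#> 3 calibration 0.979 29.3  11.4 52.4  53.2  43.5
#> 4        test 0.983 29.0  11.2 61.6  49.9  54.3
```

The tuned depth-wise boosting model explains ~97% of the SAR variance on the
held-out validation rows in original W g⁻¹ units, with a mean absolute error
around 27 W g⁻¹ on this synthetic corpus. The calibrated 90% conformal
interval and the Shapley drivers:

```r
pipe$interval$q
#> [1] 82.2   # half-width in W/g: intervals are prediction +/- 82.2

Xtr <- transform_features(pipe$scaler, pipe$table[split_rows(pipe$split, "train"), ])$X
Xte <- transform_features(pipe$scaler, pipe$table[split_rows(pipe$split, "test"), ])$X
shapley_attributions(pipe$predictor, Xtr, Xte, n_perm = 24, seed = 1)
#> <attribution_report> 200 rows, base value 355.399
#>   top features (mean |attribution|):
#>     H                               287.483  [considerable]
#>     f                               153.689  [considerable]
#>     d_TEM                            34.573  [moderate]
#>     C_SPION                          22.067  [weak]
#>     A_core                           13.262  [weak]
```

The attribution ranking recovers the generator's ground truth: field
amplitude (quadratic in the truth) dominates, frequency (linear) is second,
and the size bell and concentration decay follow — the qualitative ordering
expected from linear-response heating theory.

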