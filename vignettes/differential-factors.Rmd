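---
title: "Parsing individual brain deviations into differential factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing individual brain deviations into differential factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devfactor)
```

## The problem

Case-control comparisons of regional brain measures such as ALFF (the
amplitude of low-frequency fluctuations in resting-state fMRI) average over
patients, yet individual patients deviate from the healthy norm in very
different places: the proportion of patients sharing an extreme deviation in
any single region is typically small. `devfactor` implements a dimensional
answer: each patient's regional deviation profile is modeled as a
non-negative weighted sum of a small number of *differential factors* —
spatial patterns shared across the cohort — so that heterogeneity lives in
the patient-specific weights rather than in a single group map.

The pipeline is: ComBat site harmonization → per-region Gaussian-process
normative models on healthy controls → patient deviation Z-scores → signed
split and non-negative matrix factorization (NMF) with split-half rank
selection → characterization of the factors against group maps, clinical
scores, a structural-covariance network (epicenters), receptor and
gene-expression maps → Gaussian-mixture subtyping of the factor
compositions.

## Models and procedures

### Site harmonization (ComBat)

Regional values are adjusted per site with the parametric empirical-Bayes
location/scale model: values are standardized with a covariate model (we
protect age, sex and diagnosis by default, so group differences survive
harmonization), per-site means and variances are shrunk toward pooled
priors (normal for location, inverse-gamma for scale), and the adjustment
is inverted without the site terms. `combat_fit_transform()` returns the
standardization coefficients and the per-site `gamma*`/`delta*` estimates.
Harmonization is applied once per dataset, before normative modeling. With
a single region the empirical-Bayes priors (estimated across regions) are
undefined and the raw per-site estimates are used unshrunk.

### Normative modeling

For every region, an exact GP regression of the harmonized value on age and
sex is fitted on controls by maximizing the marginal likelihood
(analytic-gradient L-BFGS-B, three fixed-seed restarts; ties resolved by
best likelihood then restart order). The kernel is a sum of a squared
exponential over standardized age and the binary sex input (each with its
own length scale), a linear age term, and white noise — flexible enough for
smooth lifespan curves yet identifiable with two covariates. A subject's
deviation is

\[ Z = \frac{y - \mu(x)}{\sqrt{\sigma^2(x) + \sigma_n^2}}, \]

the departure from the *full* predictive distribution (latent predictive
variance plus observation-noise variance); the source study does not print
the formula, so including both terms is this package's documented choice —
it is what makes `|Z| > 2.6` correspond to a per-tail normal probability
below 0.005 on calibrated data. Predictive calibration is evaluated as the
standardized MSE (test MSE divided by test variance; 1 is the
irreducible-noise benchmark) under repeated k-fold, leave-one-site-out, or
cross-dataset schemes.

For reference-scale cohorts the cubic cost of hyperparameter search is cut
with `hyper_subsample`: kernel hyperparameters are optimized on an
age-stratified subsample, the noise variance — which drives Z calibration —
is then re-optimized one-dimensionally on the full cohort, and the GP is
conditioned on all controls. Calibration checks in this package train on
1000 controls, the scale of the reference cohorts normative models are
typically fitted on; with much smaller training sets the per-region noise
estimate alone carries ~10% sampling error, which visibly inflates or
deflates fresh-data Z variances.

### Differential factors

NMF needs non-negative input, so the Z matrix is split into
`pos = max(Z, 0)` and `neg = max(-Z, 0)` and each bank is factorized
separately (`Z = pos - neg` exactly). The factorization `X ≈ W F` is
solved by HALS coordinate-block updates (implemented in C++), with
non-negative-double-SVD initialization plus seeded random restarts; the
objective trace is monotone non-increasing and the best restart is kept.
Out-of-sample compositions come from row-wise non-negative least squares
(`project_weights()`).

The factor count K is chosen by the split-half generalizability error:
patients are split at random into halves, an NMF is fitted on each, and
in-sample (`e11`, `e22`) and cross-projected out-of-sample (`e12`, `e21`)
mean absolute reconstruction errors are recorded over repeated splits
(candidates 2–10 by default). Two GE definitions are implemented behind
`form=`. The default is the out-of-sample *excess*
`GE = ((e12 - e11) + (e21 - e22)) / 2`: projecting held-out rows onto a
larger non-negative cone never increases their reconstruction error, so the
plain mean `(e12 + e21)/2` is non-increasing in K and cannot show the
interior minimum that rank selection relies on; the excess form penalizes
factor counts that fit the training half without generalizing and recovers
planted ranks reliably. Ties in the repeat-mean GE go to the smaller K.

Factors from different fits or cohorts are paired by the Hungarian
algorithm on the spatial correlation matrix (analytic two-sided p per pair,
Benjamini–Hochberg across pairs). Per patient, the variance explained by
the factors is the adjusted R² of an OLS of the signed Z vector on the
signed factor maps (negative-bank maps entered negated, intercept
included); a permutation null refits the whole signed-split + NMF pipeline
on row-wise shuffled Z matrices (shuffling within rows preserves each
patient's deviation distribution) with the add-one-smoothed p-value
`(1 + #{null ≥ obs}) / (1 + n_perm)`.

### Group-level and clinical statistics

The group difference map is the group coefficient of a region-wise OLS of
value on group plus covariates (age, sex, dummy-coded site, mean framewise
displacement) — the standard regression form of a covariate-adjusted
two-sample t test, to which it reduces exactly without covariates. The
unthresholded t vector is then regressed on the signed factor maps;
significance is a permutation test shuffling the t vector across regions
(plain exchangeability; no spatial-autocorrelation-preserving null — the
output records this). Composition contrasts report the group t, Cohen's
d derived from it as `d = 2t/√df` (covariates preclude the raw pooled-SD
formula), and BH-FDR across factors; composition-score associations are
Pearson correlations with Fisher-z intervals.

### Structural-covariance epicenters

The SC network correlates, across subjects, region volumes residualized on
age, age², and sex; negative correlations are clipped to zero and the
diagonal is zero. The neighbor statistic is
\( D_i = N_i^{-1} \sum_{j \ne i,\ SC_{ij}>0} SC_{ij} F_j \) with \(N_i\)
the neighbor count (self-connections excluded; dividing by the summed
connection strength instead is available via `normalize = "strength"`).
Epicenter likelihood is the mean of the ascending ranks of F and of D
(average ranks on ties; larger values ⇒ larger ranks, so epicenters are
high-rank regions), with per-region permutation p-values from shuffling F
across regions. The likelihood is exactly rank-invariant in its F half;
because D is a weighted mean, monotone transforms of F can swap D ranks at
near-ties, so likelihoods are only essentially (not bitwise) invariant.

### Receptors, dominance, gene expression

Each factor map is regressed on all receptor density maps (Z-scored per
receptor across regions); significance is again a permutation of the
response map, BH-FDR-corrected across factors. Relative importance uses
dominance analysis: R² is computed for every predictor subset (via the
correlation matrix, feasible up to 20 predictors) and each predictor's
total dominance is the average over subset sizes of its mean incremental
R²; totals sum to the full-model R² exactly, and class sums (excitatory /
inhibitory) are reported when the atlas carries class labels. The
inflammation-expression vector Z-scores each gene across regions and
averages over genes; its spatial correlation with each factor gets a
Fisher-z interval and a permutation p.

### Subtyping

Patients are clustered on their factor compositions with full-covariance
Gaussian mixtures fitted for each candidate count (2–10), selected by
`BIC = -2·loglik + params·log N` with ties toward fewer components.
Fitting uses mclust's model-based hierarchical initialization, which is
deterministic — this realizes reproducibility without random restarts;
compositions are used raw by default (`standardize = TRUE` is available).
Cross-cohort stability applies a fitted mixture to a second cohort and
scores agreement with the adjusted Rand index (computed from the
contingency-table formula; `mclust::adjustedRandIndex` serves as an
independent cross-check in the tests). Subtype profiles are
covariate-adjusted t maps versus controls with Bonferroni correction at
`0.05 / n_regions`, plus pairwise clinical contrasts with BH-FDR and an
omnibus test for context.

## The synthetic cohort generator

Every stage is exercised by `generate_cohort()`, which plants ground truth
the analyses must recover:

* **Controls**: per region, a smooth age curve (linear trend plus one
  low-frequency sinusoid, period 40–80 years, random phase), an additive
  sex offset, per-site location/scale effects applied to both groups (so
  harmonization is genuinely exercised), and Gaussian noise
  (`noise_sd = 0.5` by default).
* **Patients**: the same normative signal plus
  `deviation_scale · (W⁺F⁺ − W⁻F⁻)`. Factor loadings are non-negative
  with near-disjoint regional supports and a designated maximum-loading hub
  per factor; `deviation_scale` defaults to `noise_sd`, so deviations land
  on the Z scale after normative standardization. Default weights put
  factor-affected regions at roughly 2–4 Z units — the extreme-deviation
  regime the analysis targets. The deviation magnitude has no
  published real-data anchor, so it is an explicit free parameter.
* **Subtypes**: weights are drawn from an S-component mixture whose means
  sit at a baseline with one boosted coordinate per subtype; the boost is
  `subtype_separation` (default 3) within-cluster SDs. Recovery tests use
  separation 8, a "well-separated" regime.
* **Clinical scores**: a HAMD-like severity score is a fixed linear
  function of the weights plus noise, clipped to [0, 52].
* **Networks and molecular maps**: `generate_sc_network()` builds a
  block-modular weight matrix with one planted hub per module;
  `generate_molecular_maps()` builds receptor maps whose designated groups
  reconstruct each factor at a target population R² (receptors equal the
  standardized factor plus noise scaled as
  `σ = sqrt(p(1/R² − 1))`), and gene-expression profiles whose averaged
  Z-scored vector correlates with the first factor at an exact target
  (orthogonalized construction, before small per-gene noise).

What the generator does *not* emulate: spatial autocorrelation of real
parcellated maps, non-Gaussian lifespan heteroscedasticity, missing
clinical data, scanner-specific covariance structure, or voxel-level
artifacts. Passing tests therefore demonstrate correctness of the
machinery and recoverability under the stated model, not performance on
real cohorts.

## Numerical choices and problem sizes

* NMF: convergence when the relative objective change drops below 1e-6, or
  500 iterations; GE refits use 2 restarts and 300 iterations.
* GP: log-hyperparameters bounded in [-6, 4]; a 1e-8 jitter stabilizes
  Cholesky factorizations.
* Permutation p-values always use add-one smoothing and so lie in (0, 1].
* Test-suite problem sizes are scaled for quick iteration: 60 regions
  (246 available via `n_regions`), 200 patients, 20 GE repeats, and 60–200
  permutations where the full-scale analysis would use 100 repeats and
  10,000 permutations; `run_pipeline()` exposes all of these in its
  config.

## Known limitations

* Exact GPs scale cubically; `hyper_subsample` mitigates fitting cost but
  scoring very large cohorts still builds dense kernels.
* Permutation nulls for spatial maps do not preserve spatial
  autocorrelation; on real parcellated data they are anti-conservative,
  and results record the permutation scheme used.
* NMF rank selection assumes the two signed banks are independent
  factorizations; deviations that flip sign across patients in the same
  region are split across banks.
* Dominance analysis is exhaustive and refuses more than 20 predictors;
  restrict with `predictor_subset` for larger atlases.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(list(
  simulate = list(n_hc = 200, n_patients = 200, n_regions = 60,
                  n_sites = 3, k_pos = 2, k_neg = 2, n_subtypes = 4,
                  noise_sd = 0.5),
  factors = list(k_range = 2:6, n_repeats = 20),
  n_perm = 200, seed = 7
), out_dir = "devfactor_run")

res$factors$select_pos$k_best       # selected positive-bank factor count
autoplot(res$factors$select_pos$ge) # GE curve
autoplot(res$subtypes)              # BIC trace over subtype counts
res$manifest                        # checksummed artifact list
```
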