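# devfactor

Individual patients with the same psychiatric diagnosis rarely deviate from
the healthy norm in the same brain regions: group-average maps of regional
measures such as ALFF (amplitude of low-frequency fluctuations) hide nearly
patient-specific abnormality patterns. `devfactor` is for researchers who
want to *parse* that heterogeneity instead of averaging over it. It models
each patient's regional deviation profile as a non-negative weighted sum of
a few shared **differential factors**, then characterizes those factors
biologically and uses the patient-specific weights to define subtypes.

The core model: after ComBat site harmonization, per-region Gaussian-process
normative models fitted on healthy controls turn patient data into deviation
scores

    Z = (y − μ(age, sex)) / sqrt(σ²(age, sex) + σ²_noise),

and the patients × regions matrix Z is decomposed, separately for its
positive and negative parts, as

    Z ≈ W F,   W ≥ 0 (patients × K compositions),  F ≥ 0 (K × regions factors),

with K chosen by the split-half generalizability error (NMF fitted on one
half of the patients, the held-out half reconstructed through non-negative
least squares, the out-of-sample excess error minimized over K ∈ 2–10).
Factors are then related to group-level t maps (multilinear models with
permutation tests), clinical scores, structural-covariance epicenters
(mean of value rank and neighbor-statistic rank, D_i = Σ SC_ij F_j / N_i),
receptor maps (dominance analysis over all predictor subsets), and averaged
inflammation-gene expression; compositions feed a Gaussian-mixture subtyping
with BIC model selection and adjusted-Rand cross-validation. A synthetic
cohort generator with planted factors, site effects, hubs, receptor mixes
and subtype structure makes the whole pipeline testable without any imaging
data.

## Worked example

```r
library(devfactor)

# deviation matrix with 2 positive + 2 negative planted factors
sim <- simulate_deviation_matrix(n_patients = 200, n_regions = 60, seed = 7)
sp  <- split_signed(sim$z)

select_k(sp$pos, k_range = 2:6, n_repeats = 20, seed = 7)$k_best
#> [1] 2

fm <- fit_nmf(sp$pos, 2, seed = 7)
fm
#> <factor_model>
#>   factors: 2  patients: 200  regions: 60
#>   final objective (Frobenius): 70.35 after 68 iterations

match_factors(fm, sim$truth$true_factors[1:2, ])
#> # A tibble: 2 × 5
#>   factor_a factor_b     r        p    p_fdr
#> 1 factor_1 pos_2    0.944 1.64e-29 1.64e-29
#> 2 factor_2 pos_1    0.975 2.15e-39 4.31e-39

fn <- fit_nmf(sp$neg, 2, seed = 7)
ve <- variance_explained(sim$z, fm, fn)
attr(ve, "mean")
#> [1] 0.663
```

The selected factor count matches the planted rank; Hungarian matching
pairs each recovered factor with its planted counterpart at spatial
correlations above 0.94; and the four factors together explain about 66% of
the variance in the simulated deviation profiles (per-patient adjusted R²).
At high subtype separation the compositions recover the planted grouping
exactly:

```r
sim4 <- simulate_deviation_matrix(400, 60, seed = 7, subtype_separation = 8)
sp4  <- split_signed(sim4$z)
w    <- cbind(fit_nmf(sp4$pos, 2, seed = 7)$W, fit_nmf(sp4$neg, 2, seed = 7)$W)
sm   <- fit_subtypes(w, 2:8, seed = 7)
sm
#> <subtype_model>
#>   selected subtypes: 4 (BIC over 2-8)
#>   sizes: 100, 100, 100, 100
adjusted_rand(sm$labels, sim4$truth$true_subtype_labels)
#> [1] 1
```

`run_pipeline()` chains every stage (harmonize → normative → factorize →
stats → network → molecular → subtype) from a config list or YAML file and
writes all intermediates as TSV/JSON with a checksummed manifest. See the
vignette (`vignettes/differential-factors.Rmd`) for the models,
assumptions, parameter meanings and design decisions.

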