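# phbtraj

Heterogeneous trajectories of proactive health behaviors in multimorbid
cohorts: composite scoring, trajectory mixtures, determinants,
contribution decomposition, latent comorbidity classes, and mediation.

## What problem this solves

Middle-aged and older adults living with multimorbidity (two or more
chronic conditions) differ widely in how their self-initiated health
behaviors — exercise, habits such as not smoking or drinking, and social
participation — develop over years of follow-up. phbtraj is aimed at
epidemiologists and health-services researchers working with panel
surveys of such cohorts. It packages the complete analysis chain:

1. **Composite scoring** (`score_behaviors()`): 21 behavior indicators are
   combined into a 0–10 score per subject-wave with the entropy weight
   method — indicator *j* gets weight
   `w_j = (1 - e_j) / Σ_k (1 - e_k)` where
   `e_j = -(1/ln n) Σ_i p_ij ln p_ij` is its information entropy after
   min-max standardization.
2. **Group-based trajectory modeling** (`fit_gbtm()`, `scan_models()`):
   a K-class finite mixture with per-class polynomial mean curves
   `E[y_t | class k] = β_k0 + β_k1 t + β_k2 t²` and pooled normal
   residual, estimated by EM, selected by AIC/BIC/aBIC, classification
   entropy, and the ≥5% class-share and AvePP > 0.7 adequacy rules.
3. **Determinants** (`compare_groups()`, `fit_logistic()`): univariate
   chi-square/rank-sum screens feeding a multivariable logistic model of
   class membership, reported as odds ratios with Wald CIs.
4. **Shapley decomposition** (`shapley_decompose()`): each determinant's
   exact Shapley share of the logistic model's McFadden pseudo-R².
5. **Latent class analysis** (`fit_lca()`, `blrt()`, `map_patterns()`):
   comorbidity patterns from 14 binary condition flags, with a parametric
   bootstrap likelihood-ratio test for the class count.
6. **Mediation** (`fit_paths()`, `bootstrap_ci()`, `subgroup_paths()`):
   direct/indirect effects of education, retirement, age and family size
   on class membership through depression (CES-D-10), with
   `proportion mediated = 100 · indirect / (direct + indirect)` and
   bootstrap percentile CIs, overall and within comorbidity patterns.

A seeded synthetic cohort generator (`cohort_config()`,
`simulate_cohort()`) emulates the panel structure these methods assume —
1,343 subjects × 5 waves, a 91.44%/8.56% declining/improving class split,
an education/retirement → depression → class mediation chain, and two
comorbidity patterns in 37.23%/62.77% proportion — so every estimator can
be validated by parameter recovery. `run_pipeline()` orchestrates all
stages from one config and `write_tables()` emits a CSV/JSON report
bundle with a reproducibility manifest.

## Worked example

```r
library(phbtraj)

cfg    <- cohort_config(n_subjects = 500, seed = 1, indicators = TRUE)
cohort <- simulate_cohort(cfg)

scored <- score_behaviors(cohort$panel)      # entropy-weight scoring
fit    <- fit_gbtm(scored, k = 2, orders = c(1, 2), n_starts = 5, seed = 1)
fit
#> <gbtm_fit> 2 classes, 500 subjects, 5 waves
#>   class 1 (share 0.904, avepp 1.000): 1.683, -0.042
#>   class 2 (share 0.096, avepp 1.000): 1.959, 1.456, -0.190
#>   loglik -1704.36, BIC 3452.22, entropy 1.000, sigma 0.449
```

A slowly declining majority (90.4% of subjects, intercept 1.683, slope
−0.042 score points per wave) separates cleanly (entropy 1.000, AvePP
1.000) from a small improving class whose curve rises and then bends
(negative quadratic term). The scale here reflects the weights refit on
this synthetic sample; scoring with the packaged reference weights
(`score_with_fixed_weights()`) reproduces the generator's 0–10 composite
exactly. Both adequacy rules pass:

```r
adequacy_check(fit)
#>   rule            value threshold pass
#> 1 min_class_share 0.096      0.05 TRUE
#> 2 min_avepp       1          0.7  TRUE
```

Downstream, latent comorbidity classes map onto the two named patterns,
and the path model decomposes each determinant's effect:

```r
bl  <- dplyr::left_join(cohort$baseline, assign_trajectories(fit)[, 1:2], "id")
lca <- fit_lca(bl[, chronic_conditions], k = 2, seed = 1)
map_patterns(lca)[, 1:4]
#>   class share pattern                   match_score
#> 1     1 0.696 cardiometabolic_arthritis       0.566
#> 2     2 0.304 arthritis_stomach               0.954

fit_paths(bl)$effects
#>   exposure          a      b  direct indirect   total proportion_mediated
#> 1 age          0.0105 -0.119 -0.0415 -0.00124 -0.0428                2.90
#> 2 family_size -0.132  -0.119 -0.175   0.0157  -0.159                -9.89
#> 3 education   -0.196  -0.119  0.424   0.0233   0.448                 5.21
#> 4 retirement  -0.622  -0.119  0.226   0.0739   0.300                24.6
```

Here `a` is each exposure's effect on CES-D, `b` the CES-D log-odds of
being in the improving class; education and retirement lower depression
(`a < 0`) and depression lowers the odds of improving (`b < 0`), so both
carry positive indirect effects onto the improving trajectory — e.g.
24.6% of retirement's total effect runs through depression in this draw.

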