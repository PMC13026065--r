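---
title: "Models and methods behind phbtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phbtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbtraj)
library(dplyr)
```

phbtraj studies how proactive health behaviors — self-initiated exercise,
habits, and social participation — evolve over years in middle-aged and
older adults living with two or more chronic conditions, and what drives
the differences. This vignette is the package's own account of the models
it implements, the choices that were genuinely open, and what its synthetic
cohorts do and do not establish about real data.

## The composite behavior score

Behavior at each survey wave is summarized by a weighted combination of 21
indicators spanning three dimensions: health exercise (mild, moderate,
vigorous activity), health habits (smoking, drinking, sleep, napping), and
health social interaction (paired participation/frequency items for eight
kinds of social activity). Weights come from the entropy weight method:
each indicator is min-max standardized to $[0,1]$ — positive indicators as
$(x - \min)/(\max - \min)$, the two negative ones (smoking, drinking)
direction-flipped — and indicator $j$ receives weight

$$w_j = \frac{1 - e_j}{\sum_k (1 - e_k)}, \qquad
  e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}, \qquad
  p_{ij} = \frac{z_{ij}}{\sum_i z_{ij}},$$

with $0\ln 0 := 0$. An indicator whose standardized values are more evenly
spread carries higher entropy, hence less discriminating information and a
smaller weight. The composite $s_i = 10\sum_j w_j z_{ij}$ lives on a 0–10
scale, higher meaning more proactive behavior.

Open choices we fixed once: the exact standardization variant is min-max
with direction flip (it keeps $z \ge 0$, which $p_{ij}$ requires); constant
columns get weight 0 rather than an $\varepsilon$-shift, avoiding
sensitivity to an arbitrary $\varepsilon$; and weights are estimated on all
subject-waves pooled, so one weight set applies to every wave — consistent
with reporting a single weight per indicator. The packaged reference
weights (`indicator_spec()$ref_weight`, percentages summing to 100) let new
data be scored on a fixed weighting via `score_with_fixed_weights()`; they
cannot be re-derived without the original survey microdata and are treated
as a fixture, not an estimation target.

## Group-based trajectory modeling

`fit_gbtm()` fits a $K$-class finite mixture in which a subject in class
$k$ has score
$y_{it} = \beta_{k0} + \beta_{k1} t + \beta_{k2} t^2 + \epsilon_{it}$,
$\epsilon_{it} \sim N(0, \sigma^2)$, with polynomial order 0–2 per class
and a residual SD pooled across classes (the convention of the established
trajectory software). Estimation is EM on the subject-level likelihood;
because the panel is balanced (completers-only design), the weighted
M-step reduces to a least-squares fit of each class's weighted mean
profile, which makes a full fit on 1,343 subjects a sub-second operation.
Initialization is k-means on per-subject OLS (intercept, slope) features
with seeded restarts (`n_starts`, default 10); the best restart by
log-likelihood wins, and the observed-data log-likelihood is asserted
non-decreasing in the unit tests. Classes are relabeled by ascending
intercept so "class 1" is reproducibly the lowest-starting trajectory.

Model selection follows the usual battery: AIC $=-2\ln L + 2q$, BIC
$=-2\ln L + q\ln n$, sample-size-adjusted BIC with $n^* = (n+2)/24$, all
with $n$ the number of subjects and
$q = \sum_k(\text{order}_k + 1) + (K - 1) + 1$; the relative-entropy
classification index $1 - \sum_{ik}(-\hat p_{ik}\ln \hat p_{ik})/(n\ln K)$
(defined as 1 for $K = 1$); and two adequacy rules — every class holds at
least 5% of subjects and every class's average posterior probability
(AvePP) among its assigned members exceeds 0.7. `scan_models()` recommends
the adequate candidate with the lowest BIC, ties toward fewer classes.

Two deliberate simplifications: the outcome family is plain normal — a
censored-normal variant for the bounded 0–10 scale was considered and not
implemented, because simulated scores at the study's parameter values
essentially never touch the bounds, so censoring would add machinery
without changing any estimate; and covariates do not enter the mixture
itself — determinants are related to class membership post hoc, which is
the workflow the downstream modules implement.

## Latent comorbidity classes

`fit_lca()` fits a latent class model to the 14 binary chronic-condition
flags under conditional independence, again by EM with seeded restarts.
Endorsement probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ to keep
the likelihood off the boundary — a numerical guard, not a prior. The
number of classes is tested by `blrt()`, a parametric bootstrap
likelihood-ratio test: simulate from the fitted $(K-1)$-class model, refit
both models per replicate, and report
$p = (1 + \#\{\text{boot} \ge \text{obs}\})/(n_\text{boot}+1)$. The
Lo–Mendell–Rubin test is intentionally out of scope — it depends on
software-specific regularity machinery — so the bootstrap LRT is the one
significance test offered.

Collapsing fitted classes into clinically named patterns is configuration,
not inference: `map_patterns()` labels each class with the rule (a named
set of conditions, e.g. arthritis + stomach disease, or the
cardiometabolic cluster + arthritis) whose conditions have the highest
mean endorsement in that class, with a threshold below which a class is
"other". Several classes may merge into one pattern; the clinical judgment
embodied in a given rule set is the user's.

## Determinants, contributions, mediation

`compare_groups()` screens baseline covariates: Pearson chi-square
(no continuity correction) for categorical variables, Wilcoxon rank-sum
with mid-ranks and the tie-corrected normal approximation for age, family
size, and CES-D; two-sided $p$, significance at 0.05, no multiplicity
correction. Variables passing the screen enter `fit_logistic()`, a
maximum-likelihood logistic regression of class membership (declining
class as reference outcome) reported as odds ratios with Wald 95%
intervals — the standard epidemiological presentation.

`shapley_decompose()` allocates the logistic model's McFadden pseudo-$R^2$
across predictors exactly: all $2^p$ subsets are refit ($p \le 12$
enforced) and each predictor — a categorical predictor with all its dummy
levels counts as one player — receives its Shapley value. The value
function was an open choice; McFadden $R^2$ was adopted for binary
outcomes (with linear $R^2$ available for continuous ones) because the
efficiency axiom then yields percentages that sum to exactly 100.
Per-class contribution tables are computed one-vs-rest per trajectory
class; note that with exactly two classes the two decompositions coincide
mathematically, so distinct per-class columns only arise for $K > 2$.

`fit_paths()` implements the path model: a linear (OLS) equation for the
mediator — CES-D depression score, 0–30 — on the exposures, and a
logistic equation for class membership on exposures plus mediator. For
each exposure, the indirect effect is the product of coefficients
$a \times b$, the direct effect its own outcome-equation coefficient,
total $=$ direct $+$ indirect (an identity the tests check to machine
precision), and the proportion mediated $= 100 \cdot$ indirect/total.
Mixing a linear mediator with a logistic outcome leaves the product scale
ambiguous, so both raw logit-scale products and y-standardized products
(outcome coefficients divided by the implied latent-response SD
$\sqrt{\operatorname{var}(\hat\eta) + \pi^2/3}$) are available; the
proportion mediated is invariant to that choice. Education enters path
models as an ordinal 0/1/2 score so it contributes a single path
coefficient. Confidence intervals are subject-level nonparametric
bootstrap percentiles (default 1,000 replicates; replicates that fail to
converge are dropped and counted, with more than 10% an error), since no
interval construction is canonical here. Subgroup analysis refits the
whole path model independently within each comorbidity pattern.

## The synthetic cohort generator

`simulate_cohort()` produces the data structure all of the above assumes,
at the study's scale by default: 1,343 subjects at five wave times 0–4
(calendar waves 2011–2020 coded as integers; recovery only needs internal
consistency, and the coding is configurable). Baseline covariates are
drawn to match the study's reported margins — 38.57% male, 88.76% married,
63.14% rural, 72% primary education or below, 11.99% retired, 96.35%
insured, median age 59, median family size 3, median CES-D 10, and
three-level IADL/ADL categories whose independent "no difficulty" margins
(0.868 each) give roughly the reported 75.35% joint no-difficulty share.
CES-D depends linearly on education and retirement (`a_edu`, `a_ret`),
the trajectory class on centered age, family size, education, retirement,
and CES-D through configured log-odds (`b` for CES-D) around an intercept
of $\operatorname{logit}(0.0856)$, so marginal class shares stay at
0.9144/0.0856. Observed scores follow the class polynomials — declining
$0.806 - 0.023t$, improving $0.896 + 0.816t - 0.118t^2$ — plus normal
noise with SD 0.2 (the residual spread is not reported anywhere; 0.2 score
units was fixed once as a realistic within-person wave-to-wave wobble
relative to curves sitting around 0.7–2.1, and gives class separation
comparable to the reported near-perfect classification entropy).
Comorbidity flags come from two patterns (arthritis–stomach 37.23%,
cardiometabolic–arthritis 62.77%) with within-pattern independent
Bernoulli draws, redrawn until every subject has at least two conditions;
trajectory and comorbidity classes are independent by default, with a
coupling log-odds exposed. With `indicators = TRUE` the generator also
back-solves 21 standardized indicator columns whose fixed-weight
combination reproduces each composite exactly.

Everything is driven by one integer seed, and identical configurations
produce byte-identical cohorts.

What the generator does *not* emulate — and therefore what passing tests
do not show: survey skip logic, sampling weights, attrition (completers
only by construction), dependence among baseline covariates beyond the
CES-D regression (only marginals are targeted), within-class residual
autocorrelation, or real comorbidity co-occurrence structure beyond the
two configured patterns. Recovery results on these cohorts demonstrate
that the estimators are correct under their own assumptions, not that the
substantive findings would replicate on survey data.

## Numerical choices and problem sizes

EM convergence is declared when the log-likelihood improves by less than
`tol` (defaults: `1e-8` for the trajectory and class models); posterior
ties in modal assignment break toward the lower class index; degenerate
mixing proportions (below $10^{-6}$) trigger a warning rather than an
error; and all restarts, bootstrap draws, and simulations derive their
sub-seeds from one user seed, so every result in the package is exactly
reproducible. The test suite exercises the estimators at deliberately
modest sizes chosen to make their statistical properties visible quickly:
trajectory recovery at 600–1,343 subjects, LCA recovery at 2,000, the
bootstrap LRT size study at 120 subjects × 6 items × 19 bootstrap
replicates over 100 simulations, and mediation coverage at 250 subjects ×
79 replicates over 60 simulations.

## Known limitations

- The trajectory model has no covariates, no per-class residual variance
  by default, and no censoring at the score bounds.
- The bootstrap LRT is the only class-count test; no LMR/VLMR.
- Shapley decomposition is exact-enumeration only; more than 12 players
  would need a sampling approximation that is deliberately not provided.
- Mediation is single-mediator, no exposure–mediator interaction, and
  product-of-coefficients rather than counterfactual estimands.
- Pattern naming is a labeled rule, not an inference; different clinical
  rule sets will merge classes differently.
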