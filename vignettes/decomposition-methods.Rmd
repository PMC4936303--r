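---
title: "Decomposing wealth-based gaps in facility-based delivery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposition methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nldecomp)
```

## The model

`nldecomp` quantifies how much of the poor/non-poor difference in a
binary outcome — facility-based delivery in the motivating application —
is attributable to differences in observed covariate distributions.

**Wealth grouping.** Households carry an asset index: the first
principal component of the column-standardized asset-indicator matrix,
sign-fixed to increase with total assets. Households are cut at weighted
quantiles 0.2/0.4/0.6/0.8 of the index (boundary = smallest value whose
cumulative weight share reaches the cut; ties deterministic); quintiles
1–2 are *poor*, 3–5 *non-poor*. Quintiles are computed at the household
level and propagated to all births of a household.

**Estimation.** For each group (and the pooled sample) a weighted logit
is fit by Newton–Raphson with step halving. Weights are normalized to
sum to the sample size before fitting — this leaves point estimates
unchanged and stabilizes the pseudo-log-likelihood scale. The covariance
is the sandwich estimator with scores summed within PSUs and the
small-sample correction G/(G−1)·(N−1)/(N−K); with singleton clusters
this collapses to the heteroskedasticity-robust estimator times
N/(N−K), which the tests document. Stratification is *not* reflected in
the variance (only PSU clustering); this mirrors the plain reading of
the error assumption — independence across communities — and is noted as
an extension. Convergence requires the maximum absolute score below
1e-11 (tighter than inference needs): at that tolerance the weighted
mean of fitted probabilities equals the weighted outcome mean to
~1e-13, which makes the decomposition identity below hold to 1e-12
rather than merely to optimizer tolerance. Perfect separation is
reported as an error naming the diverging column, detected either by a
coefficient passing 30 on the log-odds scale during iteration or by
every observation being perfectly predicted at convergence.

**Aggregate decomposition.** With benchmark coefficients β* (non-poor,
poor, or pooled) the explained portion is the difference in mean
predicted probabilities when the *covariate distributions* change:
mean over non-poor rows of F(x'β*) minus mean over poor rows. This one
formula is the first bracket of the canonical form (β* = β^NP), of its
swapped variant (β* = β^P), and of the pooled variant. The unexplained
portion is defined as gap − explained, so explained + unexplained = gap
exactly; when the group fits are supplied, the explicit second-bracket
form is also computed and must agree to 1e-12 (the acceptance suite
checks this on 1,000 random instances). The open question of how the
poor-benchmark variant holds samples fixed is resolved symmetrically:
both brackets swap together, which is what the single-formula
implementation yields.

**Detailed (Fairlie) decomposition.** Covariate blocks — a binary
indicator or a categorical variable's dummy group — are attributed
shares of the explained portion by sequential switching on a matched
sample: the larger group is subsampled without replacement to the
smaller group's size, both sides are ranked by predicted probability
under a ranking fit (default: pooled), and pairs are formed by rank.
Walking through a block ordering, each block's contribution is the
change in mean predicted probability when that block's columns flip from
the poor record's values to its counterpart's, earlier blocks already
flipped. Contributions telescope to the matched-sample explained portion
by construction. Because results depend on the matching draw and the
ordering, the procedure is replicated (default R = 100) with a fresh
subsample and a fresh uniform random ordering per replication, all from
child seeds of one root seed; reported contributions are means with
across-replication standard deviations as standard errors.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| benchmark | all three | coefficient vector weighting the covariate differences |
| `R` | 100 | matched-sample/ordering replications |
| ranking fit | pooled | fit whose predicted probabilities order the match |
| `missing_partner_policy` | `"dummy"` | keep partner-missing records, zero partner dummies, raise an indicator (itself a decomposable block); `"drop"` = listwise |
| quintile cuts | 0.2/0.4/0.6/0.8 | weighted household quantiles of the asset index |
| stars | 10/5/1% | two-sided significance thresholds in rendered tables |
| rounding | 3 (points), 2 (%) | table rendering only, never computation |

Design choices the contract left open, and how they were fixed:

- **Which side is subsampled.** The source description says the larger
  *non-poor* sample is subsampled, but its own descriptive counts make
  the poor group larger. The size-based rule — always subsample the
  larger group, whichever it is — is implemented.
- **Contribution standard errors** are across-replication standard
  deviations of per-replication means; the replication spread is the
  uncertainty object the replication design actually measures.
- **Pairs ignore weights; contribution means use the poor record's
  normalized weight.** Survey structure enters through the weighted
  means; making the matching itself weight-aware is not specifiable from
  the source.
- **Ties in predicted-probability ranks** are broken by a seeded
  shuffle. Ties arise exactly between identical covariate patterns, so
  the tie-break affects pair labels but not any reported number.
- **Pooled fit** pools the groups without a group indicator, the plain
  reading of "coefficient estimates from the pooled sample".
- **"Thirds" vs quintiles.** The source text once says the index groups
  households "into thirds" while defining poor/non-poor by quintiles;
  the quintile definition is implemented and the phrase treated as a
  slip.

## Numerical choices

- Identity-link (linear probability) decompositions use the *unclipped*
  linear predictor internally, so the classic closed form
  β*·(X̄^NP − X̄^P) is reproduced to 1e-10 regardless of matching seed or
  ordering; `predict_prob()` itself clips to [0, 1] and reports the
  clipped count.
- Reference-category swaps leave fitted probabilities and detailed
  contributions unchanged (to 1e-8, the fit tolerance): switching a
  whole dummy block is equivalent to switching the level identity, which
  is parametrization-invariant.
- Degenerate inputs error early with the offending column/row named:
  constant wealth index, zero-variance asset columns, undeclared
  covariate levels, non-binary outcomes, rank-deficient designs,
  separation.

## The synthetic world

The generator emulates a stratified two-stage cluster sample: strata of
PSUs of households, one birth per household. A latent household wealth
score (stratum effect + unit noise) drives conditionally independent
Bernoulli asset indicators, multinomial-logit covariate laws, and —
through group-specific coefficient vectors — the outcome, with an
optional PSU-level random intercept (sd 0.3 by default) and either
uniform or inverse-selection weights. Group membership is *never* set by
the generator: it derives the betas' group internally from the same
weighted-quintile operation the estimation pipeline uses, and the
emitted table omits quintile/group columns so the pipeline assigns them
itself.

Defaults state a world sized like a single-country DHS birth file:
17 strata × 25 PSUs × 24 households = 10,200 births (≈4,000 poor under
the 40/60 split), 10 assets, 6 covariate blocks plus a 2%
missing-partner rate. The outcome coefficient slopes are identical
across groups except education, which is flatter for the non-poor —
matching the motivating study's observation that odds ratios are similar
across groups except for education — and the two intercepts were set
once, by forward Monte-Carlo calculation, so expected coverages land
near the printed descriptive means (≈0.40 poor, ≈0.74 non-poor). The
implied true explained share is about 60% (non-poor benchmark) to 77%
(poor benchmark). None of these values was adjusted after acceptance
measurements.

`oracle_expected_decomposition()` evaluates the decomposition at the
*true* coefficients under the generator's own covariate law by
Monte-Carlo (PSU count scaled up to reach `n_mc`, batch-means standard
errors over whole PSUs so cluster-level randomness is captured). The
pooled benchmark has no true coefficient vector, so no oracle value
exists for it. The parameter-recovery and share-recovery tests run the
generator *without* PSU random intercepts: with them, the fitted logit
estimates marginal (attenuated) coefficients, so exact functional
recovery is only identified at `psu_effect_sd = 0`; at the default 0.3
agreement is approximate.

What the generator does **not** emulate — hence what a green test does
not establish: real DHS recode layouts, non-response and calibration
weighting, household-size variation in births, spatial geography,
measurement error in self-reported covariates, and any causal structure.
Green acceptance means the arithmetic of estimation and decomposition is
correct and recovers a known truth of this stated world, not that the
substantive conclusions of any particular survey are reproduced.

## Known limitations

- The motivating study's headline decomposition numbers were computed on
  restricted-access micro-data and cannot be reproduced here; only its
  printed descriptive differentials are used as worked examples.
- Variance estimation ignores stratification; standard errors may be
  conservative or anti-conservative depending on stratum homogeneity.
- The detailed decomposition's replication SE reflects subsampling and
  ordering variability, not sampling variability of the coefficient
  estimates; a full bootstrap is out of scope.
- Scaled-down settings in the test suite (e.g. 120 instead of 200
  recovery replications, with the tolerance band recomputed for the
  count actually used) keep the suite inside its time budget.
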