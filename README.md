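# nldecomp

Nonlinear Blinder–Oaxaca and Fairlie decomposition of wealth-based gaps
in a binary health-service outcome, for complex-survey micro-data.

## The problem

In many low- and middle-income countries, mothers from poorer households
are far less likely to deliver in a health facility than mothers from
wealthier households. Health-equity analyses ask how much of this
coverage gap is *explained* by differences in observable characteristics
(education, employment, distance to care, birth order, religion, region)
and how much remains *unexplained* (different behavioural responses,
unobservables). `nldecomp` implements the standard decomposition
toolchain for this question on DHS-style birth-level micro-data:
group-specific survey-weighted logit models with PSU-cluster-robust
standard errors, the aggregate nonlinear Blinder–Oaxaca decomposition,
and the Fairlie detailed decomposition with one-to-one rank matching,
repeated subsampling and randomized covariate orderings. A synthetic
generator for stratified two-stage cluster samples with a
principal-component asset index provides ground truth for every stage.

## The method

Households are ranked by an asset index (first principal component of
standardized asset indicators) and split into *poor* (bottom two
weighted quintiles) and *non-poor* (top three). For each group
*J ∈ {P, NP}* a latent-variable logit is fit:

    Y*_i = X_i' β^J + ε_i,   Y_i = 1[Y*_i > 0],   ε_i ~ logistic,

with sampling weights and errors independent across PSUs (survey
clusters). Writing F for the logistic CDF, the gap in mean coverage
decomposes as

    Ȳ^NP − Ȳ^P = [ Σ_NP F(X_i' β*)/N^NP − Σ_P F(X_i' β*)/N^P ]   (explained)
                + [ remainder ]                                    (unexplained)

where β* is the *benchmark* coefficient vector — non-poor, poor, or
pooled; all three are reported because the split is benchmark-dependent.
The detailed decomposition attributes the explained portion to covariate
blocks: poor records are matched one-to-one to records of the other
group by ranks of predicted probability, and blocks are switched from
poor to counterpart values one at a time, in sequence; the change in the
mean predicted probability at each switch is that block's contribution.
Because contributions are path-dependent and matching-dependent, the
procedure is replicated (default R = 100) over random subsamples of the
larger group and uniformly random block orderings, and means with
across-replication standard errors are reported.

## Worked example

```r
library(nldecomp)
cfg  <- synthetic_config(seed = 1)            # 10,200 births, DHS-like
tab  <- assign_wealth_groups(generate_population(cfg))
spec <- synthetic_model_spec(cfg)
dp   <- build_design_matrix(tab, spec, group = "poor")
dnp  <- build_design_matrix(tab, spec, group = "nonpoor")
fnp  <- fit_logit(dnp, benchmark = "nonpoor")
fp   <- fit_logit(dp,  benchmark = "poor")
fpool <- fit_logit(build_design_matrix(tab, spec), benchmark = "pooled")

aggregate_decomposition(fnp, dp, dnp, fit_poor = fp, fit_nonpoor = fnp)
#> Aggregate decomposition (benchmark: nonpoor, link: logit)
#>   mean non-poor 0.7393  mean poor 0.4006  gap 0.3386
#>   explained 0.2035 (60.1%)  unexplained 0.1351 (39.9%)

replicate_detailed_decomposition(tab, fnp, fpool, R = 100, root_seed = 1)
#> Detailed decomposition (benchmark: nonpoor, R = 100, seed 1)
#>   gap 0.3386, matched explained 0.2035
#>             block contribution     se pct_of_gap
#>  distance_problem       0.0170 0.0008     5.0089
#>        mother_edu       0.0481 0.0017    14.1931
#>       partner_edu       0.0329 0.0014     9.7042
#>        watches_tv       0.0413 0.0013    12.1876
#>       birth_order       0.0338 0.0009     9.9879
#>          religion       0.0305 0.0009     9.0128
#>   missing_partner       0.0000 0.0000    -0.0002
```

Reading: mean coverage is 0.74 for non-poor and 0.40 for poor births, a
gap of 33.9 percentage points; 20.4 points (60.1%) are explained by
covariate differences at non-poor coefficients. Maternal education
(4.8 points, 14.2% of the gap) and television access are the largest
block contributions; the missing-partner indicator is, correctly, inert.

The same pipeline runs from the shell:

```sh
Rscript -e 'quit(status = nldecomp::cli_main())' -- simulate --seed 1 --out pop.csv
Rscript -e 'quit(status = nldecomp::cli_main())' -- describe  --input pop.csv \
    --spec pop_spec.yaml --out table1.csv
Rscript -e 'quit(status = nldecomp::cli_main())' -- decompose --input pop.csv \
    --spec pop_spec.yaml --benchmark all --replications 100 --seed 1 --outdir out/
```

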