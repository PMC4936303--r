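test_that("identical groups decompose to all zeros", {
  set.seed(8)
  tab <- make_toy_table(40, 40, seed = 8)
  tab[tab$group == "nonpoor", c("outcome", "x1", "x2")] <-
    tab[tab$group == "poor", c("outcome", "x1", "x2")]
  spec <- toy_spec2()
  dp <- build_design_matrix(tab, spec, group = "poor")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  f <- fit_logit(build_design_matrix(tab, spec), benchmark = "pooled")
  a <- aggregate_decomposition(f, dp, dnp)
  expect_equal(a$gap, 0)
  expect_equal(a$explained, 0)
  expect_equal(a$unexplained, 0)
})

test_that("aggregate explained matches the direct-sum oracle on 6 rows", {
  tab <- data.frame(
    outcome = c(0L, 1L, 0L, 1L, 1L, 0L),
    weight = c(1, 2, 1, 1, 1.5, 1),
    stratum = "s1", psu = c("p1", "p1", "p2", "p2", "p3", "p3"),
    wealth_index = c(-1, -1, -1, 1, 1, 1),
    x1 = c("no", "yes", "no", "yes", "yes", "no"),
    x2 = c("a", "b", "c", "b", "c", "a"),
    group = rep(c("poor", "nonpoor"), each = 3),
    stringsAsFactors = FALSE)
  spec <- toy_spec2()
  dp <- build_design_matrix(tab, spec, group = "poor")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  beta <- c(0.2, -0.4, 0.6, -0.1)  # fixed printed coefficients
  f <- make_fixed_fit(beta, benchmark = "nonpoor", spec = spec)
  a <- aggregate_decomposition(f, dp, dnp)
  oracle <- oracle_explained_direct(beta, dp$X, dp$weights, dnp$X,
                                    dnp$weights)
  expect_equal(a$explained, oracle, tolerance = 1e-12)
  expect_equal(a$explained + a$unexplained, a$gap, tolerance = 1e-14)
})

test_that("identity link reproduces the classic linear decomposition", {
  tab <- make_toy_table(50, 50, seed = 9)
  spec <- toy_spec2()
  dp <- build_design_matrix(tab, spec, group = "poor")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  dall <- build_design_matrix(tab, spec)
  f <- fit_linear_probability(dall, benchmark = "pooled")
  a <- aggregate_decomposition(f, dp, dnp)
  lin <- oracle_linear_explained(f$beta, dp$X, dp$weights, dnp$X,
                                 dnp$weights)
  expect_equal(a$explained, lin, tolerance = 1e-10)

  # detailed: equal group sizes, uniform weights => per-block
  # contributions equal the closed form for any seed and ordering
  closed <- vapply(names(dp$block_cols), function(b) {
    cols <- dp$block_cols[[b]]
    sum(f$beta[cols] * (colMeans(dnp$X[, cols, drop = FALSE]) -
                          colMeans(dp$X[, cols, drop = FALSE])))
  }, numeric(1))
  for (seed in c(1, 99)) {
    m <- match_samples(tab, f, seed = seed, spec = spec)
    for (ord in list(c("x1", "x2"), c("x2", "x1"))) {
      cc <- detailed_decomposition_single(m, f, ord)
      expect_equal(as.numeric(cc), unname(closed), tolerance = 1e-10)
    }
  }
})

test_that("matching subsamples the larger side and pairs by rank", {
  tab46 <- make_toy_table(4, 6, seed = 10)
  spec <- toy_spec2()
  f <- make_fixed_fit(c(0.1, 0.9, -0.7, 0.5), benchmark = "pooled",
                      spec = spec)
  m1 <- match_samples(tab46, f, seed = 5)
  expect_equal(m1$n_pairs, 4L)
  expect_true(all(diff(m1$prob_poor) >= 0))
  expect_true(all(diff(m1$prob_other) >= 0))
  m1b <- match_samples(tab46, f, seed = 5)
  expect_identical(m1$other_rows, m1b$other_rows)
  m2 <- match_samples(tab46, f, seed = 6)
  expect_false(identical(m1$other_rows, m2$other_rows))

  # equal sizes: no subsampling, pairing is exactly the hand ranking
  # (covariate patterns chosen distinct so ranks are unambiguous)
  tab44 <- data.frame(
    outcome = rep(c(0L, 1L), 4),
    weight = 1, stratum = "s1",
    psu = rep(c("p1", "p2"), 4),
    wealth_index = rep(c(-1, 1), each = 4),
    x1 = c("no", "yes", "no", "yes", "yes", "no", "yes", "no"),
    x2 = c("a", "b", "c", "a", "b", "c", "c", "a"),
    group = rep(c("poor", "nonpoor"), each = 4),
    stringsAsFactors = FALSE)
  dp <- build_design_matrix(tab44, spec, group = "poor")
  dnp <- build_design_matrix(tab44, spec, group = "nonpoor")
  pp <- plogis(drop(dp$X %*% f$beta))
  pnp <- plogis(drop(dnp$X %*% f$beta))
  expect_equal(anyDuplicated(pp), 0L)
  expect_equal(anyDuplicated(pnp), 0L)
  m <- match_samples(tab44, f, seed = 1)
  expect_equal(m$poor_rows, dp$row_ids[order(pp)])
  expect_equal(m$other_rows, dnp$row_ids[order(pnp)])

  expect_error(match_samples(tab44,
                             make_fixed_fit(c(0, 0, 0, 0), spec = spec,
                                            benchmark = "pooled") |>
                               (\(x) { x$converged <- FALSE; x })(),
                             seed = 1),
               "did not converge")
})

test_that("single-ordering detailed decomposition telescopes and matches enumeration", {
  tab <- make_toy_table(5, 5, seed = 12)
  spec <- toy_spec2()
  beta <- c(-0.3, 0.7, -0.5, 0.9)
  f <- make_fixed_fit(beta, benchmark = "nonpoor", spec = spec)
  m <- match_samples(tab, f, seed = 2)

  states <- oracle_switch_states(m$X_poor, m$X_other, m$w_poor, beta,
                                 m$block_cols)
  # ordering (x1, x2): masks 00 -> 01 -> 11 ; ordering (x2, x1): 00 -> 10 -> 11
  c12 <- detailed_decomposition_single(m, f, c("x1", "x2"))
  expect_equal(unname(c12["x1"]), states[["m1"]] - states[["m0"]],
               tolerance = 1e-12)
  expect_equal(unname(c12["x2"]), states[["m3"]] - states[["m1"]],
               tolerance = 1e-12)
  c21 <- detailed_decomposition_single(m, f, c("x2", "x1"))
  expect_equal(unname(c21["x2"]), states[["m2"]] - states[["m0"]],
               tolerance = 1e-12)
  expect_equal(unname(c21["x1"]), states[["m3"]] - states[["m2"]],
               tolerance = 1e-12)
  for (cc in list(c12, c21))
    expect_equal(sum(cc), attr(cc, "explained_matched"), tolerance = 1e-12)

  # a block with zero benchmark coefficients contributes exactly 0
  beta0 <- beta; beta0[3:4] <- 0
  f0 <- make_fixed_fit(beta0, benchmark = "nonpoor", spec = spec)
  m0 <- match_samples(tab, f0, seed = 2)
  cc0 <- detailed_decomposition_single(m0, f0, c("x2", "x1"))
  expect_identical(unname(cc0["x2"]), 0)

  # single-block model: contribution equals the explained portion
  spec1 <- model_spec(list(spec_block("x1", "binary", c("no", "yes"), "no")),
                      missing_partner_policy = "drop")
  f1 <- make_fixed_fit(c(-0.3, 0.7), benchmark = "nonpoor", spec = spec1)
  m1 <- match_samples(tab, f1, seed = 3, spec = spec1)
  cc1 <- detailed_decomposition_single(m1, f1, "x1")
  expect_equal(unname(cc1["x1"]), attr(cc1, "explained_matched"),
               tolerance = 1e-14)

  expect_error(detailed_decomposition_single(m, f, c("x1", "x1")),
               "permutation")
})

test_that("replicated decomposition is seeded, telescopes, and stabilizes with R", {
  tab <- make_toy_table(80, 110, seed = 13)
  spec <- toy_spec2()
  dall <- build_design_matrix(tab, spec)
  fpool <- fit_logit(dall, benchmark = "pooled")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  fnp <- fit_logit(dnp, benchmark = "nonpoor")

  # R = 1 with a forced ordering equals the single-draw computation
  d1 <- replicate_detailed_decomposition(tab, fnp, fpool, R = 1,
                                         root_seed = 7,
                                         orderings = list(c("x1", "x2")))
  seeds <- nldecomp:::child_seeds(7, 2)
  m <- match_samples(tab, fpool, seeds[1], spec = spec)
  cc <- detailed_decomposition_single(m, fnp, c("x1", "x2"))
  expect_equal(d1$contributions$contribution, as.numeric(cc),
               tolerance = 1e-12)
  expect_equal(d1$explained_detailed, attr(cc, "explained_matched"),
               tolerance = 1e-12)

  # telescoping holds in every replication
  d100 <- replicate_detailed_decomposition(tab, fnp, fpool, R = 100,
                                           root_seed = 1)
  expect_lt(d100$max_telescope_error, 1e-10)
  expect_equal(rowSums(d100$contribs_matrix), d100$explained_per_rep,
               tolerance = 1e-10)

  # percent-of-gap definition
  expect_equal(d100$contributions$pct_of_gap,
               100 * d100$contributions$contribution / d100$gap)

  # across-root-seed variance of per-block means shrinks as R grows
  seeds8 <- 101:108
  spread <- sapply(c(10, 100), function(R) {
    means <- sapply(seeds8, function(s)
      replicate_detailed_decomposition(tab, fnp, fpool, R = R,
                                       root_seed = s)$contributions$contribution)
    mean(apply(means, 1, var))
  })
  expect_lt(spread[2], spread[1])

  # self-consistency of per-block means across two root seeds
  dA <- replicate_detailed_decomposition(tab, fnp, fpool, R = 200,
                                         root_seed = 301)
  dB <- replicate_detailed_decomposition(tab, fnp, fpool, R = 200,
                                         root_seed = 302)
  se <- sqrt((dA$contributions$se^2 + dB$contributions$se^2) / 200)
  expect_true(all(abs(dA$contributions$contribution -
                        dB$contributions$contribution) <= 4 * se + 1e-12))

  expect_error(replicate_detailed_decomposition(tab, fnp, fpool, R = 0,
                                                root_seed = 1),
               "at least 1")
})

test_that("detailed contributions are invariant to the reference category", {
  tab <- make_toy_table(60, 60, seed = 14)
  specA <- toy_spec2(ref2 = "a")
  specB <- toy_spec2(ref2 = "c")
  run <- function(spec) {
    dnp <- build_design_matrix(tab, spec, group = "nonpoor")
    fnp <- fit_logit(dnp, benchmark = "nonpoor")
    dall <- build_design_matrix(tab, spec)
    fpool <- fit_logit(dall, benchmark = "pooled")
    m <- match_samples(tab, fpool, seed = 4, spec = spec)
    list(contrib = detailed_decomposition_single(m, fnp, c("x2", "x1")),
         probs = predict_prob(fnp, dnp))
  }
  rA <- run(specA); rB <- run(specB)
  expect_equal(as.numeric(rA$contrib), as.numeric(rB$contrib),
               tolerance = 1e-8)
  # reference swap leaves fitted probabilities unchanged
  expect_equal(rA$probs, rB$probs, tolerance = 1e-8)
})

test_that("the report assembles stage outputs verbatim and guards totals", {
  tab <- make_toy_table(70, 90, seed = 15)
  spec <- toy_spec2()
  dp <- build_design_matrix(tab, spec, group = "poor")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  dall <- build_design_matrix(tab, spec)
  fits <- list(poor = fit_logit(dp, benchmark = "poor"),
               nonpoor = fit_logit(dnp, benchmark = "nonpoor"),
               pooled = fit_logit(dall, benchmark = "pooled"))
  agg <- list(); det <- list()
  for (b in c("nonpoor", "poor")) {
    agg[[b]] <- aggregate_decomposition(fits[[b]], dp, dnp,
                                        fit_poor = fits$poor,
                                        fit_nonpoor = fits$nonpoor)
    det[[b]] <- replicate_detailed_decomposition(tab, fits[[b]],
                                                 fits$pooled, R = 10,
                                                 root_seed = 1 + (b == "poor"))
  }
  rep_ <- decomposition_report(agg, det)
  expect_equal(rep_$totals$explained,
               c(agg$nonpoor$explained, agg$poor$explained))
  expect_equal(rep_$totals$explained_pct,
               100 * rep_$totals$explained / rep_$totals$gap)
  i <- rep_$blocks$benchmark == "nonpoor"
  expect_equal(rep_$blocks$contribution[i],
               det$nonpoor$contributions$contribution)

  # explained-share ratio contract: 0.234 / 0.336 -> 69.6%
  expect_equal(round(100 * 0.234 / 0.336, 1), 69.6)

  # tampered detailed results are rejected
  det_bad <- det
  det_bad$poor$contribs_matrix[, 1] <-
    det_bad$poor$contribs_matrix[, 1] + 0.01
  expect_error(decomposition_report(agg, det_bad), "assembly error")
  expect_error(decomposition_report(agg["nonpoor"], det), "mismatch")
})

test_that("estimated explained share recovers the generator truth", {
  # null worlds at n ~ 20,000: identical covariate laws => explained ~ 0;
  # identical betas => unexplained ~ 0 (full pipeline, not the oracle)
  beta <- default_true_beta("poor")
  flat <- lapply(default_covariate_model(), function(m) {
    m$slopes[] <- 0
    m
  })
  run_pipeline <- function(cfg) {
    tab <- assign_wealth_groups(generate_population(cfg))
    spec <- synthetic_model_spec(cfg)
    dp <- build_design_matrix(tab, spec, group = "poor")
    dnp <- build_design_matrix(tab, spec, group = "nonpoor")
    fnp <- fit_logit(dnp, benchmark = "nonpoor")
    fp <- fit_logit(dp, benchmark = "poor")
    a <- aggregate_decomposition(fnp, dp, dnp, fit_poor = fp,
                                 fit_nonpoor = fnp)
    # MC standard error of the gap estimate
    mp <- a$mean_poor; mnp <- a$mean_nonpoor
    se <- sqrt(mp * (1 - mp) / dp$n_retained +
                 mnp * (1 - mnp) / dnp$n_retained)
    list(a = a, se = se)
  }
  cfg_flat <- synthetic_config(households_per_psu = 48L,
                               covariate_model = flat, psu_effect_sd = 0,
                               seed = 51)
  r1 <- run_pipeline(cfg_flat)
  expect_lt(abs(r1$a$explained), 3 * r1$se)

  cfg_eqb <- synthetic_config(households_per_psu = 48L,
                              true_beta_poor = beta,
                              true_beta_nonpoor = beta,
                              psu_effect_sd = 0, seed = 52)
  r2 <- run_pipeline(cfg_eqb)
  expect_lt(abs(r2$a$unexplained), 3 * r2$se)
})
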