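# Fixture builders: everything is generated in code under fixed seeds.

# Two-block spec: one binary, one 3-level categorical.
toy_spec2 <- function(ref2 = "a") {
  model_spec(list(
    spec_block("x1", "binary", c("no", "yes"), "no"),
    spec_block("x2", "categorical", c("a", "b", "c"), ref2)),
    missing_partner_policy = "drop")
}

# Birth-level toy table with groups set directly (the quintile machinery
# has its own tests); covariate distributions differ by group so the
# explained portion is non-trivial.
make_toy_table <- function(n_poor = 60, n_nonpoor = 60, seed = 1,
                           beta_poor = c(-0.5, 0.8, 0.4, -0.6),
                           beta_nonpoor = c(0.4, 0.5, 0.2, -0.3),
                           n_psu = 6, weights = NULL) {
  set.seed(seed)
  n <- n_poor + n_nonpoor
  grp <- rep(c("poor", "nonpoor"), c(n_poor, n_nonpoor))
  p_yes <- ifelse(grp == "poor", 0.35, 0.65)
  x1 <- ifelse(runif(n) < p_yes, "yes", "no")
  x2 <- ifelse(grp == "poor",
               sample(c("a", "b", "c"), n, TRUE, c(0.5, 0.3, 0.2)),
               sample(c("a", "b", "c"), n, TRUE, c(0.2, 0.3, 0.5)))
  X <- cbind(1, x1 == "yes", x2 == "b", x2 == "c")
  eta <- ifelse(grp == "poor", X %*% beta_poor, X %*% beta_nonpoor)
  tab <- data.frame(
    outcome = rbinom(n, 1, plogis(eta)),
    weight = weights %||% rep(1, n),
    stratum = "s1",
    psu = sprintf("p%02d", sample.int(n_psu, n, TRUE)),
    wealth_index = ifelse(grp == "poor", -1, 1) + runif(n, 0, 0.1),
    x1 = x1, x2 = x2, group = grp,
    stringsAsFactors = FALSE)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built design matrix object (for oracle-level fits that bypass
# table coding, e.g. intercept-only models).
make_design <- function(X, y, w = rep(1, length(y)),
                        psu = as.character(seq_along(y)),
                        block_cols = NULL, spec = NULL) {
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     paste0("v", seq_len(ncol(X) - 1L)))[seq_len(ncol(X))]
  structure(list(X = X, y = y, weights = w, psu = psu,
                 stratum = rep("s1", length(y)),
                 block_cols = block_cols %||%
                   as.list(stats::setNames(seq(2L, length.out = ncol(X) - 1L),
                                           colnames(X)[-1L])),
                 row_ids = seq_along(y), n_retained = length(y),
                 n_dropped = 0L, spec = spec),
            class = "design_matrix")
}

# A logit_fit with prescribed coefficients (for decomposition oracles
# that need fixed "printed" benchmark coefficients).
make_fixed_fit <- function(beta, link = "logit", benchmark = "nonpoor",
                           spec = NULL) {
  k <- length(beta)
  structure(list(benchmark = benchmark, beta = beta,
                 vcov = diag(k), link = link, n_obs = NA_integer_,
                 n_clusters = NA_integer_, loglik = NA_real_,
                 converged = TRUE, spec = spec, n_iter = 0L),
            class = "logit_fit")
}

# Random small instance for identity sweeps: toy table plus its designs
# and the three fits.
random_toy_fits <- function(seed) {
  set.seed(seed + 10007L)
  bp <- runif(4, -1, 1); bnp <- runif(4, -1, 1)
  tab <- make_toy_table(n_poor = 100 + (seed %% 4) * 25,
                        n_nonpoor = 100 + (seed %% 3) * 30,
                        seed = seed,
                        beta_poor = bp, beta_nonpoor = bnp)
  spec <- toy_spec2()
  dp <- build_design_matrix(tab, spec, group = "poor")
  dnp <- build_design_matrix(tab, spec, group = "nonpoor")
  dall <- build_design_matrix(tab, spec)
  list(tab = tab, spec = spec, dp = dp, dnp = dnp,
       fits = list(poor = fit_logit(dp, benchmark = "poor"),
                   nonpoor = fit_logit(dnp, benchmark = "nonpoor"),
                   pooled = fit_logit(dall, benchmark = "pooled")))
}

# Small synthetic configuration for fast end-to-end runs.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_strata = 4L, psus_per_stratum = 6L,
                   households_per_psu = 30L, seed = seed, ...)
}
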