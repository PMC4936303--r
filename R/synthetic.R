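## Synthetic DHS-like micro-data generator.
##
## The generator emulates a stratified two-stage cluster sample: strata
## contain PSUs (survey clusters, e.g. barangays), PSUs contain
## households, and each household contributes one birth record.  A latent
## household wealth score drives both the asset indicators (from which
## the PCA wealth index is built) and the covariate distributions; the
## binary outcome is drawn from a group-specific logit with an optional
## PSU-level random intercept.  Group membership (poor / non-poor) is
## never set inside the generator: it is derived downstream from weighted
## quintiles of the PCA asset index, exactly as in the estimation
## pipeline.

#' Covariate-block generating law
#'
#' Level probabilities follow a multinomial logit in the latent wealth
#' score `w`: `P(level l | w) = softmax(intercept_l + slope_l * w)`.
#' The reference level's intercept and slope are conventionally 0 but any
#' values are accepted (softmax is shift-invariant).
#'
#' @param block a [spec_block()].
#' @param intercepts,slopes numeric vectors named by level (one entry per
#'   level of the block).
#' @return an object of class `"cov_block_model"`.
#' @export
cov_block_model <- function(block, intercepts, slopes) {
  stopifnot(inherits(block, "spec_block"))
  if (!setequal(names(intercepts), block$levels) ||
      !setequal(names(slopes), block$levels))
    stop("intercepts and slopes must be named by the levels of block '",
         block$name, "'")
  structure(list(block = block,
                 intercepts = intercepts[block$levels],
                 slopes = slopes[block$levels]),
            class = "cov_block_model")
}

block_level_probs <- function(m, w) {
  eta <- outer(w, m$slopes) + rep(m$intercepts, each = length(w))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Default covariate generating laws
#'
#' A compact stand-in for the covariate blocks of a DHS birth file:
#' subjective distance to the health facility, mother's and partner's
#' education (4 levels), weekly television viewing, child's birth order
#' (3 levels) and religion (4 levels).  Education, television access and
#' first births are more likely at higher wealth; reporting distance as a
#' problem, high birth orders and Islam (concentrated in poorer regions)
#' are less likely.
#'
#' @return named list of [cov_block_model()] objects.
#' @export
default_covariate_model <- function() {
  edu <- c("none", "primary_inc", "primary_comp", "secondary_plus")
  mods <- list(
    cov_block_model(
      spec_block("distance_problem", "binary", c("no", "yes"), "no"),
      intercepts = c(no = 0, yes = -0.45),
      slopes = c(no = 0, yes = -0.55)),
    cov_block_model(
      spec_block("mother_edu", "categorical", edu, "none"),
      intercepts = c(none = 0, primary_inc = 2.0, primary_comp = 2.0,
                     secondary_plus = 3.2),
      slopes = c(none = 0, primary_inc = 0.4, primary_comp = 0.8,
                 secondary_plus = 1.8)),
    cov_block_model(
      spec_block("partner_edu", "categorical", edu, "none", partner = TRUE),
      intercepts = c(none = 0, primary_inc = 2.0, primary_comp = 1.8,
                     secondary_plus = 2.6),
      slopes = c(none = 0, primary_inc = 0.3, primary_comp = 0.7,
                 secondary_plus = 1.7)),
    cov_block_model(
      spec_block("watches_tv", "binary", c("no", "yes"), "no"),
      intercepts = c(no = 0, yes = 0.9),
      slopes = c(no = 0, yes = 1.1)),
    cov_block_model(
      spec_block("birth_order", "categorical",
                 c("first", "two_four", "five_plus"), "first"),
      intercepts = c(first = 0, two_four = 0.55, five_plus = -0.25),
      slopes = c(first = 0, two_four = -0.25, five_plus = -0.95)),
    cov_block_model(
      spec_block("religion", "categorical",
                 c("catholic", "protestant", "islam", "other"), "catholic"),
      intercepts = c(catholic = 0, protestant = -2.6, islam = -2.2,
                     other = -2.1),
      slopes = c(catholic = 0, protestant = 0.1, islam = -0.9,
                 other = -0.1))
  )
  names(mods) <- vapply(mods, function(m) m$block$name, character(1))
  mods
}

#' Model specification implied by a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return the [model_spec()] whose design matrix the true coefficient
#'   vectors refer to.
#' @export
synthetic_model_spec <- function(config) {
  blocks <- lapply(config$covariate_model, `[[`, "block")
  model_spec(blocks, missing_partner_policy = "dummy",
             outcome_name = "outcome")
}

#' Default true coefficient vectors (log-odds scale)
#'
#' Group-specific outcome processes for the default covariate model.
#' Slopes are identical across groups except for education, which is
#' flatter for the non-poor (education matters less where nearly all
#' mothers are educated), and the intercepts, which were set by a forward
#' Monte-Carlo calculation so the expected group coverages land near the
#' motivating survey's printed descriptive means (about 0.40 poor / 0.74
#' non-poor, gap about 0.33).  Under these defaults the true explained
#' share of the gap is roughly 60% (non-poor benchmark) to 77% (poor
#' benchmark).
#'
#' @param group `"poor"` or `"nonpoor"`.
#' @return named numeric vector aligned with the design columns of
#'   [synthetic_model_spec()].
#' @export
default_true_beta <- function(group = c("poor", "nonpoor")) {
  group <- match.arg(group)
  if (group == "poor")
    c("(Intercept)" = -0.78,
      "distance_problem" = -0.50,
      "mother_edu:primary_inc" = 0.35, "mother_edu:primary_comp" = 0.65,
      "mother_edu:secondary_plus" = 1.25,
      "partner_edu:primary_inc" = 0.25, "partner_edu:primary_comp" = 0.50,
      "partner_edu:secondary_plus" = 0.95,
      "watches_tv" = 0.45,
      "birth_order:two_four" = -0.45, "birth_order:five_plus" = -1.00,
      "religion:protestant" = -0.15, "religion:islam" = -0.85,
      "religion:other" = -0.20,
      "missing_partner" = -0.20)
  else
    c("(Intercept)" = 0.33,
      "distance_problem" = -0.50,
      "mother_edu:primary_inc" = 0.20, "mother_edu:primary_comp" = 0.40,
      "mother_edu:secondary_plus" = 0.75,
      "partner_edu:primary_inc" = 0.15, "partner_edu:primary_comp" = 0.30,
      "partner_edu:secondary_plus" = 0.55,
      "watches_tv" = 0.45,
      "birth_order:two_four" = -0.45, "birth_order:five_plus" = -1.00,
      "religion:protestant" = -0.15, "religion:islam" = -0.85,
      "religion:other" = -0.20,
      "missing_partner" = -0.20)
}

#' Configuration of the synthetic micro-data generator
#'
#' @param n_strata,psus_per_stratum,households_per_psu positive counts.
#'   Defaults give 17 x 25 x 24 = 10,200 households (one birth each),
#'   sized like a single-country DHS birth file and yielding about 4,000
#'   poor births under the 40/60 quintile split.
#' @param asset_count number of binary asset indicators (default 10).
#' @param true_beta_poor,true_beta_nonpoor coefficient vectors on the
#'   log-odds scale, aligned with the design columns implied by
#'   `covariate_model` (intercept first, `missing_partner` last when a
#'   partner block is present).
#' @param covariate_model named list of [cov_block_model()] laws.
#' @param psu_effect_sd standard deviation (log-odds) of the PSU-level
#'   random intercept; 0 disables it.  Default 0.3: a modest intra-PSU
#'   outcome correlation.
#' @param weight_scheme `"uniform"` (all weights 1) or
#'   `"inverse-selection"` (weights proportional to the inverse of a
#'   simulated PSU selection probability).
#' @param partner_missing_rate fraction of records whose partner-block
#'   values are missing (handled downstream by the missing-partner
#'   dummy).  Default 0.02.
#' @param seed root seed; every stage consumes its own child stream.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_strata = 17L,
                             psus_per_stratum = 25L,
                             households_per_psu = 24L,
                             asset_count = 10L,
                             true_beta_poor = default_true_beta("poor"),
                             true_beta_nonpoor = default_true_beta("nonpoor"),
                             covariate_model = default_covariate_model(),
                             psu_effect_sd = 0.3,
                             weight_scheme = c("uniform", "inverse-selection"),
                             partner_missing_rate = 0.02,
                             seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  counts <- c(n_strata = n_strata, psus_per_stratum = psus_per_stratum,
              households_per_psu = households_per_psu,
              asset_count = asset_count)
  if (any(counts < 1))
    stop("configuration error: all counts must be positive")
  if (psu_effect_sd < 0)
    stop("configuration error: psu_effect_sd must be >= 0")
  if (partner_missing_rate < 0 || partner_missing_rate >= 1)
    stop("configuration error: partner_missing_rate must be in [0, 1)")
  if (length(true_beta_poor) != length(true_beta_nonpoor))
    stop("configuration error: true_beta_poor and true_beta_nonpoor must ",
         "have identical length and ordering")
  cfg <- structure(list(
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    households_per_psu = as.integer(households_per_psu),
    asset_count = as.integer(asset_count),
    true_beta_poor = true_beta_poor,
    true_beta_nonpoor = true_beta_nonpoor,
    covariate_model = covariate_model,
    psu_effect_sd = psu_effect_sd,
    weight_scheme = weight_scheme,
    partner_missing_rate = partner_missing_rate,
    seed = as.integer(seed)), class = "synthetic_config")
  spec <- synthetic_model_spec(cfg)
  k <- length(spec_design_colnames(spec))
  if (length(true_beta_poor) != k)
    stop("configuration error: coefficient vectors have length ",
         length(true_beta_poor), " but the covariate model implies ",
         k, " design columns")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic DHS-like configuration:\n",
      " ", x$n_strata, "strata x", x$psus_per_stratum, "PSUs x",
      x$households_per_psu, "households =",
      x$n_strata * x$psus_per_stratum * x$households_per_psu, "births\n",
      " ", x$asset_count, "asset indicators; psu_effect_sd =",
      x$psu_effect_sd, "; weights:", x$weight_scheme,
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic birth-level micro-data table
#'
#' One record per household/birth with stratum, PSU, sampling weight, raw
#' asset indicators, the PCA wealth index, covariates drawn from the
#' configured laws given latent wealth, and the outcome drawn
#' `Bernoulli(plogis(x' beta_group + psu_effect))`.  The group used for
#' the outcome draw is derived from weighted quintiles of the PCA asset
#' index through [assign_wealth_groups()] — the same operation the
#' estimation pipeline applies — but the returned table deliberately
#' omits the `wealth_quintile`/`group` columns so the downstream pipeline
#' assigns them itself.
#'
#' Ground truth (latent wealth, PSU effects, true design matrix, true
#' success probabilities under both coefficient vectors, group used) is
#' attached as `attr(table, "truth")` for oracle tests; it does not
#' survive CSV round trips.
#'
#' @param config a [synthetic_config()].
#' @return a `"microdata"` data.frame.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  S <- config$n_strata; P <- config$psus_per_stratum
  H <- config$households_per_psu
  n <- S * P * H
  stratum <- rep(sprintf("s%02d", seq_len(S)), each = P * H)
  psu <- rep(sprintf("s%02d_p%03d",
                     rep(seq_len(S), each = P), rep(seq_len(P), S)),
             each = H)
  household <- sprintf("h%06d", seq_len(n))
  seeds <- child_seeds(config$seed, 7L)

  # latent household wealth: stratum effect + unit noise
  alpha <- if (S > 1) seq(-1, 1, length.out = S) else 0
  w_lat <- with_seed(seeds[1L],
                     rep(alpha, each = P * H) + stats::rnorm(n))

  # conditionally independent Bernoulli assets given latent wealth
  K <- config$asset_count
  a_int <- if (K > 1) seq(-1.2, 1.2, length.out = K) else 0
  assets <- with_seed(seeds[2L], {
    m <- matrix(0L, n, K,
                dimnames = list(NULL, sprintf("asset_%02d", seq_len(K))))
    for (k in seq_len(K))
      m[, k] <- stats::rbinom(n, 1L, logistic(a_int[k] + 1.2 * w_lat))
    m
  })
  wealth_index <- compute_asset_index(assets)

  # covariates from the configured multinomial-logit laws
  covs <- with_seed(seeds[3L], {
    out <- list()
    for (m in config$covariate_model) {
      pr <- block_level_probs(m, w_lat)
      L <- ncol(pr)
      cum <- pr %*% upper.tri(diag(L), diag = TRUE)  # row-wise cumsum
      u <- stats::runif(n)
      idx <- 1L + rowSums(u > cum[, -L, drop = FALSE])
      out[[m$block$name]] <- m$block$levels[idx]
    }
    out
  })

  # partner-block missingness
  spec <- synthetic_model_spec(config)
  partner_blocks <- names(spec$blocks)[
    vapply(spec$blocks, `[[`, logical(1), "partner")]
  if (config$partner_missing_rate > 0 && length(partner_blocks)) {
    miss <- with_seed(seeds[4L],
                      stats::runif(n) < config$partner_missing_rate)
    for (nm in partner_blocks) covs[[nm]][miss] <- NA_character_
  }

  # PSU random intercepts
  upsu <- if (config$psu_effect_sd > 0)
    with_seed(seeds[5L], stats::rnorm(S * P, 0, config$psu_effect_sd))
  else rep(0, S * P)
  u <- rep(upsu, each = H)

  # sampling weights
  weight <- if (config$weight_scheme == "uniform") rep(1, n) else {
    m_psu <- with_seed(seeds[6L], stats::runif(S * P, 0.5, 1.5))
    wps <- 1 / m_psu
    rep(wps / mean(wps), each = H)
  }

  tab <- data.frame(household = household, stratum = stratum, psu = psu,
                    weight = weight, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(assets))
  tab$wealth_index <- wealth_index
  for (nm in names(covs)) tab[[nm]] <- covs[[nm]]
  tab$outcome <- 0L  # placeholder until groups known

  grouped <- assign_wealth_groups(tab)
  des <- build_design_matrix(grouped, spec)
  if (des$n_retained != n)
    stop("internal error: generator design matrix dropped rows")
  beta_p <- config$true_beta_poor
  beta_np <- config$true_beta_nonpoor
  eta_p <- drop(des$X %*% beta_p) + u
  eta_np <- drop(des$X %*% beta_np) + u
  is_poor <- grouped$group == "poor"
  p_true <- ifelse(is_poor, logistic(eta_p), logistic(eta_np))
  tab$outcome <- with_seed(seeds[7L], stats::rbinom(n, 1L, p_true))

  tab <- as_microdata(tab, spec)
  attr(tab, "truth") <- list(
    latent_wealth = w_lat, psu_effect = u, X = des$X,
    group = grouped$group, p_true = p_true,
    p_poor_law = logistic(eta_p), p_nonpoor_law = logistic(eta_np))
  attr(tab, "config") <- config
  tab
}

#' Monte-Carlo ground truth for the decomposition on a configuration
#'
#' Evaluates the decomposition quantities at the TRUE coefficient vectors
#' under the generator's own covariate law: expected facility-delivery
#' coverage for the poor and non-poor groups, the coverage gap, and the
#' expected explained portion (and explained share of the gap) under the
#' poor and non-poor benchmarks.  The pooled benchmark has no true
#' coefficient vector, so no oracle value exists for it.
#'
#' Standard errors are batch-means Monte-Carlo errors (20 batches).
#'
#' @param config a [synthetic_config()].
#' @param n_mc Monte-Carlo sample size (>= 10,000); the configuration's
#'   households-per-PSU count is rescaled to reach it.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return object of class `"decomp_oracle"`.
#' @export
oracle_expected_decomposition <- function(config, n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_mc < 1e4) stop("n_mc must be at least 10,000")
  # grow the PSU count (not PSU size) so Monte-Carlo error, including the
  # PSU-level random-intercept variance, shrinks with n_mc
  SH <- config$n_strata * config$households_per_psu
  cfg <- config
  cfg$psus_per_stratum <- as.integer(ceiling(n_mc / SH))
  cfg$seed <- as.integer(seed)
  pop <- generate_population(cfg)
  tr <- attr(pop, "truth")
  grouped <- assign_wealth_groups(pop)
  is_poor <- grouped$group == "poor"
  w <- pop$weight

  stat_fun <- function(rows) {
    ip <- is_poor[rows]; wr <- w[rows]
    pP <- tr$p_poor_law[rows]; pNP <- tr$p_nonpoor_law[rows]
    poor_cov <- wmean(pP[ip], wr[ip])
    nonpoor_cov <- wmean(pNP[!ip], wr[!ip])
    gap <- nonpoor_cov - poor_cov
    expl_np <- wmean(pNP[!ip], wr[!ip]) - wmean(pNP[ip], wr[ip])
    expl_p <- wmean(pP[!ip], wr[!ip]) - wmean(pP[ip], wr[ip])
    c(poor_coverage = poor_cov, nonpoor_coverage = nonpoor_cov, gap = gap,
      explained_nonpoor = expl_np, explained_poor = expl_p,
      share_nonpoor = expl_np / gap, share_poor = expl_p / gap)
  }
  full <- stat_fun(seq_len(nrow(pop)))
  # batch-means MC errors with whole PSUs per batch, so cluster-level
  # randomness (PSU random intercepts) is reflected in the SE
  B <- 20L
  psus <- unique(pop$psu)
  psu_batch <- with_seed(seed + 1L,
                         sample(rep_len(seq_len(B), length(psus))))
  batch <- psu_batch[match(pop$psu, psus)]
  bm <- t(vapply(seq_len(B), function(b) stat_fun(which(batch == b)),
                 full))
  se <- apply(bm, 2L, stats::sd) / sqrt(B)
  structure(list(estimates = full, se = se, n_mc = nrow(pop),
                 seed = seed), class = "decomp_oracle")
}

#' @export
print.decomp_oracle <- function(x, ...) {
  cat("Monte-Carlo decomposition ground truth (n =", x$n_mc, "):\n")
  print(round(rbind(estimate = x$estimates, mc_se = x$se), 4))
  invisible(x)
}

#' Read a synthetic configuration from YAML
#'
#' Mirrors [synthetic_config()]; the covariate model is given as a list
#' of maps with keys `name`, `kind`, `levels`, `reference`, `partner`,
#' `intercepts`, `slopes` (the latter two named by level); coefficient
#' vectors as maps from design column name to value.
#'
#' @param path YAML file.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cm <- if (is.null(cfg$covariate_model)) default_covariate_model() else {
    mods <- lapply(cfg$covariate_model, function(b) {
      blk <- spec_block(b$name, b$kind, b$levels,
                        b$reference %||% b$levels[[1L]], isTRUE(b$partner))
      cov_block_model(blk, unlist(b$intercepts), unlist(b$slopes))
    })
    names(mods) <- vapply(mods, function(m) m$block$name, character(1))
    mods
  }
  grab_beta <- function(x, default) if (is.null(x)) default else unlist(x)
  synthetic_config(
    n_strata = cfg$n_strata %||% 17L,
    psus_per_stratum = cfg$psus_per_stratum %||% 25L,
    households_per_psu = cfg$households_per_psu %||% 24L,
    asset_count = cfg$asset_count %||% 10L,
    true_beta_poor = grab_beta(cfg$true_beta_poor,
                               default_true_beta("poor")),
    true_beta_nonpoor = grab_beta(cfg$true_beta_nonpoor,
                                  default_true_beta("nonpoor")),
    covariate_model = cm,
    psu_effect_sd = cfg$psu_effect_sd %||% 0.3,
    weight_scheme = cfg$weight_scheme %||% "uniform",
    partner_missing_rate = cfg$partner_missing_rate %||% 0.02,
    seed = cfg$seed %||% 1L)
}
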