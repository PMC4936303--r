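## Nonlinear Blinder-Oaxaca (aggregate) and Fairlie (detailed)
## decomposition of the poor / non-poor gap in a binary outcome.
##
## Aggregate: with benchmark coefficients beta*, the explained portion is
##   mean_NP F(x' beta*) - mean_P F(x' beta*)
## (weighted means within group).  This single formula covers all three
## benchmarks: it is the first bracket of the canonical decomposition
## when beta* = beta^NP, of its swapped variant when beta* = beta^P, and
## of the pooled-coefficient variant otherwise.  The unexplained portion
## is the gap minus the explained portion; when the group-specific fits
## are supplied the second-bracket form is also computed and must agree
## to near machine precision (it does whenever the logits are fit to a
## tight score tolerance, since the weighted mean of fitted probabilities
## then equals the weighted outcome mean).

group_outcome_mean <- function(design) wmean(design$y, design$weights)

#' Aggregate nonlinear decomposition of the group gap
#'
#' @param fit_benchmark converged `"logit_fit"` supplying the benchmark
#'   coefficients (poor, non-poor, or pooled).
#' @param design_poor,design_nonpoor group design matrices.
#' @param fit_poor,fit_nonpoor optional converged group-specific fits;
#'   when both are supplied the unexplained portion is also computed from
#'   the explicit second bracket and checked against `gap - explained`.
#' @return object of class `"agg_decomp"` with fields `benchmark`,
#'   `mean_nonpoor`, `mean_poor`, `gap`, `explained`, `unexplained`
#'   (defined as `gap - explained`, so the telescoping identity is exact)
#'   and, when checkable, `unexplained_bracket` and `identity_error`.
#' @export
aggregate_decomposition <- function(fit_benchmark, design_poor,
                                    design_nonpoor,
                                    fit_poor = NULL, fit_nonpoor = NULL) {
  for (f in Filter(Negate(is.null),
                   list(fit_benchmark, fit_poor, fit_nonpoor)))
    if (!isTRUE(f$converged)) stop("fit did not converge; refusing to decompose")
  links <- vapply(Filter(Negate(is.null),
                         list(fit_benchmark, fit_poor, fit_nonpoor)),
                  `[[`, character(1), "link")
  if (length(unique(links)) > 1L)
    stop("link mismatch between benchmark and group fits")
  if (ncol(design_poor$X) != length(fit_benchmark$beta))
    stop("design not conformable with benchmark coefficients")

  wp <- design_poor$weights; wnp <- design_nonpoor$weights
  mean_poor <- wmean(design_poor$y, wp)
  mean_nonpoor <- wmean(design_nonpoor$y, wnp)
  gap <- mean_nonpoor - mean_poor
  Fb <- function(design, fit)
    wmean(linkinv_raw(fit, drop(design$X %*% fit$beta)), design$weights)
  explained <- Fb(design_nonpoor, fit_benchmark) - Fb(design_poor, fit_benchmark)
  unexplained <- gap - explained

  res <- list(benchmark = fit_benchmark$benchmark,
              mean_nonpoor = mean_nonpoor, mean_poor = mean_poor,
              gap = gap, explained = explained, unexplained = unexplained,
              link = fit_benchmark$link)
  if (!is.null(fit_poor) && !is.null(fit_nonpoor)) {
    # explicit second bracket(s) of the decomposition identity
    bracket <- (Fb(design_nonpoor, fit_nonpoor) -
                  Fb(design_nonpoor, fit_benchmark)) +
      (Fb(design_poor, fit_benchmark) - Fb(design_poor, fit_poor))
    res$unexplained_bracket <- bracket
    res$identity_error <- abs(unexplained - bracket)
  }
  structure(res, class = "agg_decomp")
}

#' @export
print.agg_decomp <- function(x, ...) {
  cat(sprintf(paste0("Aggregate decomposition (benchmark: %s, link: %s)\n",
                     "  mean non-poor %.4f  mean poor %.4f  gap %.4f\n",
                     "  explained %.4f (%.1f%%)  unexplained %.4f (%.1f%%)\n"),
              x$benchmark, x$link, x$mean_nonpoor, x$mean_poor, x$gap,
              x$explained, 100 * x$explained / x$gap,
              x$unexplained, 100 * x$unexplained / x$gap))
  invisible(x)
}

#' One-to-one matching of poor and non-poor records
#'
#' Draws one matched sample: the larger group is subsampled without
#' replacement to the smaller group's size using the seeded stream, both
#' sides are sorted ascending by predicted probability under
#' `ranking_fit` (ties broken by a seeded stable shuffle), and pairs are
#' formed by rank position.
#'
#' @param table micro-data with assigned groups.
#' @param ranking_fit converged `"logit_fit"` used to rank records
#'   (conventionally the pooled fit).
#' @param seed integer seed for the subsample draw and tie-breaking.
#' @param spec optional [model_spec()]; defaults to the one stored on the
#'   ranking fit.
#' @return object of class `"matched_sample"`: matched design matrices
#'   `X_poor`, `X_other` (rows aligned pair-wise), the poor-side weights
#'   used for contribution means, block->column map, and bookkeeping.
#' @export
match_samples <- function(table, ranking_fit, seed, spec = NULL) {
  spec <- spec %||% ranking_fit$spec
  if (is.null(spec)) stop("no model spec available for matching")
  if (!"group" %in% names(table))
    stop("groups not assigned; run assign_wealth_groups() first")
  dp <- build_design_matrix(table, spec, group = "poor")
  dnp <- build_design_matrix(table, spec, group = "nonpoor")
  match_from_designs(dp, dnp, ranking_fit, seed)
}

match_from_designs <- function(dp, dnp, ranking_fit, seed) {
  if (!isTRUE(ranking_fit$converged))
    stop("ranking fit did not converge")
  spec <- dp$spec
  if (dp$n_retained == 0L || dnp$n_retained == 0L)
    stop("both groups must be non-empty")
  np <- dp$n_retained; nnp <- dnp$n_retained
  m <- min(np, nnp)
  seeds <- child_seeds(seed, 3L)
  sub <- function(design, n_keep, s) {
    if (design$n_retained == n_keep) seq_len(design$n_retained)
    else with_seed(s, sort(sample.int(design$n_retained, n_keep)))
  }
  ip <- sub(dp, m, seeds[1L])
  inp <- sub(dnp, m, seeds[2L])
  pp <- predict_prob(ranking_fit, dp$X[ip, , drop = FALSE])
  pnp <- predict_prob(ranking_fit, dnp$X[inp, , drop = FALSE])
  ord <- with_seed(seeds[3L], {
    list(p = order(pp, stats::runif(m)), np = order(pnp, stats::runif(m)))
  })
  ip <- ip[ord$p]; inp <- inp[ord$np]
  structure(list(
    X_poor = dp$X[ip, , drop = FALSE],
    X_other = dnp$X[inp, , drop = FALSE],
    w_poor = dp$weights[ip],
    prob_poor = pp[ord$p], prob_other = pnp[ord$np],
    poor_rows = dp$row_ids[ip], other_rows = dnp$row_ids[inp],
    block_cols = dp$block_cols,
    n_pairs = m, n_poor = np, n_nonpoor = nnp,
    subsample_seed = seed, ranking_benchmark = ranking_fit$benchmark,
    spec = spec), class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf(paste0("Matched sample: %d pairs (poor %d, non-poor %d; ",
                     "larger side subsampled), seed %d, ranked by '%s' fit\n"),
              x$n_pairs, x$n_poor, x$n_nonpoor, x$subsample_seed,
              x$ranking_benchmark))
  invisible(x)
}

matched_explained <- function(match, fit) {
  w <- match$w_poor / sum(match$w_poor)
  sum(w * linkinv_raw(fit, drop(match$X_other %*% fit$beta))) -
    sum(w * linkinv_raw(fit, drop(match$X_poor %*% fit$beta)))
}

#' Detailed decomposition for one matched sample and one ordering
#'
#' Sequential-switching attribution: walking through the blocks in the
#' given order, the contribution of the block at position k is the change
#' in the mean predicted probability (benchmark coefficients, poor-side
#' weights) when that block's columns are switched from the poor record's
#' values to its matched counterpart's values, with blocks at earlier
#' positions already switched and later positions still at poor values.
#' The intercept is never switched.  Contributions over all blocks
#' telescope to the matched-sample explained portion.
#'
#' @param match a [match_samples()] result.
#' @param fit_benchmark converged benchmark fit.
#' @param ordering character permutation of the block names.
#' @return named numeric vector of contributions in the spec's block
#'   order, with attributes `explained_matched` and `ordering`.
#' @export
detailed_decomposition_single <- function(match, fit_benchmark, ordering) {
  if (!isTRUE(fit_benchmark$converged)) stop("benchmark fit not converged")
  blocks <- names(match$block_cols)
  if (length(ordering) != length(blocks) ||
      !setequal(ordering, blocks) || anyDuplicated(ordering))
    stop("ordering must be a permutation of the block names: ",
         paste(blocks, collapse = ", "))
  beta <- fit_benchmark$beta
  w <- match$w_poor / sum(match$w_poor)
  Xcur <- match$X_poor
  mean_prob <- function(X)
    sum(w * linkinv_raw(fit_benchmark, drop(X %*% beta)))
  prev <- mean_prob(Xcur)
  contrib <- numeric(length(blocks))
  names(contrib) <- ordering
  for (b in ordering) {
    cols <- match$block_cols[[b]]
    Xcur[, cols] <- match$X_other[, cols, drop = FALSE]
    cur <- mean_prob(Xcur)
    contrib[b] <- cur - prev
    prev <- cur
  }
  out <- contrib[blocks]  # report in spec order
  attr(out, "explained_matched") <- matched_explained(match, fit_benchmark)
  attr(out, "ordering") <- ordering
  out
}

#' Replicated detailed decomposition with randomized orderings
#'
#' For each of `R` replications, draws a fresh matched sample (fresh
#' subsample of the larger group) and a fresh uniformly random block
#' ordering from child seeds of `root_seed`, runs
#' [detailed_decomposition_single()], and summarizes per-block
#' contributions as means across replications with across-replication
#' standard deviations as standard errors (the replication spread over
#' subsampling and ordering randomness).  Percent-of-gap shares use the
#' full-sample weighted outcome gap.
#'
#' @param table micro-data with assigned groups.
#' @param fit_benchmark converged benchmark fit (poor, non-poor or
#'   pooled coefficients).
#' @param ranking_fit converged fit used to rank for matching.
#' @param R number of replications (default 100).
#' @param root_seed integer root seed.
#' @param orderings optional list of fixed orderings (length `R`),
#'   overriding randomization — used for diagnostics.
#' @return object of class `"detailed_decomp"`.
#' @export
replicate_detailed_decomposition <- function(table, fit_benchmark,
                                             ranking_fit, R = 100L,
                                             root_seed = 1L,
                                             orderings = NULL) {
  if (R < 1) stop("R must be at least 1")
  spec <- ranking_fit$spec %||% fit_benchmark$spec
  dp <- build_design_matrix(table, spec, group = "poor")
  dnp <- build_design_matrix(table, spec, group = "nonpoor")
  gap <- group_outcome_mean(dnp) - group_outcome_mean(dp)
  blocks <- names(dp$block_cols)
  seeds <- child_seeds(root_seed, 2L * R)
  contribs <- matrix(NA_real_, R, length(blocks),
                     dimnames = list(NULL, blocks))
  expl <- numeric(R)
  telescope_err <- numeric(R)
  for (r in seq_len(R)) {
    m <- match_from_designs(dp, dnp, ranking_fit, seeds[2L * r - 1L])
    ord <- if (is.null(orderings))
      with_seed(seeds[2L * r], sample(blocks))
    else orderings[[r]]
    cc <- detailed_decomposition_single(m, fit_benchmark, ord)
    contribs[r, ] <- cc
    expl[r] <- attr(cc, "explained_matched")
    telescope_err[r] <- abs(sum(cc) - expl[r])
  }
  means <- colMeans(contribs)
  ses <- if (R > 1) apply(contribs, 2L, stats::sd) else rep(NA_real_, length(blocks))
  structure(list(
    benchmark = fit_benchmark$benchmark,
    replications = R, root_seed = root_seed,
    contributions = data.frame(
      block = blocks, contribution = means, se = ses,
      pct_of_gap = 100 * means / gap, row.names = NULL),
    explained_detailed = mean(expl),
    explained_per_rep = expl,
    contribs_matrix = contribs,
    gap = gap,
    max_telescope_error = max(telescope_err)),
    class = "detailed_decomp")
}

#' @export
print.detailed_decomp <- function(x, ...) {
  cat(sprintf(paste0("Detailed decomposition (benchmark: %s, R = %d, ",
                     "seed %d)\n  gap %.4f, matched explained %.4f\n"),
              x$benchmark, x$replications, x$root_seed, x$gap,
              x$explained_detailed))
  print(cbind(x$contributions[1L],
              round(x$contributions[-1L], 4)), row.names = FALSE)
  invisible(x)
}

#' Assemble aggregate and detailed results into one report
#'
#' @param agg named list of `"agg_decomp"` objects (one per benchmark).
#' @param det named list of `"detailed_decomp"` objects with matching
#'   benchmark names.
#' @return object of class `"decomp_report"`: per-benchmark block table
#'   with contributions, replication standard errors, percent-of-gap
#'   shares and significance stars from replication t-ratios, plus totals.
#' @export
decomposition_report <- function(agg, det) {
  if (!setequal(names(agg), names(det)))
    stop("benchmark mismatch between aggregate and detailed results")
  rows <- list(); totals <- list()
  for (b in names(agg)) {
    a <- agg[[b]]; d <- det[[b]]
    if (!identical(a$benchmark, d$benchmark) || !identical(a$benchmark, b))
      stop("benchmark mismatch between aggregate and detailed results")
    sums <- rowSums(d$contribs_matrix)
    if (max(abs(sums - d$explained_per_rep)) > 1e-8)
      stop("assembly error: detailed contributions do not sum to the ",
           "matched-sample explained portion")
    tab <- d$contributions
    tratio <- tab$contribution / tab$se
    tab$p <- 2 * stats::pnorm(-abs(tratio))
    tab$stars <- vapply(tab$p, star_string, character(1))
    tab$benchmark <- b
    rows[[b]] <- tab
    totals[[b]] <- data.frame(
      benchmark = b, mean_nonpoor = a$mean_nonpoor, mean_poor = a$mean_poor,
      gap = a$gap, explained = a$explained, unexplained = a$unexplained,
      explained_pct = 100 * a$explained / a$gap,
      unexplained_pct = 100 * a$unexplained / a$gap,
      explained_detailed = d$explained_detailed,
      replications = d$replications, row.names = NULL)
  }
  structure(list(blocks = do.call(rbind, c(rows, make.row.names = FALSE)),
                 totals = do.call(rbind, c(totals, make.row.names = FALSE))),
            class = "decomp_report")
}

#' @export
print.decomp_report <- function(x, ...) {
  cat("Decomposition report\n\nTotals:\n")
  print(cbind(x$totals["benchmark"],
              round(x$totals[setdiff(names(x$totals), "benchmark")], 4)),
        row.names = FALSE)
  cat("\nPer-block contributions:\n")
  tab <- x$blocks
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- round(tab[num], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a decomposition report
#'
#' Writes one CSV row per block per benchmark plus a totals CSV, and a
#' JSON file carrying both together with seed metadata.
#'
#' @param report a `"decomp_report"`.
#' @param dir output directory (created if needed).
#' @param meta named list of run metadata (seeds, sizes) stored in the
#'   JSON.
#' @return invisibly, the paths written.
#' @export
write_decomposition_report <- function(report, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "decomposition_blocks.csv")
  p2 <- file.path(dir, "decomposition_totals.csv")
  p3 <- file.path(dir, "decomposition.json")
  utils::write.csv(report$blocks, p1, row.names = FALSE)
  utils::write.csv(report$totals, p2, row.names = FALSE)
  jsonlite::write_json(list(meta = meta, totals = report$totals,
                            blocks = report$blocks),
                       p3, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(p1, p2, p3))
}
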