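#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive deterministic child seeds from one root seed
#'
#' All stochastic stages (wealth draw, assets, covariates, PSU effects,
#' outcomes, subsampling, orderings) consume their own child stream so any
#' stage can be replayed in isolation.  Child seeds are drawn from a
#' temporary RNG state seeded with the root; the caller's RNG state is
#' restored on exit.
#'
#' @param root_seed integer scalar.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in [1, 2^31 - 2].
#' @keywords internal
child_seeds <- function(root_seed, n) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a local seed, restoring RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Weighted quantile by CDF inversion
#'
#' Boundary convention: the quantile at probability `p` is the smallest
#' observed value whose cumulative weight share is >= `p`.  Deterministic
#' under ties, matching the convention used for wealth quintile cuts.
#'
#' @param x numeric values.
#' @param w positive weights.
#' @param probs probabilities in (0, 1).
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  cs <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cs >= p - 1e-12)[1L]], numeric(1))
}

#' Weighted mean with normalized weights
#' @keywords internal
wmean <- function(x, w) sum(x * w) / sum(w)

#' Logistic CDF
#' @keywords internal
logistic <- function(eta) stats::plogis(eta)

star_string <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

`%||%` <- function(a, b) if (is.null(a)) b else a
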