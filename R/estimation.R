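## Survey-weighted estimation with PSU-cluster-robust covariance.
##
## The logit is fit by Newton-Raphson on the weighted Bernoulli
## pseudo-log-likelihood with step halving; convergence requires the
## maximum absolute score component below 1e-10 (tighter than needed for
## inference, but it makes the decomposition's telescoping identity hold
## to near machine precision, because the weighted mean of fitted
## probabilities then equals the weighted outcome mean exactly).
## Weights are normalized to sum to the number of observations before
## fitting; this stabilizes the pseudo-log-likelihood scale and leaves
## point estimates unchanged.

check_rank <- function(X, w) {
  qd <- qr(X * sqrt(w))
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("rank deficiency: collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

#' Cluster-robust sandwich covariance
#'
#' `vcov = c * A^-1 B A^-1` where `A` is the (negative) Hessian of the
#' weighted pseudo-log-likelihood, `B` the outer product of score vectors
#' summed within PSU clusters, and `c = G/(G-1) * (N-1)/(N-K)` the
#' small-sample cluster correction (G clusters, N observations, K
#' parameters).  With one observation per cluster this reduces to the
#' heteroskedasticity-robust estimator up to the same factor, which then
#' equals `N/(N-1) * (N-1)/(N-K) = N/(N-K)`.
#'
#' @keywords internal
cluster_sandwich <- function(A, scores, cluster) {
  n <- nrow(scores); k <- ncol(scores)
  sg <- rowsum(scores, cluster, reorder = FALSE)
  G <- nrow(sg)
  if (G < 2L) stop("need at least 2 clusters for a clustered vcov")
  B <- crossprod(sg)
  corr <- (G / (G - 1)) * ((n - 1) / (n - k))
  Ainv <- solve(A)
  V <- corr * Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}

new_logit_fit <- function(beta, vcov, link, benchmark, n_obs, n_clusters,
                          loglik, converged, spec, n_iter) {
  structure(list(benchmark = benchmark, beta = beta, vcov = vcov,
                 link = link, n_obs = n_obs, n_clusters = n_clusters,
                 loglik = loglik, converged = converged, spec = spec,
                 n_iter = n_iter),
            class = "logit_fit")
}

#' Survey-weighted logit with PSU-clustered standard errors
#'
#' Fits `P(y=1|x) = plogis(x'beta)` by weighted maximum pseudo-likelihood
#' with the sandwich covariance clustered on the design's `psu` ids.
#'
#' @param design a [build_design_matrix()] result (carries `X`, `y`,
#'   weights and PSU ids).
#' @param y optional outcome override; defaults to `design$y`.
#' @param benchmark label stored on the fit: `"poor"`, `"nonpoor"` or
#'   `"pooled"`.
#' @return an object of class `"logit_fit"`.
#' @export
fit_logit <- function(design, y = NULL, benchmark = "pooled") {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  y <- y %||% design$y
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(y) != nrow(X)) stop("outcome length does not match design")
  w <- design$weights
  if (any(w <= 0)) stop("weights must be positive")
  w <- w * length(w) / sum(w)
  check_rank(X, w)
  if (all(y == 1) || all(y == 0))
    stop("perfect separation: outcome is constant; offending column: ",
         colnames(X)[1L])

  k <- ncol(X)
  beta <- numeric(k)
  # start the intercept at the weighted logit of the mean
  ybar <- wmean(y, w)
  beta[1L] <- log(ybar / (1 - ybar))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- logistic(drop(X %*% beta))
    score <- drop(crossprod(X, w * (y - p)))
    ll <- sum(w * ifelse(y == 1, log(pmax(p, 1e-300)),
                         log(pmax(1 - p, 1e-300))))
    if (max(abs(beta)) > 30) {
      bad <- colnames(X)[which.max(abs(beta))]
      stop("perfect separation suspected (diverging coefficient on '",
           bad, "')")
    }
    if (max(abs(score)) < 1e-11 ||
        (is.finite(ll_old) && abs(ll - ll_old) < 1e-14 * (abs(ll) + 1) &&
         max(abs(score)) < 1e-9)) {
      converged <- TRUE
      break
    }
    if (iter > 100L) break
    Wd <- w * p * (1 - p)
    A <- crossprod(X, X * Wd)
    step <- tryCatch(solve(A, score), error = function(e)
      stop("singular Hessian during logit fit: ", conditionMessage(e)))
    # step halving on the pseudo-log-likelihood
    s <- 1
    repeat {
      beta_new <- beta + s * step
      p_new <- logistic(drop(X %*% beta_new))
      ll_new <- sum(w * ifelse(y == 1, log(pmax(p_new, 1e-300)),
                               log(pmax(1 - p_new, 1e-300))))
      if (ll_new >= ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta_new
    ll_old <- ll
  }
  if (!converged)
    stop("logit did not converge in 100 iterations")
  p <- logistic(drop(X %*% beta))
  if (all(abs(y - p) < 1e-6)) {
    # every observation perfectly predicted: complete separation
    nonint <- if (length(beta) > 1L) beta[-1L] else beta
    bad <- names(nonint)[which.max(abs(nonint))]
    stop("perfect separation: outcome perfectly predicted; ",
         "offending column: ", bad)
  }
  Wd <- w * p * (1 - p)
  A <- crossprod(X, X * Wd)
  scores <- X * (w * (y - p))
  V <- cluster_sandwich(A, scores, design$psu)
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  new_logit_fit(beta, V, "logit", benchmark, nrow(X),
                length(unique(design$psu)),
                sum(w * ifelse(y == 1, log(p), log(1 - p))),
                TRUE, design$spec, iter)
}

#' Weighted linear probability model with clustered standard errors
#'
#' Weighted least squares of the binary outcome on the design, with the
#' same PSU-clustered sandwich as [fit_logit()]; used as a robustness
#' check whose decomposition has the classic linear closed form.
#'
#' @inheritParams fit_logit
#' @return a `"logit_fit"` object with `link = "identity"`.
#' @export
fit_linear_probability <- function(design, y = NULL, benchmark = "pooled") {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  y <- y %||% design$y
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  w <- design$weights
  w <- w * length(w) / sum(w)
  check_rank(X, w)
  A <- crossprod(X, X * w)
  beta <- drop(solve(A, crossprod(X, w * y)))
  names(beta) <- colnames(X)
  e <- y - drop(X %*% beta)
  scores <- X * (w * e)
  V <- cluster_sandwich(A, scores, design$psu)
  dimnames(V) <- list(colnames(X), colnames(X))
  new_logit_fit(beta, V, "identity", benchmark, nrow(X),
                length(unique(design$psu)),
                -0.5 * sum(w * e^2), TRUE, design$spec, 1L)
}

#' @export
print.logit_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$beta / se
  tab <- data.frame(estimate = x$beta, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  cat(sprintf("%s fit, benchmark '%s': %d obs, %d PSU clusters%s\n",
              if (x$link == "logit") "Logit" else "Linear probability",
              x$benchmark, x$n_obs, x$n_clusters,
              if (x$link == "logit")
                sprintf(", loglik %.2f (%d iter)", x$loglik, x$n_iter)
              else ""))
  print(round(tab, 4))
  invisible(x)
}

#' Predicted success probabilities
#'
#' Logit link: `plogis(x'beta)`.  Identity link: the linear predictor
#' clipped to `[0, 1]`; the number of clipped rows is attached as
#' `attr(, "n_clipped")`.
#'
#' @param fit a `"logit_fit"`.
#' @param X numeric design matrix (or a `"design_matrix"` object) with
#'   columns matching `fit$beta`.
#' @return numeric probability vector.
#' @export
predict_prob <- function(fit, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  if (ncol(X) != length(fit$beta))
    stop("dimension mismatch: design has ", ncol(X),
         " columns but fit has ", length(fit$beta), " coefficients")
  eta <- drop(X %*% fit$beta)
  if (fit$link == "logit") return(logistic(eta))
  p <- pmin(pmax(eta, 0), 1)
  structure(p, n_clipped = sum(eta < 0 | eta > 1))
}

# Linear predictor pushed through the link WITHOUT clipping; the
# decomposition uses this so the identity-link closed form is exact.
linkinv_raw <- function(fit, eta) {
  if (fit$link == "logit") logistic(eta) else eta
}

#' Odds ratios with 95% Wald intervals
#'
#' @param fit a logit-link `"logit_fit"`.
#' @return data.frame with columns `or`, `lower`, `upper`, `p`.
#' @export
odds_ratios <- function(fit) {
  if (fit$link != "logit")
    stop("odds ratios are unsupported for the identity link")
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(0.975)
  data.frame(or = exp(fit$beta),
             lower = exp(fit$beta - z * se),
             upper = exp(fit$beta + z * se),
             p = 2 * stats::pnorm(-abs(fit$beta / se)),
             row.names = names(fit$beta))
}

#' Weighted two-sample proportion test between wealth groups
#'
#' Computes the weighted share of a binary covariate (or one level of a
#' categorical block, or the outcome) in the poor and non-poor groups and
#' tests equality with a two-sided z-test using the unpooled variance.
#' The effective sample size `(sum w)^2 / sum w^2` replaces n under
#' weighting; with `cluster = TRUE` the variance of each group share is
#' instead the PSU-cluster-robust variance of the weighted mean with a
#' `G/(G-1)` correction.
#'
#' @param table micro-data with assigned groups.
#' @param variable column name (binary 0/1 or character/factor).
#' @param level for categorical variables, the level whose share is
#'   tested.
#' @param cluster logical; cluster-adjust the variances on `psu`.
#' @return list with `poor_share`, `nonpoor_share`, `differential`
#'   (non-poor minus poor), `se`, `z`, `p`, `stars`.
#' @export
proportion_diff_test <- function(table, variable, level = NULL,
                                 cluster = FALSE) {
  if (!"group" %in% names(table))
    stop("groups not assigned; run assign_wealth_groups() first")
  v <- table[[variable]]
  if (is.null(v)) stop("no such variable: ", variable)
  x <- if (is.null(level)) {
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("variable '", variable, "' is not binary; supply a level")
    as.numeric(v)
  } else as.numeric(as.character(v) == level)
  keep <- !is.na(x)
  x <- x[keep]
  g <- table$group[keep]; w <- table$weight[keep]; psu <- table$psu[keep]
  one <- function(sel) {
    if (!any(sel)) stop("empty group in proportion test")
    xi <- x[sel]; wi <- w[sel]
    p <- wmean(xi, wi)
    if (cluster) {
      sg <- rowsum(wi * (xi - p), psu[sel])
      G <- nrow(sg)
      v <- (G / (G - 1)) * sum(sg^2) / sum(wi)^2
    } else {
      neff <- sum(wi)^2 / sum(wi^2)
      v <- p * (1 - p) / neff
    }
    c(p = p, var = v)
  }
  sp <- one(g == "poor"); snp <- one(g == "nonpoor")
  diff <- snp[["p"]] - sp[["p"]]
  se <- sqrt(sp[["var"]] + snp[["var"]])
  z <- if (se == 0) ifelse(diff == 0, 0, sign(diff) * Inf) else diff / se
  p <- 2 * stats::pnorm(-abs(z))
  list(poor_share = sp[["p"]], nonpoor_share = snp[["p"]],
       differential = diff, se = se, z = z, p = p, stars = star_string(p))
}
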