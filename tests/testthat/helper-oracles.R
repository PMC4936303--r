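# Independent brute-force oracles.  Deliberately naive and separate from
# the package's code paths: plain loops, solve() on explicit matrices,
# enumeration.

# Weighted-logit Newton iteration, no step halving, explicit Hessian.
oracle_newton_logit <- function(X, y, w, tol = 1e-12, maxit = 50) {
  w <- w * length(w) / sum(w)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    g <- drop(t(X) %*% (w * (y - p)))
    H <- t(X) %*% (X * (w * p * (1 - p)))
    beta <- beta + solve(H, g)
    if (max(abs(g)) < tol) break
  }
  beta
}

# Hand-assembled cluster sandwich for a weighted logit at beta.
oracle_cluster_sandwich_logit <- function(X, y, w, beta, cluster) {
  w <- w * length(w) / sum(w)
  n <- nrow(X); k <- ncol(X)
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  A <- matrix(0, k, k)
  for (i in seq_len(n))
    A <- A + w[i] * p[i] * (1 - p[i]) * tcrossprod(X[i, ])
  B <- matrix(0, k, k)
  for (g in unique(cluster)) {
    sg <- rep(0, k)
    for (i in which(cluster == g))
      sg <- sg + w[i] * (y[i] - p[i]) * X[i, ]
    B <- B + tcrossprod(sg)
  }
  G <- length(unique(cluster))
  corr <- (G / (G - 1)) * ((n - 1) / (n - k))
  corr * solve(A) %*% B %*% solve(A)
}

# First-PC scores from an explicit eigen-decomposition of the
# correlation matrix.
oracle_pca_scores <- function(assets) {
  z <- scale(assets)
  ev <- eigen(stats::cor(assets), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  s <- drop(z %*% v)
  if (sum(s * rowSums(z)) < 0) s <- -s
  s - mean(s)
}

# Brute-force weighted-CDF inversion.
oracle_weighted_quantile <- function(x, w, p) {
  o <- order(x)
  xo <- x[o]; cs <- cumsum(w[o]) / sum(w)
  for (i in seq_along(xo)) if (cs[i] >= p - 1e-12) return(xo[i])
  xo[length(xo)]
}

# Classic linear Blinder-Oaxaca explained portion.
oracle_linear_explained <- function(beta, Xp, wp, Xnp, wnp) {
  xbar_p <- drop(t(Xp) %*% wp) / sum(wp)
  xbar_np <- drop(t(Xnp) %*% wnp) / sum(wnp)
  sum(beta * (xbar_np - xbar_p))
}

# Direct-sum evaluation of the aggregate explained portion.
oracle_explained_direct <- function(beta, Xp, wp, Xnp, wnp,
                                    link = "logit") {
  f <- if (link == "logit") function(e) 1 / (1 + exp(-e)) else identity
  s_np <- 0
  for (i in seq_len(nrow(Xnp)))
    s_np <- s_np + wnp[i] * f(sum(Xnp[i, ] * beta))
  s_p <- 0
  for (i in seq_len(nrow(Xp)))
    s_p <- s_p + wp[i] * f(sum(Xp[i, ] * beta))
  s_np / sum(wnp) - s_p / sum(wp)
}

# Enumerate all switch states of a matched pair set for blocks given as
# a list of column-index vectors; returns mean predicted probability for
# each subset of switched blocks (named by binary mask string).
oracle_switch_states <- function(Xp, Xnp, w, beta, block_cols,
                                 link = "logit") {
  f <- if (link == "logit") function(e) 1 / (1 + exp(-e)) else identity
  B <- length(block_cols)
  w <- w / sum(w)
  out <- list()
  for (mask in 0:(2^B - 1)) {
    X <- Xp
    for (b in seq_len(B))
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0)
        X[, block_cols[[b]]] <- Xnp[, block_cols[[b]], drop = FALSE]
    out[[paste0("m", mask)]] <- sum(w * f(drop(X %*% beta)))
  }
  unlist(out)
}

# Unpooled two-proportion z statistic from 2x2 counts.
oracle_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  (p2 - p1) / sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}
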