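#' Asset-based wealth index via principal component analysis
#'
#' Computes the standard DHS-style wealth proxy: the first principal
#' component score of the column-standardized household asset matrix.
#' The sign of the component is fixed so that the score correlates
#' positively with the row sum of assets (more assets = wealthier), and
#' scores are mean-centred at 0.
#'
#' @param assets numeric matrix or data.frame, one row per household, one
#'   column per asset indicator (typically 0/1 ownership dummies, but any
#'   numeric indicator is accepted).  No missing values; every column must
#'   have nonzero variance; at least 2 households and 1 column.
#' @return numeric vector of first-principal-component scores, one per
#'   household, mean 0.
#' @examples
#' a <- cbind(radio = c(0, 1, 1, 0), tv = c(0, 0, 1, 1))
#' compute_asset_index(a)
#' @export
compute_asset_index <- function(assets) {
  assets <- as.matrix(assets)
  if (!is.numeric(assets)) stop("asset matrix must be numeric")
  if (nrow(assets) < 2L)
    stop("need at least 2 households to compute an asset index")
  if (ncol(assets) < 1L) stop("need at least 1 asset column")
  if (anyNA(assets)) stop("asset matrix contains missing values")
  sds <- apply(assets, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(assets)[sds == 0] %||% which(sds == 0)
    stop("zero-variance asset column(s): ", paste(bad, collapse = ", "))
  }
  z <- scale(assets)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1L]
  # orient so score increases with total assets
  if (sum(score * rowSums(z)) < 0) score <- -score
  as.numeric(score - mean(score))
}
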