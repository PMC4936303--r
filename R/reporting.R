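## Table rendering: descriptive statistics by wealth group and the
## decomposition summary table.

block_rows <- function(b) {
  if (b$kind == "binary") {
    data.frame(variable = b$name, level = setdiff(b$levels, b$reference),
               stringsAsFactors = FALSE)
  } else {
    data.frame(variable = b$name, level = b$levels, stringsAsFactors = FALSE)
  }
}

#' Descriptive statistics by wealth group
#'
#' One row per variable/level: weighted poor mean (sd), non-poor mean
#' (sd), differential (non-poor minus poor) with its standard error and
#' significance stars at the 10/5/1% levels, from
#' [proportion_diff_test()].  Binary blocks contribute the share of
#' their non-reference level; categorical blocks one row per level.  The
#' outcome is reported first; group observation counts are attached as
#' attributes `n_poor` / `n_nonpoor`.
#'
#' @param table micro-data with assigned groups.
#' @param spec a [model_spec()].
#' @param digits rounding applied to means/sds/differentials (2..6).
#' @param cluster passed to [proportion_diff_test()].
#' @return data.frame of class `"descriptive_table"`.
#' @export
render_descriptive_table <- function(table, spec, digits = 2,
                                     cluster = FALSE) {
  if (!digits %in% 2:6) stop("digits must be in 2..6")
  rows <- rbind(
    data.frame(variable = spec$outcome_name, level = NA_character_,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(unname(spec$blocks), block_rows)))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    v <- rows$variable[i]; lv <- rows$level[i]
    binary_col <- is.na(lv) ||
      (v %in% names(spec$blocks) && spec$blocks[[v]]$kind == "binary" &&
       all(table[[v]] %in% c(0, 1) | is.na(table[[v]])))
    t <- proportion_diff_test(table, v,
                              level = if (binary_col) NULL else lv,
                              cluster = cluster)
    data.frame(
      variable = v, level = if (is.na(lv)) "" else lv,
      poor_mean = round(t$poor_share, digits),
      poor_sd = round(sqrt(t$poor_share * (1 - t$poor_share)), digits),
      nonpoor_mean = round(t$nonpoor_share, digits),
      nonpoor_sd = round(sqrt(t$nonpoor_share * (1 - t$nonpoor_share)),
                         digits),
      differential = round(t$differential, digits),
      se = round(t$se, digits), stars = t$stars,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "n_poor") <- sum(table$group == "poor")
  attr(res, "n_nonpoor") <- sum(table$group == "nonpoor")
  class(res) <- c("descriptive_table", "data.frame")
  res
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat("Descriptive statistics by wealth group\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Obs.: poor %d, non-poor %d\n",
              attr(x, "n_poor"), attr(x, "n_nonpoor")))
  invisible(x)
}

#' Decomposition summary table
#'
#' Per-block probability-point contributions with replication standard
#' errors, percent-of-gap shares and stars, one column group per
#' benchmark, plus totals rows (total explained / total unexplained in
#' points and percent).  Probability points are rounded to
#' `digits_points`, percents to `digits_pct`.
#'
#' @param report a [decomposition_report()] result.
#' @param digits_points rounding for probability-point columns
#'   (default 3).
#' @param digits_pct rounding for percent columns (default 2).
#' @return data.frame of class `"decomposition_table"` with the block
#'   rows followed by `Total explained` / `Total unexplained` rows per
#'   benchmark.
#' @export
render_decomposition_table <- function(report, digits_points = 3,
                                       digits_pct = 2) {
  stopifnot(inherits(report, "decomp_report"))
  blk <- report$blocks
  body <- data.frame(
    benchmark = blk$benchmark, row = blk$block,
    contribution = round(blk$contribution, digits_points),
    se = round(blk$se, digits_points),
    pct_of_gap = round(blk$pct_of_gap, digits_pct),
    stars = blk$stars, stringsAsFactors = FALSE)
  tot <- report$totals
  totals <- do.call(rbind, lapply(seq_len(nrow(tot)), function(i) {
    data.frame(
      benchmark = rep(tot$benchmark[i], 2L),
      row = c("Total explained", "Total unexplained"),
      contribution = round(c(tot$explained[i], tot$unexplained[i]),
                           digits_points),
      se = NA_real_,
      pct_of_gap = round(c(tot$explained_pct[i], tot$unexplained_pct[i]),
                         digits_pct),
      stars = "", stringsAsFactors = FALSE)
  }))
  res <- rbind(body, totals)
  attr(res, "gap") <- round(tot$gap[1L], digits_points)
  attr(res, "mean_nonpoor") <- round(tot$mean_nonpoor[1L], digits_points)
  attr(res, "mean_poor") <- round(tot$mean_poor[1L], digits_points)
  class(res) <- c("decomposition_table", "data.frame")
  res
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat(sprintf(paste0("Decomposition of the facility-delivery gap\n",
                     "  mean non-poor %s   mean poor %s   gap %s\n"),
              attr(x, "mean_nonpoor"), attr(x, "mean_poor"),
              attr(x, "gap")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
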