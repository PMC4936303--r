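#' Declare one covariate block of a model specification
#'
#' A block is a single conceptual covariate: a binary indicator or a
#' categorical variable that enters the design matrix as a group of dummy
#' columns and is switched as a unit in the detailed decomposition.
#'
#' @param name column name in the micro-data.
#' @param kind `"binary"` or `"categorical"`.
#' @param levels character vector of admissible levels (exactly 2 for
#'   binary blocks).
#' @param reference the omitted reference level; must be one of `levels`.
#' @param partner logical; partner-reported blocks get the missing-partner
#'   treatment (see [model_spec()]).
#' @return an object of class `"spec_block"`.
#' @export
spec_block <- function(name, kind = c("binary", "categorical"),
                       levels, reference = levels[1L], partner = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0)
  levels <- as.character(levels)
  if (kind == "binary" && length(levels) != 2L)
    stop("binary block '", name, "' must have exactly 2 levels")
  if (length(levels) < 2L)
    stop("block '", name, "' needs at least 2 levels")
  if (anyDuplicated(levels))
    stop("block '", name, "' has duplicated levels")
  if (!reference %in% levels)
    stop("reference level '", reference, "' of block '", name,
         "' is not among its levels")
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference, partner = isTRUE(partner)),
            class = "spec_block")
}

#' Model specification: ordered covariate blocks and missing-data policy
#'
#' @param blocks list of [spec_block()] objects, in the order they appear
#'   in descriptive tables.  Block names must be unique.
#' @param missing_partner_policy `"dummy"` retains records with missing
#'   partner-block values, zeroing their partner dummies and raising a
#'   `missing_partner` indicator column (itself a decomposable block);
#'   `"drop"` deletes such records listwise like any other missingness.
#' @param outcome_name name of the binary outcome column.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(blocks, missing_partner_policy = c("dummy", "drop"),
                       outcome_name = "outcome") {
  missing_partner_policy <- match.arg(missing_partner_policy)
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (!all(vapply(blocks, inherits, logical(1), "spec_block")))
    stop("all blocks must be created by spec_block()")
  nm <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("block names must be unique")
  names(blocks) <- nm
  structure(list(blocks = blocks,
                 missing_partner_policy = missing_partner_policy,
                 outcome_name = outcome_name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification (", length(x$blocks), " blocks, outcome '",
      x$outcome_name, "', missing-partner policy '",
      x$missing_partner_policy, "')\n", sep = "")
  for (b in x$blocks)
    cat(sprintf("  %-18s %-11s ref=%-14s levels: %s%s\n", b$name, b$kind,
                b$reference, paste(b$levels, collapse = ", "),
                if (b$partner) "  [partner]" else ""))
  invisible(x)
}

spec_design_colnames <- function(spec) {
  cols <- "(Intercept)"
  for (b in spec$blocks) {
    nonref <- setdiff(b$levels, b$reference)
    cols <- c(cols, if (b$kind == "binary") b$name
              else paste(b$name, nonref, sep = ":"))
  }
  if (spec$missing_partner_policy == "dummy" &&
      any(vapply(spec$blocks, `[[`, logical(1), "partner")))
    cols <- c(cols, "missing_partner")
  cols
}

required_columns <- function(spec) {
  c(spec$outcome_name, "weight", "stratum", "psu",
    vapply(spec$blocks, `[[`, character(1), "name"))
}

#' Read birth-level micro-data from CSV
#'
#' Expects comma-separated UTF-8 with a header row: the outcome column,
#' `weight`, `stratum`, `psu`, `wealth_index` and/or `wealth_quintile`,
#' and one column per covariate block of `spec`.  Optional columns
#' `household` (for household-level quintile cuts) and `group` are kept.
#'
#' @param path CSV file path (or connection).
#' @param spec a [model_spec()].
#' @return a validated `data.frame` of class `"microdata"`.
#' @export
read_microdata <- function(path, spec) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  as_microdata(tab, spec)
}

#' Validate a data.frame as micro-data
#'
#' @param tab data.frame.
#' @param spec a [model_spec()].
#' @return `tab` with class `"microdata"` prepended.
#' @export
as_microdata <- function(tab, spec) {
  req <- required_columns(spec)
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!any(c("wealth_index", "wealth_quintile") %in% names(tab)))
    stop("schema error: need wealth_index or wealth_quintile column")
  y <- tab[[spec$outcome_name]]
  bad <- which(!(y %in% c(0L, 1L)))
  if (length(bad))
    stop("validation error: non-binary outcome value in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (any(!is.finite(tab$weight) | tab$weight <= 0))
    stop("validation error: non-positive weight in row(s): ",
         paste(utils::head(which(!is.finite(tab$weight) | tab$weight <= 0),
                           10L), collapse = ", "))
  if ("wealth_quintile" %in% names(tab)) {
    q <- tab$wealth_quintile
    badq <- which(!is.na(q) & !(q %in% 1:5))
    if (length(badq))
      stop("validation error: wealth_quintile outside 1..5 in row(s): ",
           paste(utils::head(badq, 10L), collapse = ", "))
  }
  class(tab) <- unique(c("microdata", class(tab)))
  tab
}

#' Write micro-data to CSV
#'
#' Inverse of [read_microdata()]: comma separator, `"."` decimal, header
#' row, UTF-8, no row names.
#'
#' @param table micro-data table.
#' @param path output file path.
#' @export
write_microdata <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Assign wealth quintiles and poor/non-poor groups
#'
#' Quintile boundaries are weighted quantiles of the wealth index at
#' cumulative shares 0.2/0.4/0.6/0.8, computed over households (rows with
#' a `household` column are collapsed to one observation per household;
#' otherwise every row counts as a household) and then propagated to all
#' births of the household.  A household's quintile is 1 plus the number
#' of boundaries strictly below its index.  Poor = bottom two quintiles;
#' non-poor = top three.
#'
#' @param table micro-data with a `wealth_index` column and positive
#'   weights.
#' @return the table with `wealth_quintile` and `group` columns filled.
#' @export
assign_wealth_groups <- function(table) {
  if (!"wealth_index" %in% names(table))
    stop("wealth_index column required to assign wealth groups")
  wi <- table$wealth_index
  if (anyNA(wi)) stop("wealth_index contains missing values")
  if (diff(range(wi)) == 0)
    stop("wealth_index is constant: quintiles undefined")
  if ("household" %in% names(table)) {
    hh <- !duplicated(table$household)
    x <- wi[hh]; w <- table$weight[hh]
    if (diff(range(x)) == 0)
      stop("wealth_index is constant across households: quintiles undefined")
  } else {
    x <- wi; w <- table$weight
  }
  cuts <- weighted_quantile(x, w, c(0.2, 0.4, 0.6, 0.8))
  q <- 1L + rowSums(outer(wi, cuts, `>`))
  table$wealth_quintile <- as.integer(q)
  table$group <- ifelse(q <= 2L, "poor", "nonpoor")
  table
}

#' Build the estimation design matrix from micro-data
#'
#' Dummy-codes every block against its reference level, with a leading
#' intercept column.  Missing-data handling: under the `"dummy"` policy a
#' record with any missing partner-block value is retained with all its
#' partner dummies set to 0 and the `missing_partner` indicator set to 1;
#' any other missing covariate value causes listwise deletion.  Rows for
#' a specific `group` can be selected with the `group` argument.
#'
#' @param table micro-data table.
#' @param spec a [model_spec()].
#' @param group optional `"poor"` / `"nonpoor"` filter (requires assigned
#'   groups).
#' @return an object of class `"design_matrix"`: list with `X` (numeric
#'   matrix, leading intercept), `y`, `weights`, `psu`, `stratum`,
#'   `block_cols` (block name -> column indices), `row_ids` (row numbers
#'   of `table` retained), `n_dropped`, and the `spec`.
#' @export
build_design_matrix <- function(table, spec, group = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  miss_block <- setdiff(required_columns(spec), names(table))
  if (length(miss_block))
    stop("spec block column(s) absent from table: ",
         paste(miss_block, collapse = ", "))
  tab <- as.data.frame(table)
  orig_rows <- seq_len(nrow(tab))
  if (!is.null(group)) {
    if (!"group" %in% names(tab))
      stop("groups not assigned; run assign_wealth_groups() first")
    sel <- tab$group == group
    tab <- tab[sel, , drop = FALSE]
    orig_rows <- orig_rows[sel]
  }
  blocks <- spec$blocks
  partner_blocks <- names(blocks)[vapply(blocks, `[[`, logical(1), "partner")]
  use_dummy <- spec$missing_partner_policy == "dummy" &&
    length(partner_blocks) > 0L

  # validate declared levels before any dropping so errors name real data
  for (b in blocks) {
    v <- tab[[b$name]]
    bad <- !is.na(v) & !(as.character(v) %in% b$levels)
    if (any(bad))
      stop("coding error in block '", b$name, "': undeclared level '",
           as.character(v[bad][1L]), "'")
  }

  nonpartner <- setdiff(names(blocks), if (use_dummy) partner_blocks else character())
  drop_mask <- Reduce(`|`, lapply(nonpartner, function(nm) is.na(tab[[nm]])),
                      rep(FALSE, nrow(tab)))
  keep <- which(!drop_mask)
  n_dropped <- sum(drop_mask)
  tab2 <- tab[keep, , drop = FALSE]
  partner_missing <- if (use_dummy)
    Reduce(`|`, lapply(partner_blocks, function(nm) is.na(tab2[[nm]])),
           rep(FALSE, nrow(tab2)))
  else rep(FALSE, nrow(tab2))

  cols <- spec_design_colnames(spec)
  X <- matrix(0, nrow(tab2), length(cols), dimnames = list(NULL, cols))
  X[, 1L] <- 1
  block_cols <- list()
  j <- 2L
  for (b in blocks) {
    nonref <- setdiff(b$levels, b$reference)
    idx <- j:(j + length(nonref) - 1L)
    v <- as.character(tab2[[b$name]])
    for (k in seq_along(nonref)) {
      col <- ifelse(is.na(v), 0, as.numeric(v == nonref[k]))
      if (b$partner && use_dummy) col[partner_missing] <- 0
      X[, idx[k]] <- col
    }
    block_cols[[b$name]] <- idx
    j <- j + length(nonref)
  }
  if (use_dummy) {
    X[, "missing_partner"] <- as.numeric(partner_missing)
    block_cols[["missing_partner"]] <- j
  }
  structure(list(
    X = X,
    y = as.numeric(tab2[[spec$outcome_name]]),
    weights = as.numeric(tab2$weight),
    psu = as.character(tab2$psu),
    stratum = as.character(tab2$stratum),
    block_cols = block_cols,
    row_ids = orig_rows[keep],
    n_retained = nrow(tab2),
    n_dropped = n_dropped,
    spec = spec
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", x$n_retained, "rows retained,", x$n_dropped,
      "dropped,", ncol(x$X), "columns,",
      length(x$block_cols), "blocks\n")
  invisible(x)
}

#' Read a model specification from YAML
#'
#' Expected layout: `outcome`, `missing_partner_policy`, and a `blocks`
#' list of maps with keys `name`, `kind`, `levels`, `reference`,
#' `partner`.
#'
#' @param path YAML file.
#' @return a [model_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  blocks <- lapply(cfg$blocks, function(b)
    spec_block(b$name, b$kind, b$levels,
               b$reference %||% b$levels[[1L]], isTRUE(b$partner)))
  model_spec(blocks,
             missing_partner_policy = cfg$missing_partner_policy %||% "dummy",
             outcome_name = cfg$outcome %||% "outcome")
}

#' Write a model specification to YAML
#' @param spec a [model_spec()].
#' @param path output file.
#' @export
write_model_spec <- function(spec, path) {
  cfg <- list(
    outcome = spec$outcome_name,
    missing_partner_policy = spec$missing_partner_policy,
    blocks = lapply(unname(spec$blocks), function(b)
      list(name = b$name, kind = b$kind, levels = as.list(b$levels),
           reference = b$reference, partner = b$partner)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
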