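property_columns <- function(properties) {
  setdiff(names(properties), c("substance_id", "molecular_weight"))
}

#' Drop members of highly correlated property groups
#'
#' Computes pairwise Pearson correlations between descriptor columns, links
#' pairs whose |r| exceeds `threshold` into connected groups, and keeps
#' exactly one property per group: the one appearing earliest in
#' `keep_priority`. This mirrors the usual collinearity pruning applied to
#' QSAR descriptor sets before regression; which member survives is a
#' judgment call, so the priority order is explicit configuration.
#'
#' @param properties Substance-property table (one row per substance).
#' @param threshold Absolute Pearson correlation above which two properties
#'   are considered redundant.
#' @param keep_priority Character vector ordering all descriptor columns from
#'   most to least preferred; defaults to column order.
#' @return Character vector of retained property names, in original column
#'   order.
#' @export
prune_correlated <- function(properties, threshold = 0.85,
                             keep_priority = NULL) {
  cols <- property_columns(properties)
  if (nrow(properties) < 2L) abort("need at least two substances to estimate correlations")
  keep_priority <- keep_priority %||% cols
  if (!all(cols %in% keep_priority)) {
    abort(sprintf("`keep_priority` is missing properties: %s",
                  paste(setdiff(cols, keep_priority), collapse = ", ")))
  }
  R <- abs(stats::cor(as.matrix(properties[cols])))
  adj <- R > threshold
  diag(adj) <- FALSE
  # connected components of the redundancy graph
  comp <- rep(NA_integer_, length(cols))
  cid <- 0L
  for (s in seq_along(cols)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  prio <- match(cols, keep_priority)
  keep <- vapply(split(seq_along(cols), comp), function(members) {
    members[which.min(prio[members])]
  }, integer(1))
  cols[sort(keep)]
}

#' Center and scale property columns
#'
#' Standardizes each descriptor column to zero mean and unit (sample)
#' variance. Parameters are estimated on `fit_rows` only (the training
#' substances) and can be re-applied to new rows via `params`, so test or
#' screening substances are always transformed with the training moments.
#'
#' @param properties Substance-property table.
#' @param fit_rows Logical or integer index of rows used to estimate means
#'   and sds; default all rows.
#' @param params Optional parameter table from a previous call; when given,
#'   it is applied as-is and nothing is estimated.
#' @param columns Descriptor columns to transform; default all property
#'   columns present.
#' @return A list with `data` (the table with transformed columns) and
#'   `params` (data.frame `property`, `mean`, `sd`).
#' @export
standardize <- function(properties, fit_rows = NULL, params = NULL,
                        columns = NULL) {
  columns <- columns %||% property_columns(properties)
  if (is.null(params)) {
    fit_rows <- fit_rows %||% seq_len(nrow(properties))
    sub <- properties[fit_rows, columns, drop = FALSE]
    mu <- vapply(sub, mean, numeric(1))
    sd <- vapply(sub, stats::sd, numeric(1))
    bad <- names(sd)[!is.finite(sd) | sd == 0]
    if (length(bad)) {
      abort(sprintf("constant property column(s) on the fitting rows: %s",
                    paste(bad, collapse = ", ")))
    }
    params <- data.frame(property = columns, mean = unname(mu),
                         sd = unname(sd), stringsAsFactors = FALSE)
  } else {
    if (!all(columns %in% params$property)) {
      abort("`params` does not cover all requested columns")
    }
    params <- params[match(columns, params$property), , drop = FALSE]
  }
  out <- properties
  for (i in seq_along(columns)) {
    cl <- columns[i]
    out[[cl]] <- (properties[[cl]] - params$mean[i]) / params$sd[i]
  }
  list(data = out, params = params)
}

# per-substance design rows (main effects + all two-way interactions) from a
# standardized property table; rownames are substance ids
design_rows <- function(std_properties) {
  cols <- property_columns(std_properties)
  X <- as.matrix(std_properties[cols])
  P <- length(cols)
  if (P >= 2L) {
    pairs <- utils::combn(P, 2L)
    inter <- X[, pairs[1L, ], drop = FALSE] * X[, pairs[2L, ], drop = FALSE]
    colnames(inter) <- paste(cols[pairs[1L, ]], "x", cols[pairs[2L, ]])
    X <- cbind(X, inter)
  }
  rownames(X) <- std_properties$substance_id
  X
}

#' Build the observation-aligned design matrix
#'
#' Expands standardized property main effects with all pairwise interaction
#' columns (labelled `"a x b"`, computed as elementwise products of the
#' standardized mains and not re-standardized) and aligns one row per
#' observation by substance id. Width is `P + P*(P-1)/2`.
#'
#' @param std_properties Standardized substance-property table (see
#'   [standardize()]); may carry the standardization parameters.
#' @param observations Observation table with a `substance_id` column.
#' @return Numeric matrix with attributes `main_columns` (the property
#'   names) and, when available on input, `standardization`.
#' @export
build_design_matrix <- function(std_properties, observations) {
  rows <- design_rows(std_properties)
  idx <- match(observations$substance_id, rownames(rows))
  if (anyNA(idx)) {
    missing <- unique(observations$substance_id[is.na(idx)])
    abort(sprintf("no property row for substance(s): %s",
                  paste(utils::head(missing, 10L), collapse = ", ")))
  }
  X <- rows[idx, , drop = FALSE]
  rownames(X) <- NULL
  attr(X, "main_columns") <- property_columns(std_properties)
  X
}
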