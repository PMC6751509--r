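# Internal validators shared across modules.

check_scalar_prob <- function(x, name, lower = 0, upper = 1,
                              lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s, got %g.",
      name, if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]", x
    ))
  }
  invisible(x)
}

# A similarity matrix must be square, numeric, with matching dimnames.
check_square_named <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be square, got %d x %d.", name, nrow(m), ncol(m)))
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    abort(sprintf("`%s` must carry identical row and column names.", name))
  }
  invisible(m)
}

check_disease_similarity <- function(dsim, tol = 1e-12) {
  check_square_named(dsim, "dsim")
  if (max(abs(dsim - t(dsim))) > tol) {
    abort("`dsim` must be symmetric.")
  }
  if (any(abs(diag(dsim) - 1) > tol)) {
    abort("`dsim` must have a unit diagonal.")
  }
  if (any(dsim < -tol | dsim > 1 + tol)) {
    abort("`dsim` entries must lie in [0, 1].")
  }
  invisible(dsim)
}

# Association tables are plain data frames with `circrna` and `disease`
# columns; coerce and validate once at module boundaries.
as_assoc <- function(assoc, name = "assoc") {
  if (!is.data.frame(assoc)) {
    abort(sprintf("`%s` must be a data frame of circRNA-disease pairs.", name))
  }
  if (!all(c("circrna", "disease") %in% names(assoc))) {
    abort(sprintf("`%s` must have `circrna` and `disease` columns.", name))
  }
  out <- dplyr::distinct(
    tibble::as_tibble(assoc)[, intersect(c("circrna", "disease", "source"), names(assoc))],
    .data$circrna, .data$disease, .keep_all = TRUE
  )
  if (any(!nzchar(out$circrna)) || any(!nzchar(out$disease)) ||
      anyNA(out$circrna) || anyNA(out$disease)) {
    abort(sprintf("`%s` contains empty or missing identifiers.", name))
  }
  out
}

assoc_label <- function(assoc, default = "assoc") {
  lbl <- attr(assoc, "label", exact = TRUE)
  if (is.null(lbl) && "source" %in% names(assoc) &&
      length(unique(assoc$source)) == 1L) {
    lbl <- assoc$source[[1L]]
  }
  lbl %||% default
}

# DisSet(c): diseases curated for one circRNA.
disease_set <- function(assoc, circrna) {
  sort(unique(assoc$disease[assoc$circrna == circrna]))
}
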