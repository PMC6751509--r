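# Spearman expression similarity per source, max-combination over sources,
# and the tau sparsification filter.

#' Spearman rank correlation between two expression profiles
#'
#' Positions missing in either vector are removed pairwise. Ties receive
#' average ranks and the correlation is the Pearson correlation of the rank
#' vectors, which reduces exactly to the classical
#' `1 - 6 * sum(d_i^2) / (n * (n^2 - 1))` form when no ties are present.
#'
#' @param x,y Numeric vectors of equal length (expression across conditions).
#' @return The rank correlation in \[-1, 1\], or `NA_real_` when the
#'   similarity is undefined: fewer than 3 shared non-missing positions, or a
#'   constant vector (zero rank variance). `NA` is an "absent similarity"
#'   signal, distinct from a correlation of 0.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) {
    return(NA_real_)
  }
  rx <- rank(x[keep])
  ry <- rank(y[keep])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(NA_real_)
  }
  cor(rx, ry)
}

#' All-pairs expression similarity for one source
#'
#' Computes the Spearman correlation between every pair of circRNA expression
#' profiles in one source, giving the source's raw similarity matrix.
#'
#' @param expr Numeric matrix, rows = circRNAs (rownames required),
#'   columns = conditions; `NA` marks missing measurements.
#' @return A symmetric similarity matrix with unit diagonal; entries are
#'   `NA` where the pairwise similarity is undefined (see [spearman_rho()]).
#'   Attribute `stage = "raw"`; the `source` attribute of `expr` is carried
#'   through.
#' @export
expression_similarity <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix.")
  }
  if (is.null(rownames(expr))) abort("`expr` must carry circRNA rownames.")
  if (nrow(expr) < 2L) abort("Need at least 2 circRNAs.")
  n <- nrow(expr)
  ids <- rownames(expr)

  if (!anyNA(expr)) {
    # common case: rank each profile once, then Pearson on ranks
    ranks <- t(apply(expr, 1L, rank))
    sim <- suppressWarnings(cor(t(ranks))) # constant rows -> NA
    if (ncol(expr) < 3L) sim[] <- NA_real_
  } else {
    sim <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        sim[i, j] <- sim[j, i] <- spearman_rho(expr[i, ], expr[j, ])
      }
    }
  }
  diag(sim) <- 1
  dimnames(sim) <- list(ids, ids)
  attr(sim, "stage") <- "raw"
  attr(sim, "source") <- attr(expr, "source", exact = TRUE)
  sim
}

#' Combine per-source expression similarities and apply the tau filter
#'
#' For a circRNA pair measured in both sources the combined similarity is the
#' maximum of the two raw similarities; the combined value is kept when it
#' reaches the threshold `tau` and set to 0 otherwise. Pairs measured in only
#' one source are by default thresholded on that source's value alone
#' (discarding measured evidence would be strictly less informative);
#' `both_sources_only = TRUE` restores the strict both-sources rule, zeroing
#' single-source pairs. Undefined similarities count as absent.
#'
#' @param cb Raw similarity matrix of the first source
#'   (see [expression_similarity()]).
#' @param cp Raw similarity matrix of the second source, or `NULL` when only
#'   one source is available.
#' @param tau Similarity threshold in (0, 1\]; default 0.7.
#' @param both_sources_only Logical; zero out pairs not measured in both
#'   sources. Default `FALSE`.
#' @return A symmetric matrix over the union of circRNA IDs whose entries lie
#'   in `{0} U [tau, 1]`, with unit diagonal and attributes
#'   `stage = "combined"` and `tau`.
#' @export
combine_expression_similarity <- function(cb, cp = NULL, tau = 0.7,
                                          both_sources_only = FALSE) {
  check_scalar_prob(tau, "tau", lower = 0, upper = 1, lower_open = TRUE)
  check_square_named(cb, "cb")
  if (!is.null(cp)) check_square_named(cp, "cp")

  ids <- sort(union(rownames(cb), if (is.null(cp)) character() else rownames(cp)))
  align <- function(m) {
    out <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    if (!is.null(m)) {
      common <- intersect(ids, rownames(m))
      out[common, common] <- m[common, common]
    }
    out
  }
  a <- align(cb)
  b <- align(cp)

  combined <- pmax(a, b, na.rm = TRUE) # NA only where both absent
  if (both_sources_only) {
    combined[is.na(a) | is.na(b)] <- NA_real_
  }
  combined[is.na(combined)] <- 0
  combined[combined < tau] <- 0
  diag(combined) <- 1
  attr(combined, "stage") <- "combined"
  attr(combined, "tau") <- tau
  combined
}

#' Count retained circRNA pairs in a combined similarity matrix
#'
#' @param exsim A combined-thresholded matrix from
#'   [combine_expression_similarity()].
#' @return Number of unordered off-diagonal pairs with nonzero similarity.
#' @export
n_similar_pairs <- function(exsim) {
  check_square_named(exsim, "exsim")
  sum(exsim[upper.tri(exsim)] > 0)
}
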