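# Disease-association score vectors and cosine functional similarity.

#' Association score between one disease and one circRNA
#'
#' The score is 1 when the disease is curated for the circRNA; otherwise it
#' is the maximum similarity between the disease and any disease in the
#' circRNA's curated disease set.
#'
#' @param dis Disease ID.
#' @param circrna circRNA ID; must have at least one curated disease.
#' @param assoc Association table (columns `circrna`, `disease`).
#' @param dsim Disease similarity matrix (symmetric, unit diagonal, values in
#'   \[0, 1\]).
#' @return A score in \[0, 1\].
#' @export
disease_score <- function(dis, circrna, assoc, dsim) {
  assoc <- as_assoc(assoc)
  check_disease_similarity(dsim)
  ds <- disease_set(assoc, circrna)
  if (length(ds) == 0L) {
    abort(sprintf("circRNA '%s' has no curated disease; it is outside the disease-related set.", circrna))
  }
  if (!dis %in% rownames(dsim)) {
    abort(sprintf("Disease '%s' is absent from the disease similarity matrix.", dis))
  }
  if (dis %in% ds) {
    return(1)
  }
  missing <- setdiff(ds, rownames(dsim))
  if (length(missing)) {
    abort(sprintf("Disease(s) %s absent from the disease similarity matrix.",
                  paste(missing, collapse = ", ")))
  }
  max(dsim[dis, ds])
}

#' Build the circRNA x disease association score matrix
#'
#' Fills a dense matrix of scores for every circRNA in the association table
#' (set C) against every circRNA-related disease (set D, the diseases
#' appearing in the table). Known-association cells are exactly 1.
#'
#' @inheritParams disease_score
#' @return A numeric matrix (rows = circRNAs, columns = diseases) of scores
#'   in \[0, 1\].
#' @export
score_matrix <- function(assoc, dsim) {
  assoc <- as_assoc(assoc)
  check_disease_similarity(dsim)
  circ <- sort(unique(assoc$circrna))
  diseases <- sort(unique(assoc$disease))
  missing <- setdiff(diseases, rownames(dsim))
  if (length(missing)) {
    abort(sprintf("Disease(s) %s absent from the disease similarity matrix.",
                  paste(missing, collapse = ", ")))
  }
  sub <- dsim[diseases, diseases, drop = FALSE]
  scores <- matrix(0, length(circ), length(diseases),
                   dimnames = list(circ, diseases))
  for (c_id in circ) {
    ds <- disease_set(assoc, c_id)
    # max similarity to any curated disease, per candidate disease
    scores[c_id, ] <- apply(sub[, ds, drop = FALSE], 1L, max)
    scores[c_id, ds] <- 1
  }
  scores
}

#' Cosine similarity between two score vectors
#'
#' @param u,v Nonnegative numeric vectors of equal length.
#' @return The cosine of the angle between `u` and `v`, clamped to \[0, 1\]
#'   against floating-point rounding; `NA_real_` for a zero vector.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(NA_real_)
  }
  min(max(sum(u * v) / (nu * nv), 0), 1)
}

#' All-pairs circRNA functional similarity
#'
#' Cosine similarity between every pair of rows of the association score
#' matrix. Score rows of circRNAs in set C always contain a 1 (their known
#' associations), so the result is fully defined with unit diagonal.
#'
#' @param scores Score matrix from [score_matrix()].
#' @return A symmetric similarity matrix over the circRNAs with entries in
#'   \[0, 1\] and unit diagonal.
#' @export
functional_similarity <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) < 2L) {
    abort("`scores` must be a matrix with at least 2 circRNA rows.")
  }
  norms <- sqrt(rowSums(scores^2))
  if (any(norms == 0)) {
    abort(sprintf("Zero score vector for circRNA(s): %s.",
                  paste(rownames(scores)[norms == 0], collapse = ", ")))
  }
  sim <- (scores %*% t(scores)) / outer(norms, norms)
  sim[sim < 0] <- 0
  sim[sim > 1] <- 1
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(scores), rownames(scores))
  sim
}
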