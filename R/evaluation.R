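# Cross-database hold-out validation, per-disease AUC, threshold sweep and
# the cosine-only ablation.

#' Extract cross-database test cases
#'
#' For every disease present in both databases, a test case collects the
#' circRNAs that (a) are nodes of the network built from the network
#' database (i.e. appear in its pairs), (b) have no association with the
#' disease in the network database, and (c) are curated for the disease in
#' the reference database. Diseases with no qualifying circRNA are omitted.
#'
#' @param network_db Association table the network is built from.
#' @param reference_db Independent association table supplying held-out
#'   positives.
#' @return Tibble with columns `disease`, `positives` (list-column of
#'   circRNA IDs) and `n_positives`.
#' @export
extract_test_cases <- function(network_db, reference_db) {
  network_db <- as_assoc(network_db, "network_db")
  reference_db <- as_assoc(reference_db, "reference_db")
  net_circ <- unique(network_db$circrna)
  shared_dis <- intersect(unique(network_db$disease), unique(reference_db$disease))

  net_keys <- paste(network_db$circrna, network_db$disease)
  cases <- purrr::map_dfr(sort(shared_dis), function(dis) {
    ref_circ <- unique(reference_db$circrna[reference_db$disease == dis])
    pos <- ref_circ[ref_circ %in% net_circ &
                      !(paste(ref_circ, dis) %in% net_keys)]
    if (length(pos) == 0L) {
      return(NULL)
    }
    tibble::tibble(disease = dis, positives = list(sort(pos)),
                   n_positives = length(pos))
  })
  if (nrow(cases)) {
    # hard guarantee: no selected pair may exist in the network database
    sel <- unlist(purrr::map2(cases$positives, cases$disease, paste))
    stopifnot(!any(sel %in% net_keys))
  }
  cases
}

#' AUC of a candidate ranking against held-out positives
#'
#' The rank-sum (Mann-Whitney) estimator over the candidate list: the
#' fraction of (positive, negative) pairs where the positive scores higher,
#' counting score ties as 1/2.
#'
#' @param ranking Data frame with columns `circrna` and `score` (e.g. the
#'   `candidates` tibble of [personal_rank()]).
#' @param positives Character vector of held-out positive circRNAs; must all
#'   be present in `ranking`.
#' @return AUC in \[0, 1\], or `NA_real_` when there are no positives or no
#'   negatives.
#' @export
auc_from_ranking <- function(ranking, positives) {
  if (!all(c("circrna", "score") %in% names(ranking))) {
    abort("`ranking` needs `circrna` and `score` columns.")
  }
  missing <- setdiff(positives, ranking$circrna)
  if (length(missing)) {
    abort(sprintf("Positive(s) not in the ranking: %s.",
                  paste(missing, collapse = ", ")))
  }
  is_pos <- ranking$circrna %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    return(NA_real_)
  }
  r <- rank(ranking$score) # average ranks handle score ties as 1/2
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run the cross-database validation scheme
#'
#' Builds the heterogeneous network from `network_db`, extracts held-out
#' test cases against `reference_db`, runs PersonalRank once per test-case
#' disease, and scores each disease by the AUC of its candidate ranking over
#' all of that disease's positives jointly. The summary macro-average is the
#' unweighted mean of per-disease AUCs; a positive-weighted pooled mean is
#' reported alongside.
#'
#' @param network_db,reference_db Association tables (see
#'   [extract_test_cases()]).
#' @param dsim Disease similarity matrix covering every disease in
#'   `network_db`.
#' @param expr Optional list of per-source expression matrices (1 or 2
#'   entries) used to compute expression similarity; `NULL` for the
#'   cosine-only network.
#' @param exsim Optional precomputed combined-thresholded expression
#'   similarity matrix; overrides `expr`.
#' @param tau Expression-similarity threshold in (0, 1\]. Default 0.7.
#' @param d,tol,max_iter,weighted PersonalRank parameters
#'   (see [personal_rank()]).
#' @param both_sources_only Passed to [combine_expression_similarity()].
#' @return A `precda_validation`: list with `results` (tibble: `disease`,
#'   `n_positives`, `n_candidates`, `auc`), `macro_auc`, `pooled_auc`,
#'   `n_test_cases` and the parameters used.
#' @export
run_validation <- function(network_db, reference_db, dsim,
                           expr = NULL, exsim = NULL, tau = 0.7,
                           d = 0.85, tol = 1e-10, max_iter = 1000L,
                           weighted = TRUE, both_sources_only = FALSE) {
  network_db <- as_assoc(network_db, "network_db")
  reference_db <- as_assoc(reference_db, "reference_db")

  if (is.null(exsim) && !is.null(expr) && length(expr)) {
    raw <- lapply(expr, expression_similarity)
    exsim <- combine_expression_similarity(
      raw[[1L]], if (length(raw) >= 2L) raw[[2L]] else NULL,
      tau = tau, both_sources_only = both_sources_only
    )
  }
  fnsim <- functional_similarity(score_matrix(network_db, dsim))
  net <- build_network(fnsim, exsim, network_db)

  cases <- extract_test_cases(network_db, reference_db)
  results <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    dis <- cases$disease[[i]]
    pr <- personal_rank(net, dis, d = d, tol = tol,
                        max_iter = max_iter, weighted = weighted)
    tibble::tibble(
      disease = dis,
      n_positives = cases$n_positives[[i]],
      n_candidates = nrow(pr$candidates),
      auc = auc_from_ranking(pr$candidates, cases$positives[[i]])
    )
  })
  if (nrow(results) == 0L) {
    results <- tibble::tibble(disease = character(), n_positives = integer(),
                              n_candidates = integer(), auc = double())
  }
  auc_ok <- results$auc[!is.na(results$auc)]
  w <- results$n_positives[!is.na(results$auc)]
  structure(
    list(
      results = results,
      macro_auc = if (length(auc_ok)) mean(auc_ok) else NA_real_,
      pooled_auc = if (length(auc_ok)) sum(auc_ok * w) / sum(w) else NA_real_,
      n_test_cases = nrow(results),
      network_db = assoc_label(network_db, "network_db"),
      reference_db = assoc_label(reference_db, "reference_db"),
      tau = tau, d = d,
      used_expression = !is.null(exsim)
    ),
    class = "precda_validation"
  )
}

#' Cosine-only ablation of the validation scheme
#'
#' Identical pipeline with all expression similarities forced to zero, so
#' circRNA-circRNA weights reduce to functional similarity alone.
#'
#' @inheritParams run_validation
#' @return A `precda_validation`.
#' @export
ablation_cosine_only <- function(network_db, reference_db, dsim,
                                 d = 0.85, tol = 1e-10, max_iter = 1000L,
                                 weighted = TRUE) {
  run_validation(network_db, reference_db, dsim, expr = NULL, exsim = NULL,
                 d = d, tol = tol, max_iter = max_iter, weighted = weighted)
}

#' Sweep the expression-similarity threshold
#'
#' Re-runs the full validation for each threshold and reports the number of
#' retained circRNA pairs and the macro-averaged AUC per threshold. Raw
#' per-source similarities are computed once and re-thresholded.
#'
#' @param taus Numeric vector of thresholds, each in (0, 1\].
#' @inheritParams run_validation
#' @return Tibble with columns `tau`, `n_pairs`, `macro_auc`,
#'   `n_test_cases`.
#' @export
threshold_sweep <- function(taus, network_db, reference_db, dsim, expr,
                            d = 0.85, tol = 1e-10, max_iter = 1000L,
                            weighted = TRUE, both_sources_only = FALSE) {
  raw <- lapply(expr, expression_similarity)
  purrr::map_dfr(taus, function(tau) {
    exsim <- combine_expression_similarity(
      raw[[1L]], if (length(raw) >= 2L) raw[[2L]] else NULL,
      tau = tau, both_sources_only = both_sources_only
    )
    v <- run_validation(network_db, reference_db, dsim, exsim = exsim,
                        tau = tau, d = d, tol = tol, max_iter = max_iter,
                        weighted = weighted)
    tibble::tibble(tau = tau, n_pairs = n_similar_pairs(exsim),
                   macro_auc = v$macro_auc, n_test_cases = v$n_test_cases)
  })
}

#' @export
print.precda_validation <- function(x, ...) {
  cat(sprintf(
    "<precda_validation> %s vs %s: %d test-case diseases, macro AUC %.4f (pooled %.4f)\n",
    x$network_db, x$reference_db, x$n_test_cases,
    x$macro_auc, x$pooled_auc
  ))
  print(x$results)
  invisible(x)
}

#' @describeIn run_validation Per-disease results as a tibble.
#' @param x A `precda_validation`.
#' @param ... Unused.
#' @method tidy precda_validation
#' @export
tidy.precda_validation <- function(x, ...) {
  x$results
}

#' @describeIn run_validation One-row summary (macro and pooled AUC).
#' @method glance precda_validation
#' @export
glance.precda_validation <- function(x, ...) {
  tibble::tibble(
    network_db = x$network_db,
    reference_db = x$reference_db,
    n_test_cases = x$n_test_cases,
    macro_auc = x$macro_auc,
    pooled_auc = x$pooled_auc,
    tau = x$tau,
    d = x$d,
    used_expression = x$used_expression
  )
}

#' @describeIn run_validation Per-disease AUC bar chart with the macro mean.
#' @param object A `precda_validation`.
#' @method autoplot precda_validation
#' @export
autoplot.precda_validation <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(
    x = stats::reorder(.data$disease, .data$auc), y = .data$auc
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$macro_auc, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "AUC",
      title = sprintf("Per-disease AUC (macro mean %.3f)", object$macro_auc)
    )
}

#' Line plot of a threshold sweep
#'
#' @param sweep Tibble from [threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$tau, y = .data$macro_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = "Macro-averaged AUC")
}
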