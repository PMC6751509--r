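# PersonalRank: random walk with restart at a single target node.

#' Row-normalised transition matrix of a network
#'
#' Each node's outgoing probability mass is split among its neighbours in
#' proportion to edge weight (`weighted = TRUE`) or uniformly over its degree
#' (`weighted = FALSE`, the literal out-degree formulation; both coincide on
#' unweighted graphs). Rows of isolated nodes are all zero, so a walker there
#' is reinjected only through the restart term.
#'
#' @param net A `precda_network`.
#' @param weighted Normalise by summed edge weight rather than degree.
#' @return A dense row-stochastic (or zero-row) matrix over all nodes.
#' @export
transition_matrix <- function(net, weighted = TRUE) {
  nodes <- net$nodes$node
  n <- length(nodes)
  w <- net$edges$weight
  if (any(w < 0)) abort("Negative edge weights are not allowed.")
  if (!weighted) w <- rep(1, length(w))
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(net$edges$from, nodes)
  j <- match(net$edges$to, nodes)
  # undirected: each edge contributes two directed arcs
  adj[cbind(i, j)] <- adj[cbind(i, j)] + w
  adj[cbind(j, i)] <- adj[cbind(j, i)] + w
  strength <- rowSums(adj)
  pos <- strength > 0
  adj[pos, ] <- adj[pos, , drop = FALSE] / strength[pos]
  adj
}

#' Rank network nodes relative to a target disease by PersonalRank
#'
#' Fixed-point iteration of
#' `PR = (1 - d) * r + d * t(P) %*% PR`, where `P` is the row-normalised
#' transition matrix and `r` is the restart vector (1 at the target, 0
#' elsewhere), initialised at `PR = r`. Iteration stops when the largest
#' absolute componentwise change falls below `tol` or after `max_iter`
#' iterations (flagged, not an error). The candidate ranking lists circRNAs
#' not curated for the target, in descending score order with lexicographic
#' tie-break on the ID.
#'
#' @param net A `precda_network`.
#' @param target Disease node to personalise on; must be in the network.
#' @param d Transfer probability in (0, 1): probability of following an edge
#'   rather than restarting at the target. Default 0.85.
#' @param tol Convergence tolerance on the L-infinity change. Default 1e-10.
#' @param max_iter Maximum number of iterations. Default 1000.
#' @param weighted Use edge weights in the walk (see [transition_matrix()]).
#' @return A `precda_rank`: list with `target`, `scores` (named vector over
#'   all nodes), `candidates` (tibble: `rank`, `circrna`, `score`),
#'   `iterations`, `converged`, and the parameters used.
#' @export
personal_rank <- function(net, target, d = 0.85, tol = 1e-10,
                          max_iter = 1000L, weighted = TRUE) {
  check_scalar_prob(d, "d", lower_open = TRUE, upper_open = TRUE)
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive.")
  if (max_iter < 1L) abort("`max_iter` must be at least 1.")
  nodes <- net$nodes$node
  if (!target %in% nodes) {
    abort(sprintf("Target node '%s' is not in the network.", target))
  }

  pt <- t(transition_matrix(net, weighted = weighted))
  r <- as.numeric(nodes == target)
  pr <- r
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    pr_new <- (1 - d) * r + d * drop(pt %*% pr)
    delta <- max(abs(pr_new - pr))
    pr <- pr_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  scores <- setNames(pr, nodes)

  res <- structure(
    list(
      target = target,
      scores = scores,
      node_type = setNames(net$nodes$type, nodes),
      known = sort(unique(
        net$edges$from[net$edges$type == "cd" & net$edges$to == target]
      )),
      iterations = iter,
      converged = converged,
      d = d, tol = tol, weighted = weighted
    ),
    class = "precda_rank"
  )
  res$candidates <- candidate_table(res)
  res
}

candidate_table <- function(res) {
  circ <- names(res$node_type)[res$node_type == "circRNA"]
  cand <- setdiff(circ, res$known)
  sc <- res$scores[cand]
  ord <- order(-sc, cand)
  tibble::tibble(
    rank = seq_along(ord),
    circrna = cand[ord],
    score = unname(sc[ord])
  )
}

#' @export
print.precda_rank <- function(x, ...) {
  cat(sprintf(
    "<precda_rank> target %s: %d candidate circRNAs (%d known excluded); %s in %d iterations\n",
    x$target, nrow(x$candidates), length(x$known),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(head(x$candidates, 5L))
  invisible(x)
}

#' Re-derive the candidate ranking of a PersonalRank result
#'
#' Removes circRNAs curated for the target in `assoc` and orders the rest by
#' score (descending), breaking ties lexicographically by ID.
#'
#' @param result A `precda_rank`.
#' @param assoc Association table the network was built from.
#' @return Tibble with columns `rank`, `circrna`, `score`.
#' @export
rank_candidates <- function(result, assoc) {
  assoc <- as_assoc(assoc)
  res <- result
  res$known <- sort(unique(assoc$circrna[assoc$disease == result$target]))
  candidate_table(res)
}

#' @describeIn personal_rank Candidate ranking as a tibble.
#' @param x A `precda_rank`.
#' @param ... Unused.
#' @method tidy precda_rank
#' @export
tidy.precda_rank <- function(x, ...) {
  x$candidates
}

#' @describeIn personal_rank One-row run summary.
#' @method glance precda_rank
#' @export
glance.precda_rank <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_nodes = length(x$scores),
    n_candidates = nrow(x$candidates),
    n_known = length(x$known),
    iterations = x$iterations,
    converged = x$converged,
    d = x$d
  )
}

#' @describeIn personal_rank Bar chart of the top-ranked candidates.
#' @param object A `precda_rank`.
#' @param top Number of top candidates to show.
#' @method autoplot precda_rank
#' @export
autoplot.precda_rank <- function(object, top = 20L, ...) {
  df <- head(object$candidates, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$circrna, .data$score), y = .data$score
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "PersonalRank score",
      title = sprintf("Top candidate circRNAs for %s", object$target)
    )
}
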