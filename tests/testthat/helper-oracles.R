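# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct transcription of the defining formula, kept free
# of any package internals.

# Classical no-ties Spearman: 1 - 6 * sum(d_i^2) / (n (n^2 - 1))
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Dense linear-system solution of the personalised random walk:
# (I - d * t(P)) %*% pr = (1 - d) * r
pr_linear_solve <- function(net, target, d = 0.85, weighted = TRUE) {
  nodes <- network_nodes(net)$node
  n <- length(nodes)
  edges <- network_edges(net)
  w <- if (weighted) edges$weight else rep(1, nrow(edges))
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$from[k], nodes)
    j <- match(edges$to[k], nodes)
    adj[i, j] <- adj[i, j] + w[k]
    adj[j, i] <- adj[j, i] + w[k]
  }
  s <- rowSums(adj)
  p <- adj
  p[s > 0, ] <- p[s > 0, , drop = FALSE] / s[s > 0]
  r <- as.numeric(nodes == target)
  setNames(drop(solve(diag(n) - d * t(p), (1 - d) * r)), nodes)
}

# Brute-force Mann-Whitney AUC: enumerate every positive-negative pair.
auc_brute_force <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# All-pairs cosine by direct per-pair evaluation.
cosine_brute_force <- function(m) {
  n <- nrow(m)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(m), rownames(m))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum(m[i, ] * m[j, ]) /
        (sqrt(sum(m[i, ]^2)) * sqrt(sum(m[j, ]^2)))
    }
  }
  out
}

# Small deterministic fixtures -----------------------------------------------

toy_assoc <- function() {
  tibble::tibble(
    circrna = c("circA", "circA", "circB", "circC"),
    disease = c("DOID:1", "DOID:2", "DOID:1", "DOID:3")
  )
}

toy_dsim <- function() {
  ids <- c("DOID:1", "DOID:2", "DOID:3", "DOID:4")
  m <- matrix(
    c(1.0, 0.8, 0.2, 0.1,
      0.8, 1.0, 0.3, 0.1,
      0.2, 0.3, 1.0, 0.6,
      0.1, 0.1, 0.6, 1.0),
    4, 4, byrow = TRUE, dimnames = list(ids, ids)
  )
  m
}

# similarity matrix helper with explicit entries
sym_matrix <- function(ids, entries) {
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  for (e in entries) {
    m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- e[[3]]
  }
  m
}

random_network <- function(n_circ, n_dis, edge_prob = 0.4) {
  circ <- sprintf("c%02d", seq_len(n_circ))
  dis <- sprintf("d%02d", seq_len(n_dis))
  fn <- matrix(0, n_circ, n_circ, dimnames = list(circ, circ))
  for (i in seq_len(n_circ - 1)) {
    for (j in seq(i + 1, n_circ)) {
      if (runif(1) < edge_prob) fn[i, j] <- fn[j, i] <- runif(1)
    }
  }
  diag(fn) <- 1
  assoc <- tidyr::expand_grid(circrna = circ, disease = dis)
  assoc <- assoc[runif(nrow(assoc)) < edge_prob, ]
  if (nrow(assoc) == 0L) {
    assoc <- tibble::tibble(circrna = circ[1], disease = dis[1])
  }
  build_network(fn, NULL, assoc)
}
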