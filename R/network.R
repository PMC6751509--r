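# Assembly of the weighted heterogeneous circRNA-disease network.

#' circRNA-circRNA edge weight
#'
#' The weight between two circRNAs is the average of their functional and
#' expression similarity when the (thresholded) expression similarity is
#' positive, and the functional similarity alone otherwise.
#'
#' @param fnsim Functional similarity value(s) in \[0, 1\].
#' @param exsim Thresholded expression similarity value(s) in
#'   `{0} U [tau, 1]`.
#' @return Numeric weight(s); vectorised over both arguments.
#' @export
circ_weight <- function(fnsim, exsim) {
  if (any(fnsim < 0 | fnsim > 1, na.rm = TRUE)) {
    abort("`fnsim` values must lie in [0, 1].")
  }
  if (any(exsim < 0 | exsim > 1, na.rm = TRUE)) {
    abort("`exsim` values must lie in [0, 1].")
  }
  ifelse(exsim > 0, (fnsim + exsim) / 2, fnsim)
}

#' circRNA-disease edge weight
#'
#' 1 for a curated association, 0 otherwise.
#'
#' @param circrna,disease Vectors of IDs (recycled to common length).
#' @param assoc Association table.
#' @return Numeric 0/1 vector.
#' @export
circdis_weight <- function(circrna, disease, assoc) {
  assoc <- as_assoc(assoc)
  as.numeric(paste(circrna, disease) %in% paste(assoc$circrna, assoc$disease))
}

#' Assemble the heterogeneous circRNA-disease network
#'
#' circRNA-circRNA edges carry [circ_weight()] (only positive weights are
#' stored); every curated circRNA-disease association becomes an edge of
#' weight 1. Disease-disease edges do not exist: disease similarity enters
#' the model only through the score vectors. circRNAs without expression
#' data are treated as having expression similarity 0 against all partners.
#'
#' @param fnsim Functional similarity matrix covering every circRNA in
#'   `assoc` (its rownames define the circRNA node set).
#' @param exsim Combined-thresholded expression similarity matrix, or `NULL`
#'   for the cosine-only network.
#' @param assoc Association table supplying circRNA-disease edges and the
#'   disease node set.
#' @return A `precda_network`: list with `nodes` (tibble: `node`, `type`) and
#'   `edges` (tibble: `from`, `to`, `weight`, `type` in `{"cc", "cd"}`),
#'   undirected, no self-loops, all weights in (0, 1\].
#' @export
build_network <- function(fnsim, exsim = NULL, assoc) {
  assoc <- as_assoc(assoc)
  check_square_named(fnsim, "fnsim")
  circ <- rownames(fnsim)
  missing <- setdiff(unique(assoc$circrna), circ)
  if (length(missing)) {
    abort(sprintf("circRNA(s) in `assoc` missing from `fnsim`: %s.",
                  paste(missing, collapse = ", ")))
  }
  diseases <- sort(unique(assoc$disease))
  clash <- intersect(circ, diseases)
  if (length(clash)) {
    abort(sprintf("ID(s) used both as circRNA and disease: %s.",
                  paste(clash, collapse = ", ")))
  }

  ex <- matrix(0, length(circ), length(circ), dimnames = list(circ, circ))
  if (!is.null(exsim)) {
    check_square_named(exsim, "exsim")
    common <- intersect(circ, rownames(exsim))
    ex[common, common] <- exsim[common, common]
  }

  w <- circ_weight(fnsim[circ, circ], ex)
  ut <- upper.tri(w)
  keep <- ut & w > 0
  idx <- which(keep, arr.ind = TRUE)
  cc <- tibble::tibble(
    from = circ[idx[, "row"]], to = circ[idx[, "col"]],
    weight = w[keep], type = "cc"
  )
  cd <- tibble::tibble(
    from = assoc$circrna, to = assoc$disease,
    weight = 1, type = "cd"
  )
  net <- list(
    nodes = tibble::tibble(
      node = c(circ, diseases),
      type = c(rep("circRNA", length(circ)), rep("disease", length(diseases)))
    ),
    edges = dplyr::bind_rows(cc, cd)
  )
  class(net) <- "precda_network"
  net
}

#' @export
print.precda_network <- function(x, ...) {
  n_circ <- sum(x$nodes$type == "circRNA")
  n_dis <- sum(x$nodes$type == "disease")
  cat(sprintf(
    "<precda_network> %d circRNA + %d disease nodes; %d circRNA-circRNA and %d circRNA-disease edges\n",
    n_circ, n_dis, sum(x$edges$type == "cc"), sum(x$edges$type == "cd")
  ))
  invisible(x)
}

#' Nodes of a heterogeneous network
#' @param net A `precda_network`.
#' @return Tibble with columns `node`, `type`.
#' @export
network_nodes <- function(net) net$nodes

#' Edges of a heterogeneous network
#' @param net A `precda_network`.
#' @return Tibble with columns `from`, `to`, `weight`, `type`.
#' @export
network_edges <- function(net) net$edges

#' Write a network as a weighted edge-list TSV
#'
#' Columns: `node_a`, `node_b`, `weight`, `edge_type` (`cc` or `cd`).
#'
#' @param net A `precda_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  df <- data.frame(node_a = net$edges$from, node_b = net$edges$to,
                   weight = net$edges$weight, edge_type = net$edges$type)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a network from a weighted edge-list TSV
#'
#' @param path Path to a TSV written by [write_network()].
#' @return A `precda_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  edges <- tibble::tibble(from = df$node_a, to = df$node_b,
                          weight = as.numeric(df$weight), type = df$edge_type)
  circ <- unique(c(edges$from[edges$type == "cc"], edges$to[edges$type == "cc"],
                   edges$from[edges$type == "cd"]))
  diseases <- setdiff(unique(edges$to[edges$type == "cd"]), circ)
  net <- list(
    nodes = tibble::tibble(
      node = c(sort(circ), sort(diseases)),
      type = c(rep("circRNA", length(circ)), rep("disease", length(diseases)))
    ),
    edges = edges
  )
  class(net) <- "precda_network"
  net
}
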