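# End-to-end pipeline driver shared by the R interface and the command-line
# wrapper: ingest -> expression similarity -> functional similarity ->
# network -> rank / validate, with versioned, checksummed output headers.

#' Default run configuration
#'
#' @param tau Expression-similarity threshold (default 0.7).
#' @param d PersonalRank transfer probability (default 0.85).
#' @param tol,max_iter PersonalRank convergence controls.
#' @param both_sources_only Strict both-sources rule for
#'   [combine_expression_similarity()].
#' @param unweighted_walk Use the literal out-degree walk instead of the
#'   weighted one.
#' @param ... Path entries: `network_db`, `reference_db`, `dsim`, `expr`
#'   (character vector of 1-2 paths), `target`, `out_dir`.
#' @return A `precda_run_config` list.
#' @export
run_config <- function(tau = 0.7, d = 0.85, tol = 1e-10, max_iter = 1000L,
                       both_sources_only = FALSE, unweighted_walk = FALSE,
                       ...) {
  cfg <- c(
    list(tau = tau, d = d, tol = tol, max_iter = as.integer(max_iter),
         both_sources_only = isTRUE(both_sources_only),
         unweighted_walk = isTRUE(unweighted_walk)),
    list(...)
  )
  check_scalar_prob(cfg$tau, "tau", lower_open = TRUE)
  check_scalar_prob(cfg$d, "d", lower_open = TRUE, upper_open = TRUE)
  structure(cfg, class = "precda_run_config")
}

#' Read a run configuration from YAML or flat key:value text
#'
#' @param path Path to a YAML file (flat `key: value` lines are valid YAML,
#'   so both dialects are read the same way).
#' @return A `precda_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

output_header <- function(config, inputs) {
  sums <- vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  c(
    sprintf("# precda %s", as.character(utils::packageVersion("precda"))),
    sprintf("# config_hash=%s",
            substr(rlang::hash(config[sort(names(unclass(config)))]), 1, 12)),
    sprintf("# input %s md5=%s", inputs, sums)
  )
}

write_with_header <- function(df, path, header_lines) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the full prediction pipeline from files on disk
#'
#' Reads the configured inputs, computes expression and functional
#' similarity, assembles the network, and then either ranks candidates for
#' `target` (writing `ranking_<target>.tsv`) and/or runs the cross-database
#' validation (writing `validation.tsv`) when a `reference_db` is
#' configured. Every output carries a header recording the package version,
#' a configuration hash and input checksums. The run is fully deterministic.
#'
#' @param config A `precda_run_config` (see [run_config()]) carrying paths
#'   `network_db`, `dsim`, `out_dir`, and optionally `expr`, `reference_db`,
#'   `target`.
#' @return Invisibly, a list with the computed `network` and any `ranking` /
#'   `validation` results.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  for (required in c("network_db", "dsim", "out_dir")) {
    if (is.null(config[[required]])) {
      abort(sprintf("`config$%s` is required.", required))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- unlist(config[intersect(
    c("network_db", "reference_db", "dsim", "expr"), names(unclass(config))
  )])
  hdr <- stage("ingest", output_header(config, inputs))

  assoc <- stage("ingest", read_association_table(config$network_db))
  dsim <- stage("ingest", read_disease_similarity(config$dsim))

  exsim <- NULL
  if (!is.null(config$expr) && length(config$expr)) {
    raw <- stage("expression-similarity",
                 lapply(config$expr, function(p) {
                   expression_similarity(read_expression_matrix(p))
                 }))
    exsim <- stage("expression-similarity", combine_expression_similarity(
      raw[[1L]], if (length(raw) >= 2L) raw[[2L]] else NULL,
      tau = config$tau, both_sources_only = config$both_sources_only
    ))
  }
  fnsim <- stage("functional-similarity",
                 functional_similarity(score_matrix(assoc, dsim)))
  net <- stage("network", build_network(fnsim, exsim, assoc))
  stage("network", write_network(net, file.path(config$out_dir, "network.tsv")))

  out <- list(network = net)
  if (!is.null(config$target)) {
    pr <- stage("rank", personal_rank(
      net, config$target, d = config$d, tol = config$tol,
      max_iter = config$max_iter, weighted = !config$unweighted_walk
    ))
    write_with_header(
      pr$candidates,
      file.path(config$out_dir,
                sprintf("ranking_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_", config$target))),
      hdr
    )
    out$ranking <- pr
  }
  if (!is.null(config$reference_db)) {
    ref <- stage("validate", read_association_table(config$reference_db))
    v <- stage("validate", run_validation(
      assoc, ref, dsim, exsim = exsim, tau = config$tau, d = config$d,
      tol = config$tol, max_iter = config$max_iter,
      weighted = !config$unweighted_walk
    ))
    write_with_header(v$results, file.path(config$out_dir, "validation.tsv"), hdr)
    out$validation <- v
  }
  invisible(out)
}
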