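# Reading and harmonising association tables, expression matrices, disease
# similarity matrices and synonym/ontology inputs.
#
# File dialect (all readers/writers here): UTF-8, tab-separated, lines
# starting with "#" are comments. Expression and similarity matrices require
# a header row; association tables take an explicit `header` flag.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], line_no = which(keep))
}

#' Coerce a synonym mapping to a named lookup vector
#'
#' A synonym map sends an alias to its canonical identifier. It may be given
#' as a named character vector (`names` = aliases) or a data frame with
#' `alias` and `canonical` columns. Canonical identifiers always map to
#' themselves, so resolving an already-canonical ID is a no-op.
#'
#' @param map A named character vector, a data frame with `alias` and
#'   `canonical` columns, or `NULL` (empty map).
#' @return A named character vector; names are aliases.
#' @export
as_synonym_map <- function(map) {
  if (is.null(map)) {
    return(setNames(character(), character()))
  }
  if (is.data.frame(map)) {
    if (!all(c("alias", "canonical") %in% names(map))) {
      abort("A synonym map data frame needs `alias` and `canonical` columns.")
    }
    map <- setNames(as.character(map$canonical), as.character(map$alias))
  }
  if (!is.character(map) || is.null(names(map))) {
    abort("A synonym map must be a named character vector or an alias/canonical data frame.")
  }
  dup <- names(map)[duplicated(names(map))]
  conflicting <- unique(dup[vapply(
    dup, function(a) length(unique(map[names(map) == a])) > 1L, logical(1)
  )])
  if (length(conflicting)) {
    abort(sprintf(
      "Conflicting synonym mappings for: %s.",
      paste(conflicting, collapse = ", ")
    ))
  }
  map <- map[!duplicated(names(map))]
  # canonical IDs map to themselves
  canon <- setdiff(unique(unname(map)), names(map))
  c(map, setNames(canon, canon))
}

resolve_alias <- function(aliases, map) {
  if (length(map) == 0L) {
    return(aliases) # empty map: inputs are taken as canonical
  }
  unname(map[aliases]) # NA where unmappable
}

#' Read a circRNA-disease association table
#'
#' Reads a tab-separated table of (circRNA alias, disease alias) pairs,
#' resolves both columns through synonym maps, collapses duplicates, and
#' collects unmappable rows in a rejects report rather than dropping them
#' silently.
#'
#' @param path Path to a TSV file with at least two columns: circRNA alias,
#'   disease alias, and optionally a third source column.
#' @param circ_map,disease_map Synonym maps (see [as_synonym_map()]); `NULL`
#'   or empty maps accept identifiers as already canonical.
#' @param label Source label recorded in the `source` column; defaults to the
#'   file name.
#' @param header Logical; does the file carry a header row? Default `FALSE`.
#' @return A tibble with columns `circrna`, `disease`, `source`, one row per
#'   unique pair, with attributes `label` and `rejects` (a tibble of
#'   unmappable/malformed rows; see [assoc_rejects()]).
#' @seealso [write_association_table()], [intersect_databases()]
#' @export
read_association_table <- function(path, circ_map = NULL, disease_map = NULL,
                                   label = NULL, header = FALSE) {
  label <- label %||% basename(path)
  circ_map <- as_synonym_map(circ_map)
  disease_map <- as_synonym_map(disease_map)

  tl <- read_tsv_lines(path)
  lines <- tl$lines
  line_no <- tl$line_no
  if (header && length(lines)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 2L)) {
    bad <- line_no[which(nfld < 2L)[1L]]
    abort(sprintf("Malformed row at line %d of '%s': expected >= 2 tab-separated columns.", bad, path))
  }

  circ_raw <- vapply(fields, `[[`, character(1), 1L)
  dis_raw <- vapply(fields, `[[`, character(1), 2L)
  src <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else label, character(1))

  circ <- resolve_alias(circ_raw, circ_map)
  dis <- resolve_alias(dis_raw, disease_map)
  reason <- dplyr::case_when(
    is.na(circ) & is.na(dis) ~ "unmapped circRNA and disease",
    is.na(circ) ~ "unmapped circRNA",
    is.na(dis) ~ "unmapped disease",
    .default = NA_character_
  )
  ok <- is.na(reason)

  rejects <- tibble::tibble(
    line = line_no[!ok], circrna = circ_raw[!ok],
    disease = dis_raw[!ok], reason = reason[!ok]
  )
  pairs <- tibble::tibble(circrna = circ[ok], disease = dis[ok], source = src[ok])
  n_accepted <- nrow(pairs)
  pairs <- dplyr::distinct(pairs, .data$circrna, .data$disease, .keep_all = TRUE)

  attr(pairs, "label") <- label
  attr(pairs, "rejects") <- rejects
  attr(pairs, "n_input_rows") <- length(lines)
  attr(pairs, "n_accepted_rows") <- n_accepted
  pairs
}

#' Rejects report of an association table
#'
#' @param assoc An association tibble from [read_association_table()].
#' @return A tibble with columns `line`, `circrna`, `disease`, `reason`.
#' @export
assoc_rejects <- function(assoc) {
  attr(assoc, "rejects", exact = TRUE) %||%
    tibble::tibble(line = integer(), circrna = character(),
                   disease = character(), reason = character())
}

#' Write an association table as TSV
#'
#' @param assoc A data frame with `circrna` and `disease` (and optionally
#'   `source`) columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assoc, path) {
  assoc <- as_assoc(assoc)
  cols <- intersect(c("circrna", "disease", "source"), names(assoc))
  utils::write.table(assoc[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a circRNA expression matrix
#'
#' Expects a TSV with a header row of condition (cell type/tissue) names and
#' a first column of circRNA identifiers. Empty or `NA` cells are recorded as
#' missing.
#'
#' @param path Path to the TSV file.
#' @param source Label for the expression source (e.g. `"circbase"`).
#' @return A numeric matrix (rows = circRNAs, columns = conditions) with a
#'   `source` attribute; missing cells are `NA`.
#' @export
read_expression_matrix <- function(path, source = basename(path)) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 2L) {
    abort(sprintf("Expression matrix '%s' needs a header row and at least one data row.", path))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  conditions <- header[-1L]
  if (length(fields[[2L]]) == length(header) + 1L) {
    # header written without a corner cell above the ID column
    conditions <- header
  }
  if (anyDuplicated(conditions)) {
    abort(sprintf("Duplicate condition names in '%s'.", path))
  }
  body <- fields[-1L]
  rows_no <- tl$line_no[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate circRNA row identifiers in '%s': %s.",
      path, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(conditions),
                dimnames = list(ids, conditions))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    if (length(cells) != length(conditions)) {
      abort(sprintf("Line %d of '%s': expected %d value cells, found %d.",
                    rows_no[i], path, length(conditions), length(cells)))
    }
    missing <- cells %in% c("", "NA", "na", "NaN")
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !missing)
    if (length(bad)) {
      abort(sprintf("Non-numeric cell at line %d, column '%s' of '%s': '%s'.",
                    rows_no[i], conditions[bad[1L]], path, cells[bad[1L]]))
    }
    vals[missing] <- NA_real_
    mat[i, ] <- vals
  }
  attr(mat, "source") <- source
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with circRNA rownames and condition colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(circrna = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a disease-disease similarity matrix
#'
#' Reads a square TSV matrix (header row and first column are disease IDs)
#' and validates that it is symmetric with a unit diagonal and entries in
#' \[0, 1\]. The matrix is consumed as an external input, e.g. the output of
#' an ontology-based disease similarity method.
#'
#' @param path Path to the TSV file.
#' @return A validated numeric similarity matrix.
#' @export
read_disease_similarity <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    if (!setequal(rownames(m), colnames(m))) {
      abort(sprintf("Row and column disease IDs disagree in '%s'.", path))
    }
    m <- m[, rownames(m), drop = FALSE]
  }
  check_disease_similarity(m)
}

#' Write a disease similarity matrix as TSV
#'
#' @param dsim Symmetric numeric matrix with disease IDs as dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_disease_similarity <- function(dsim, path) {
  df <- data.frame(disease = rownames(dsim), dsim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a disease ontology as terms with synonyms
#'
#' Accepts either an OBO file (`[Term]` stanzas with `id:`, `name:` and
#' `synonym:` lines; obsolete terms skipped) or a flat three-column TSV
#' (`ontology_id`, `name`, pipe-separated synonyms). The format is detected
#' from the file content.
#'
#' @param path Path to the ontology file.
#' @return A tibble with columns `ontology_id`, `name` and a `synonyms`
#'   list-column of character vectors.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(startsWith(trimws(lines), "[Term]"))) {
    return(parse_obo_terms(lines))
  }
  keep <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(keep, "\t", fixed = TRUE)
  tibble::tibble(
    ontology_id = vapply(fields, `[[`, character(1), 1L),
    name = vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", character(1)),
    synonyms = lapply(fields, function(f) {
      if (length(f) >= 3L && nzchar(f[[3L]])) {
        strsplit(f[[3L]], "|", fixed = TRUE)[[1L]]
      } else {
        character()
      }
    })
  )
}

# Minimal OBO [Term] stanza reader: id, name, synonym, is_obsolete.
parse_obo_terms <- function(lines) {
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  ends <- c(which(startsWith(lines, "[")), length(lines) + 1L)
  terms <- lapply(starts, function(s) {
    e <- min(ends[ends > s]) - 1L
    block <- lines[seq(s + 1L, max(s + 1L, e))]
    if (any(block == "is_obsolete: true")) return(NULL)
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1L])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1L])
    syn_lines <- grep("^synonym:", block, value = TRUE)
    syns <- sub('^synonym: *"([^"]*)".*$', "\\1", syn_lines)
    if (is.na(id)) return(NULL)
    tibble::tibble(ontology_id = id, name = nm %||% "", synonyms = list(syns))
  })
  dplyr::bind_rows(terms)
}

#' Merge extra synonym lists into an ontology by a shared reference key
#'
#' Terms are matched to extra vocabulary entries through an external
#' cross-reference key (e.g. a shared OMIM or MeSH accession); the extra
#' entries' synonyms are unioned into the matching terms' synonym lists.
#'
#' @param ontology A term tibble from [read_ontology()] with an added `xref`
#'   character column (the external-reference key per term).
#' @param extra A data frame with columns `xref` and `synonym`.
#' @return The ontology tibble with enlarged `synonyms` lists.
#' @export
merge_ontology_synonyms <- function(ontology, extra) {
  if (!"xref" %in% names(ontology)) {
    abort("`ontology` needs an `xref` column to merge against.")
  }
  if (!all(c("xref", "synonym") %in% names(extra))) {
    abort("`extra` needs `xref` and `synonym` columns.")
  }
  by_key <- split(as.character(extra$synonym), as.character(extra$xref))
  ontology$synonyms <- purrr::map2(
    ontology$synonyms, ontology$xref,
    function(syns, key) {
      if (!is.na(key) && key %in% names(by_key)) {
        union(syns, by_key[[key]])
      } else {
        syns
      }
    }
  )
  ontology
}

#' Match free-text disease names against an ontology
#'
#' Case-insensitive exact matching of each name against every term's primary
#' name and synonyms. No fuzzy matching is attempted. Names matching nothing
#' are omitted from the map and listed in the `unmatched` attribute.
#'
#' @param names Character vector of disease names to resolve.
#' @param ontology A term tibble from [read_ontology()].
#' @return A synonym-map tibble with columns `alias` (the input name) and
#'   `canonical` (the matched ontology ID), with attribute `unmatched`
#'   listing names that matched no term. Usable directly as the
#'   `disease_map` of [read_association_table()].
#' @export
match_disease_names <- function(names, ontology) {
  keys <- purrr::map2(
    ontology$synonyms, ontology$name,
    function(syns, nm) unique(tolower(c(nm, syns)))
  )
  lookup <- tibble::tibble(
    key = unlist(keys),
    ontology_id = rep(ontology$ontology_id, lengths(keys))
  )
  lookup <- dplyr::distinct(lookup)
  amb <- lookup$key[duplicated(lookup$key)]
  if (length(amb)) {
    claimants <- lookup$ontology_id[lookup$key == amb[[1L]]]
    abort(sprintf(
      "Ambiguous disease synonym '%s' claimed by terms %s.",
      amb[[1L]], paste(claimants, collapse = " and ")
    ))
  }
  idx <- match(tolower(names), lookup$key)
  out <- tibble::tibble(alias = names[!is.na(idx)],
                        canonical = lookup$ontology_id[idx[!is.na(idx)]])
  attr(out, "unmatched") <- names[is.na(idx)]
  out
}

#' Cross-tabulate shared content of association databases
#'
#' @param dbs A named list of two or more association tables (canonical IDs).
#' @return A tibble with one row per unordered pair of databases and columns
#'   `db_a`, `db_b`, `shared_circrnas`, `shared_diseases`, `shared_pairs`.
#' @export
intersect_databases <- function(dbs) {
  if (length(dbs) < 2L) abort("Need at least two databases to intersect.")
  if (is.null(names(dbs)) || any(!nzchar(names(dbs)))) {
    names(dbs) <- paste0("db", seq_along(dbs))
  }
  dbs <- lapply(dbs, as_assoc)
  combos <- utils::combn(names(dbs), 2L, simplify = FALSE)
  purrr::map_dfr(combos, function(pr) {
    a <- dbs[[pr[1L]]]
    b <- dbs[[pr[2L]]]
    tibble::tibble(
      db_a = pr[1L], db_b = pr[2L],
      shared_circrnas = length(intersect(unique(a$circrna), unique(b$circrna))),
      shared_diseases = length(intersect(unique(a$disease), unique(b$disease))),
      shared_pairs = nrow(dplyr::inner_join(
        a[c("circrna", "disease")], b[c("circrna", "disease")],
        by = c("circrna", "disease")
      ))
    )
  })
}
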