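write_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("association tables collapse duplicates and resolve synonyms", {
  path <- write_lines(c(
    "ciRS-7\tliver cancer",
    "hsa_circ_0001946\tliver cancer",
    "hsa_circ_0000284\tDOID:3571"
  ))
  circ_map <- c("ciRS-7" = "hsa_circ_0001946",
                "hsa_circ_0000284" = "hsa_circ_0000284")
  dis_map <- c("liver cancer" = "DOID:3571")

  db <- read_association_table(path, circ_map, dis_map, label = "toy")
  # ciRS-7 resolves to its circBase accession, collapsing with row 2
  expect_equal(nrow(db), 2L)
  expect_setequal(db$circrna, c("hsa_circ_0001946", "hsa_circ_0000284"))
  expect_true(all(db$disease == "DOID:3571"))
  expect_equal(nrow(assoc_rejects(db)), 0L)
})

test_that("unmappable rows land in the rejects report, never in the pairs", {
  path <- write_lines(c(
    "# comment line",
    "circX\tDOID:1",
    "circY\tmystery disease",
    "circX\tDOID:1"
  ))
  db <- read_association_table(
    path,
    circ_map = c(circX = "circX", circY = "circY"),
    disease_map = c("DOID:1" = "DOID:1")
  )
  expect_equal(db$circrna, "circX")
  rej <- assoc_rejects(db)
  expect_equal(rej$disease, "mystery disease")
  expect_equal(rej$reason, "unmapped disease")
  expect_equal(rej$line, 3L) # line number in the file, comments included
  # accounting: accepted rows + rejected rows = input rows
  expect_equal(attr(db, "n_accepted_rows") + nrow(rej), 3L)
})

test_that("malformed association rows raise an error naming the line", {
  path <- write_lines(c("circA\tDOID:1", "lonely-field"))
  expect_error(read_association_table(path), "line 2")
  expect_error(read_association_table(tempfile()), "not found")
})

test_that("association tables round-trip through disk", {
  db <- toy_assoc()
  path <- tempfile(fileext = ".tsv")
  write_association_table(db, path)
  back <- read_association_table(path)
  expect_setequal(paste(back$circrna, back$disease),
                  paste(db$circrna, db$disease))
})

test_that("synonym resolution is idempotent on canonical IDs", {
  map <- as_synonym_map(c("ciRS-7" = "hsa_circ_0001946"))
  expect_equal(unname(map["hsa_circ_0001946"]), "hsa_circ_0001946")
  expect_error(
    as_synonym_map(c(a = "x", a = "y")),
    "Conflicting"
  )
})

test_that("expression matrices parse shapes, missing cells and bad input", {
  path <- write_lines(c(
    "circrna\tcond1\tcond2\tcond3",
    "circA\t1.5\t2\t3",
    "circB\t0.1\tNA\t0.3"
  ))
  m <- read_expression_matrix(path, source = "cb")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("circA", "circB"))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["circB", "cond2"]))
  expect_equal(attr(m, "source"), "cb")

  bad <- write_lines(c("circrna\tc1\tc2", "circA\t1\toops"))
  expect_error(read_expression_matrix(bad), "Non-numeric cell")
  dup <- write_lines(c("circrna\tc1", "circA\t1", "circA\t2"))
  expect_error(read_expression_matrix(dup), "Duplicate circRNA")
})

test_that("expression matrices round-trip through disk", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("ca", "cb"), c("t1", "t2", "t3")))
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  expect_equal(unclass(read_expression_matrix(path)), m,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("disease similarity matrices are validated on read", {
  path <- tempfile(fileext = ".tsv")
  write_disease_similarity(toy_dsim(), path)
  expect_equal(read_disease_similarity(path), toy_dsim())

  bad <- toy_dsim()
  bad[1, 2] <- 0.5 # breaks symmetry
  write_disease_similarity(bad, path)
  expect_error(read_disease_similarity(path), "symmetric")
})

test_that("disease names match terms case-insensitively, synonyms included", {
  ontology <- tibble::tibble(
    ontology_id = c("DOID:3571", "DOID:1612"),
    name = c("liver cancer", "breast cancer"),
    synonyms = list(c("hepatic cancer"), c("breast carcinoma"))
  )
  map <- match_disease_names(
    c("Liver Cancer", "BREAST CARCINOMA", "gill rot"), ontology
  )
  expect_equal(map$canonical[map$alias == "Liver Cancer"], "DOID:3571")
  expect_equal(map$canonical[map$alias == "BREAST CARCINOMA"], "DOID:1612")
  expect_equal(attr(map, "unmatched"), "gill rot")

  clash <- ontology
  clash$synonyms[[2]] <- "liver cancer"
  expect_error(match_disease_names("x", clash), "DOID:3571 and DOID:1612")
})

test_that("flat-TSV and OBO ontology files parse to the same terms", {
  tsv <- write_lines(c(
    "DOID:3571\tliver cancer\thepatic cancer|hepatic neoplasm",
    "DOID:1612\tbreast cancer\t"
  ))
  obo <- write_lines(c(
    "format-version: 1.2", "",
    "[Term]",
    "id: DOID:3571",
    "name: liver cancer",
    'synonym: "hepatic cancer" EXACT []',
    'synonym: "hepatic neoplasm" RELATED []', "",
    "[Term]",
    "id: DOID:1612",
    "name: breast cancer", "",
    "[Term]",
    "id: DOID:9999",
    "name: gone",
    "is_obsolete: true"
  ), tempfile(fileext = ".obo"))
  t1 <- read_ontology(tsv)
  t2 <- read_ontology(obo)
  expect_equal(t1$ontology_id, t2$ontology_id)
  expect_equal(t1$name, t2$name)
  expect_equal(t1$synonyms, t2$synonyms)
})

test_that("synonym lists merge through a shared external-reference key", {
  ontology <- tibble::tibble(
    ontology_id = "DOID:3571", name = "liver cancer",
    synonyms = list("hepatic cancer"), xref = "OMIM:114550"
  )
  extra <- tibble::tibble(
    xref = c("OMIM:114550", "OMIM:999999"),
    synonym = c("hepatocellular cancer", "unrelated")
  )
  merged <- merge_ontology_synonyms(ontology, extra)
  expect_setequal(merged$synonyms[[1]],
                  c("hepatic cancer", "hepatocellular cancer"))
})

test_that("database intersection counts shared circRNAs, diseases and pairs", {
  a <- tibble::tibble(circrna = c("c1", "c2"), disease = c("d1", "d1"))
  b <- tibble::tibble(circrna = c("c1", "c1"), disease = c("d1", "d2"))
  out <- intersect_databases(list(A = a, B = b))
  expect_equal(out$shared_circrnas, 1L)
  expect_equal(out$shared_diseases, 1L)
  expect_equal(out$shared_pairs, 1L)

  same <- intersect_databases(list(A = a, B = a))
  expect_equal(same$shared_pairs, nrow(a))
  dis <- intersect_databases(list(
    A = a, B = tibble::tibble(circrna = "cx", disease = "dx")
  ))
  expect_equal(unlist(dis[, 3:5]), c(0L, 0L, 0L), ignore_attr = TRUE)
})
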