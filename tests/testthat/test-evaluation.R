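test_that("test-case extraction matches a hand-worked fixture", {
  network_db <- tibble::tibble(
    circrna = c("c1", "c2", "c3", "c4", "c5"),
    disease = c("d1", "d1", "d2", "d2", "d3")
  )
  reference_db <- tibble::tibble(
    circrna = c("c1", "c3", "c5", "c6", "c2"),
    disease = c("d1", "d1", "d2", "d2", "d9")
  )
  cases <- extract_test_cases(network_db, reference_db)
  # d1: c1 already in network DB; c3 is a network node without the pair -> positive
  # d2: c5 qualifies; c6 is not a network node -> excluded
  # d3: not in the reference DB; d9: not in the network DB
  expect_equal(cases$disease, c("d1", "d2"))
  expect_equal(cases$positives, list("c3", "c5"))
  expect_equal(cases$n_positives, c(1L, 1L))
})

test_that("nothing is extracted when the reference adds no new pairs", {
  db <- toy_assoc()
  expect_equal(nrow(extract_test_cases(db, db)), 0L)
  sub <- db[1:2, ]
  expect_equal(nrow(extract_test_cases(db, sub)), 0L)
})

test_that("single-positive AUC endpoints behave as expected", {
  ranking <- tibble::tibble(circrna = paste0("c", 1:5), score = c(5, 4, 3, 2, 1))
  expect_equal(auc_from_ranking(ranking, "c1"), 1) # ranked first
  expect_equal(auc_from_ranking(ranking, "c5"), 0) # ranked last
  expect_equal(auc_from_ranking(ranking, "c3"), 0.5) # 2 below, 2 above
  expect_true(is.na(auc_from_ranking(ranking, character()))) # no positives
  expect_true(is.na(auc_from_ranking(ranking, ranking$circrna))) # no negatives
  expect_error(auc_from_ranking(ranking, "ghost"), "ghost")
})

test_that("the rank-sum AUC equals brute-force pair enumeration", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    scores <- sample(round(runif(n), 2)) # rounding forces score ties
    is_pos <- runif(n) < 0.3
    if (!any(is_pos) || all(is_pos)) next
    ranking <- tibble::tibble(circrna = sprintf("c%03d", seq_len(n)),
                              score = scores)
    expect_equal(
      auc_from_ranking(ranking, ranking$circrna[is_pos]),
      auc_brute_force(scores, is_pos),
      tolerance = 1e-12
    )
  }
})

test_that("random rankings average AUC one half", {
  set.seed(52)
  aucs <- replicate(1000, {
    n <- 40
    ranking <- tibble::tibble(circrna = sprintf("c%02d", 1:n), score = rnorm(n))
    auc_from_ranking(ranking, sample(ranking$circrna, 5))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("validation on a planted-module bundle recovers held-out pairs", {
  b <- simulate_bundle(sim_config(seed = 60))
  v <- run_validation(b$network_db, b$reference_db, b$dsim, expr = b$expr)
  expect_gt(v$macro_auc, 0.75)
  expect_equal(v$n_test_cases, nrow(v$results))
  expect_true(all(v$results$auc >= 0 & v$results$auc <= 1, na.rm = TRUE))
  # determinism of the whole scheme
  v2 <- run_validation(b$network_db, b$reference_db, b$dsim, expr = b$expr)
  expect_identical(v$results, v2$results)
  # tidy/glance/autoplot surfaces
  expect_identical(tidy(v), v$results)
  expect_equal(glance(v)$macro_auc, v$macro_auc)
  expect_s3_class(autoplot(v), "ggplot")
})

test_that("an identical reference database yields an empty report", {
  b <- simulate_bundle(sim_config(seed = 61, holdout_fraction = 0.1))
  v <- run_validation(b$network_db, b$network_db, b$dsim)
  expect_equal(v$n_test_cases, 0L)
  expect_true(is.na(v$macro_auc))
})

test_that("a single test case makes the macro average equal its AUC", {
  network_db <- tibble::tibble(
    circrna = c("c1", "c2", "c3"),
    disease = c("d1", "d1", "d2")
  )
  reference_db <- dplyr::bind_rows(
    network_db, tibble::tibble(circrna = "c3", disease = "d1")
  )
  ids <- c("d1", "d2")
  dsim <- sym_matrix(ids, list(list("d1", "d2", 0.4)))
  v <- run_validation(network_db, reference_db, dsim)
  expect_equal(v$n_test_cases, 1L)
  expect_equal(v$macro_auc, v$results$auc[[1]])
  expect_equal(v$macro_auc, v$pooled_auc)
})

test_that("the threshold sweep is monotone in retained pairs", {
  b <- simulate_bundle(sim_config(seed = 62, n_modules = 3))
  sweep <- threshold_sweep(c(0.5, 0.7, 0.9), b$network_db, b$reference_db,
                           b$dsim, b$expr)
  expect_equal(nrow(sweep), 3L)
  expect_true(all(diff(sweep$n_pairs) <= 0))
  # singleton sweep equals a direct validation run at that tau
  single <- threshold_sweep(0.7, b$network_db, b$reference_db, b$dsim, b$expr)
  direct <- run_validation(b$network_db, b$reference_db, b$dsim,
                           expr = b$expr, tau = 0.7)
  expect_equal(single$macro_auc, direct$macro_auc)
})

test_that("tau above every similarity reduces to the cosine-only ablation", {
  b <- simulate_bundle(sim_config(seed = 63, n_modules = 3))
  high <- run_validation(b$network_db, b$reference_db, b$dsim,
                         expr = b$expr, tau = 1)
  ablation <- ablation_cosine_only(b$network_db, b$reference_db, b$dsim)
  # tau = 1 keeps only perfect correlations; with none the networks coincide
  if (n_similar_pairs(combine_expression_similarity(
    expression_similarity(b$expr[[1]]), expression_similarity(b$expr[[2]]),
    tau = 1
  )) == 0) {
    expect_equal(high$results, ablation$results)
  }
  expect_false(ablation$used_expression)
})

test_that("the ablation equals validation with an empty expression input", {
  b <- simulate_bundle(sim_config(seed = 64, n_modules = 3))
  a1 <- ablation_cosine_only(b$network_db, b$reference_db, b$dsim)
  a2 <- run_validation(b$network_db, b$reference_db, b$dsim, expr = NULL)
  expect_equal(a1$results, a2$results)
})
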