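test_that("world configuration validates its parameter space", {
  expect_s3_class(planted_world_config(), "planted_world_config")
  # the null world (equal probabilities) is legal by design
  expect_no_error(planted_world_config(p_planted = 0.05, p_background = 0.05))
  expect_error(planted_world_config(p_planted = 0.01, p_background = 0.3),
               class = "comention_usage_error")
  expect_error(planted_world_config(drugs_per_term = 500),
               class = "comention_usage_error")
  expect_error(planted_world_config(n_drugs = 1),
               class = "comention_usage_error")
})

test_that("generate_world is deterministic and internally consistent", {
  cfg <- planted_world_config(n_drugs = 40, n_terms = 4, n_pmids = 600,
                              n_genes = 30, rng_seed = 9)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$rif, w2$rif)
  expect_identical(w1$signatures, w2$signatures)
  expect_identical(w1$truth, w2$truth)

  # planted sets have exactly drugs_per_term members; library mirrors truth
  expect_true(all(lengths(w1$truth$planted) == cfg$drugs_per_term))
  expect_identical(w1$library, w1$truth$planted)
  # every corpus pmid carries exactly one term
  expect_equal(anyDuplicated(w1$corpus$pmid), 0)
  # rif respects the >= 2 PMID filter
  expect_true(all(rif_totals(w1$rif)$total >= 2))
  # planted co-term drugs share a signature cluster
  cl <- w1$truth$clusters
  for (tm in names(w1$truth$planted)) {
    ids <- unique(cl[w1$truth$planted[[tm]]])
    expect_length(ids[ids > 0], 1)
  }
})

test_that("planted drugs dominate their term's association ranking", {
  w <- generate_world(planted_world_config(
    n_drugs = 100, n_terms = 10, n_pmids = 2500, rng_seed = 0
  ))
  rates <- vapply(names(w$library), function(tm) {
    a <- associate(w$rif, query_pmids(w$corpus, tm))
    recovery_rate(a, w$truth, tm, k = 10)
  }, numeric(1))
  expect_gt(mean(rates), 0.8)
})

test_that("recovery_rate counts planted drugs in the top-k", {
  truth <- list(planted = list(t1 = c("a", "b", "c", "d", "e")))
  tab <- tibble::tibble(drug = c("a", "x", "b", "y", "c", "d", "e"))
  expect_equal(recovery_rate(tab, truth, "t1", k = 5), 3 / 5)
  expect_equal(recovery_rate(tab[tab$drug %in% c("a", "b", "c", "d", "e"), ],
                             truth, "t1", k = 5), 1)
  expect_equal(recovery_rate(tibble::tibble(drug = c("x", "y")), truth, "t1", 5), 0)
  expect_error(recovery_rate(tab, truth, "nope", 5),
               class = "comention_domain_error")
})

test_that("mean recovery is monotone in the planted co-mention probability", {
  rates <- vapply(c(0.05, 0.15, 0.3), function(p) {
    w <- generate_world(planted_world_config(
      n_drugs = 80, n_terms = 8, n_pmids = 1500, p_planted = p,
      n_genes = 20, rng_seed = 123
    ))
    mean(vapply(names(w$library), function(tm) {
      a <- suppressWarnings(associate(w$rif, query_pmids(w$corpus, tm)))
      recovery_rate(a, w$truth, tm, k = 10)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("signature clusters make planted sets separable under cosine", {
  w <- small_world()
  m <- cosine_matrix(w$signatures)
  res <- evaluate_term(w$truth$planted[[1]], m)
  expect_gt(res$auroc, 0.9)
})

test_that("write_world emits the five artifacts and they read back", {
  w <- generate_world(planted_world_config(
    n_drugs = 30, n_terms = 3, n_pmids = 400, n_genes = 10, rng_seed = 5
  ))
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_rif(paths[["rif"]]), w$rif)
  expect_identical(read_corpus(paths[["corpus"]]), w$corpus)
  expect_identical(read_gmt(paths[["library"]]), w$library)
  sig <- read_signature_matrix(paths[["signatures"]])
  expect_equal(sig, w$signatures, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_setequal(names(truth$planted), names(w$truth$planted))
})
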