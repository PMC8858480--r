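test_that("auroc matches hand-counted concordant pairs and handles edges", {
  expect_equal(auroc(c(a = .9, b = .4, c = .6, d = .1), c("a", "b")), 0.75)
  # perfect and inverted separation
  expect_equal(auroc(c(a = 3, b = 2, c = 1), c("a", "b")), 1)
  expect_equal(auroc(c(a = 1, b = 2, c = 3), "a"), 0)
  # all-tied scores force 1/2
  expect_equal(auroc(c(a = 1, b = 1, c = 1, d = 1), c("a", "c")), 0.5)
  expect_error(auroc(c(a = 1, b = 2), c("a", "b")),
               class = "comention_domain_error")
  expect_error(auroc(c(a = 1, b = 2), character()),
               class = "comention_domain_error")
})

test_that("average_precision matches the definition on hand cases", {
  expect_equal(average_precision(c(a = 3, b = 2, c = 1), c("a", "b")), 1)
  expect_equal(average_precision(c(a = 3, b = 2, c = 1), c("a", "c")),
               (1 + 2 / 3) / 2)
  # single positive ranked last of n -> 1/n
  expect_equal(average_precision(c(a = 4, b = 3, c = 2, d = 1), "d"), 1 / 4)
})

test_that("ranking metrics agree with brute-force oracles on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    r <- random_ranking(n, sample(seq_len(n - 1), 1),
                        tie_levels = if (i %% 2) sample(2:8, 1) else NULL)
    expect_equal(auroc(r$scores, r$positives),
                 oracle_auroc(r$scores, r$positives), tolerance = 1e-9)
    expect_equal(average_precision(r$scores, r$positives),
                 oracle_average_precision(r$scores, r$positives),
                 tolerance = 1e-9)
  }
})

test_that("auroc of negated tie-free scores is the complement", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    r <- random_ranking(n, sample(seq_len(n - 1), 1))
    expect_equal(auroc(r$scores, r$positives) +
                   auroc(-r$scores, r$positives), 1, tolerance = 1e-12)
  }
})

test_that("mann_whitney_u exact path agrees with the exact reference distribution", {
  res <- mann_whitney_u(c(3, 4), c(1, 2))
  expect_equal(res$u, 4)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact enumeration")

  # identical samples -> U = n1*n2/2 under midranks
  same <- suppressWarnings(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$u, 4.5)

  # all tie-free configurations up to n1+n2 = 8: compare with wilcox.test's
  # exact distribution (independent implementation)
  for (n1 in 1:4) {
    for (n2 in n1:(8 - n1)) {
      combos <- utils::combn(n1 + n2, n1)
      for (j in seq_len(ncol(combos))) {
        x <- combos[, j]
        y <- setdiff(seq_len(n1 + n2), x)
        ours <- mann_whitney_u(x, y)
        ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
        expect_equal(ours$u, unname(ref$statistic))
        expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  }
})

test_that("mann_whitney_u large-sample path tracks the reference implementation", {
  set.seed(77)
  for (i in 1:60) {
    x <- round(rnorm(30), if (i %% 2) 1 else 3) # half the cases have ties
    y <- round(rnorm(25, mean = (i %% 3) * 0.3), if (i %% 2) 1 else 3)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
  expect_error(mann_whitney_u(numeric(), 1), class = "comention_domain_error")
})

test_that("evaluate_term separates block-structured seeds perfectly and ties give 1/2", {
  labs <- sprintf("d%d", 1:6)
  block <- matrix(0.1, 6, 6, dimnames = list(labs, labs))
  block[1:3, 1:3] <- 0.9
  diag(block) <- 1
  m <- similarity_matrix(block, "cosine")
  res <- evaluate_term(labs[1:3], m)
  expect_equal(res$auroc, 1)
  expect_equal(res$avg_precision, 1)
  expect_equal(res$n_positives, 3)

  flat <- similarity_matrix(matrix(0.4, 6, 6, dimnames = list(labs, labs)), "cosine")
  expect_equal(evaluate_term(labs[1:3], flat)$auroc, 0.5)
})

test_that("evaluate_term equals brute-force pair counting on small fixtures", {
  set.seed(21)
  labs <- sprintf("d%d", 1:8)
  v <- matrix(rnorm(64), 8, dimnames = list(labs, labs))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  m <- similarity_matrix(v, "cosine")
  seed <- labs[c(2, 5, 7)]
  res <- evaluate_term(seed, m)
  # oracle: recompute loo means by hand, then count pairs
  scores <- vapply(labs, function(d) {
    others <- setdiff(seed, d)
    if (d %in% seed) mean(v[d, others]) else mean(v[d, seed])
  }, numeric(1))
  expect_equal(res$auroc, oracle_auroc(scores, seed), tolerance = 1e-12)
  expect_equal(res$avg_precision, oracle_average_precision(scores, seed),
               tolerance = 1e-12)
})

test_that("shuffled_matrix is a seeded joint label permutation preserving values", {
  w <- small_world()
  m <- comention_matrix(w$rif)
  s1 <- shuffled_matrix(m, 1)
  s1b <- shuffled_matrix(m, 1)
  expect_identical(unclass(s1), unclass(s1b)) # deterministic per seed
  expect_identical(sort(as.vector(unclass(s1))), sort(as.vector(unclass(m))))
  expect_identical(rownames(s1), colnames(s1))
  expect_setequal(rownames(s1), rownames(m))
  expect_true(all(unclass(s1) == t(unclass(s1))))

  # different seeds give different assignments essentially always
  assignments <- vapply(1:100, function(s) {
    paste(rownames(shuffled_matrix(m, s))[1:5], collapse = ",")
  }, character(1))
  expect_gt(length(unique(assignments)), 90)
})

test_that("run_benchmark detects planted structure and reports skipped terms", {
  w <- small_world()
  m <- comention_matrix(w$rif)
  res <- run_benchmark(w$library, w$rif, w$corpus, m,
                       k = 10, n_shuffles = 3, seed = 11)
  expect_s3_class(res, "drug_benchmark")
  expect_equal(nrow(res$per_term), length(w$library))
  expect_gt(mean(res$per_term$auroc), mean(res$null_per_term$auroc))
  expect_lt(res$tests$p_value[res$tests$metric == "auroc"], 0.05)

  # identical seed -> bit-identical result
  res2 <- run_benchmark(w$library, w$rif, w$corpus, m,
                        k = 10, n_shuffles = 3, seed = 11)
  expect_identical(res, res2)

  # an orphan term (absent from the corpus) is skipped and named
  lib2 <- c(w$library, list(orphanterm = c("drug0001", "drug0002")))
  res3 <- run_benchmark(lib2, w$rif, w$corpus, m,
                        k = 10, n_shuffles = 2, seed = 11)
  expect_equal(res3$skipped$term, "orphanterm")
  expect_match(res3$skipped$reason, "no publications")

  expect_error(run_benchmark(list(), w$rif, w$corpus, m),
               class = "comention_usage_error")
})

test_that("same-corpus circularity inflates the co-mention benchmark in a null world", {
  # Even with no planted signal, drugs selected into a term's seed set by
  # chance co-occurrence share more PMIDs with each other than random
  # pairs do, so the co-mention benchmark sits above its shuffle null.
  # This documents why calibration claims require the similarity matrix
  # to be independent of the corpus that selected the seeds.
  gaps <- vapply(1:5, function(s) {
    w <- generate_world(planted_world_config(
      n_drugs = 60, n_terms = 6, n_pmids = 1200, drugs_per_term = 10,
      p_planted = 0.05, p_background = 0.05, n_genes = 20, rng_seed = s
    ))
    cm <- comention_matrix(w$rif)
    res <- run_benchmark(w$library, w$rif, w$corpus, cm,
                         k = 10, n_shuffles = 5, seed = s)
    mean(res$per_term$auroc) - mean(res$null_per_term$auroc)
  }, numeric(1))
  expect_gt(mean(gaps), 0.02)
})

test_that("degenerate constant matrix yields chance metrics for real and null", {
  w <- small_world()
  labs <- sort(unique(w$rif$drug), method = "radix")
  flat <- similarity_matrix(
    matrix(0.5, length(labs), length(labs), dimnames = list(labs, labs)),
    "cosine"
  )
  res <- run_benchmark(w$library, w$rif, w$corpus, flat,
                       k = 10, n_shuffles = 1, seed = 2)
  expect_true(all(res$per_term$auroc == 0.5))
  expect_true(all(res$null_per_term$auroc == 0.5))
  expect_gt(res$tests$p_value[res$tests$metric == "auroc"], 0.9)
})

test_that("benchmark tidiers and writers expose the documented shapes", {
  w <- small_world()
  m <- comention_matrix(w$rif)
  res <- run_benchmark(w$library, w$rif, w$corpus, m,
                       k = 10, n_shuffles = 2, seed = 4)
  td <- tidy(res)
  expect_setequal(unique(td$source), c("observed", "shuffled null"))
  expect_setequal(unique(td$metric), c("auroc", "avg_precision"))
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(all(c("mean_auroc", "p_auroc", "p_avg_precision") %in% names(g)))

  out <- withr::local_tempdir()
  write_benchmark(res,
                  report_path = file.path(out, "b.tsv"),
                  summary_path = file.path(out, "s.json"),
                  violin_path = file.path(out, "v.tsv"))
  expect_equal(names(readr::read_tsv(file.path(out, "b.tsv"), show_col_types = FALSE)),
               c("term", "auroc", "avg_precision", "n_positives"))
  s <- jsonlite::read_json(file.path(out, "s.json"))
  expect_true(all(c("u_auroc", "p_auroc", "n_skipped") %in% names(s)))
  p <- plot_benchmark(res)
  expect_s3_class(p, "ggplot")
})

test_that("GMT libraries round-trip and malformed lines are located", {
  lib <- list(t1 = c("a", "b"), t2 = c("c", "d", "e"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, f)
  expect_identical(read_gmt(f), lib)
  writeLines(c("t1\tdesc\ta\tb", "bad_line_no_members"), f)
  expect_error(read_gmt(f), regexp = "line 2", class = "comention_format_error")
})
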