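#' Area under the ROC curve of a drug ranking
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted as
#' one half. Computed from midranks, so it is exact under ties.
#'
#' @param scores Named numeric vector of ranking scores (higher = better).
#' @param positives Character vector naming the positive drugs; must be a
#'   nonempty proper subset of `names(scores)`.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(a = 0.9, b = 0.4, c = 0.6, d = 0.1), positives = c("a", "b")) # 0.75
#' @export
auroc <- function(scores, positives) {
  check_ranking(scores, positives)
  is_pos <- names(scores) %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision of a drug ranking
#'
#' Standard AP: the mean, over the positives taken in rank order, of the
#' precision at each positive's rank. Ties in score are broken
#' deterministically by ascending drug name so the value is reproducible.
#'
#' @inheritParams auroc
#' @return Average precision in (0, 1\].
#' @examples
#' # ranking [pos, neg, pos] -> (1/1 + 2/3) / 2
#' average_precision(c(a = 3, b = 2, c = 1), positives = c("a", "c"))
#' @export
average_precision <- function(scores, positives) {
  check_ranking(scores, positives)
  ord <- order(-scores, names(scores), method = "radix")
  hit <- names(scores)[ord] %in% positives
  prec_at_hit <- cumsum(hit)[hit] / which(hit)
  mean(prec_at_hit)
}

check_ranking <- function(scores, positives) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    abort("`scores` must be a named vector with unique names",
          class = "comention_usage_error")
  }
  n_pos <- sum(names(scores) %in% positives)
  if (n_pos < 1 || n_pos >= length(scores)) {
    abort("need at least one positive and one negative in the ranking",
          class = "comention_domain_error")
  }
  invisible(TRUE)
}

#' Score one term's drug set against a similarity matrix
#'
#' The per-term benchmark unit: every drug in the matrix is scored by
#' leave-one-out mean similarity to the seed set ([augment()] with
#' `mode = "loo"`), the seed members are taken as the positives, and the
#' AUROC and average precision of that ranking are returned. High values
#' mean the matrix "knows" the seed drugs belong together.
#'
#' @param seed Character vector of seed drugs (the unweighted drug set).
#' @param matrix A [similarity_matrix()].
#' @return One-row tibble (`auroc`, `avg_precision`, `n_positives`).
#' @export
evaluate_term <- function(seed, matrix) {
  pred <- augment(seed, matrix, top_n = Inf, mode = "loo")
  scores <- setNames(pred$mean_similarity, pred$drug)
  positives <- intersect(unique(normalize_name(seed)), rownames(matrix))
  tibble(
    auroc = auroc(scores, positives),
    avg_precision = average_precision(scores, positives),
    n_positives = length(positives)
  )
}

#' Shuffle a similarity matrix's drug labels
#'
#' The permutation null: one uniformly random permutation is applied
#' jointly to the row and column labels, detaching every drug from its
#' similarity profile while preserving the value grid exactly (multiset,
#' symmetry, spectrum). Deterministic for a given `seed`.
#'
#' @param matrix A [similarity_matrix()].
#' @param seed Integer RNG seed.
#' @return A `similarity_matrix` of the same kind and size.
#' @export
shuffled_matrix <- function(matrix, seed) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  labels <- rownames(matrix)
  perm <- withr::with_seed(as.integer(seed), sample.int(length(labels)))
  out <- unclass(matrix)
  dimnames(out) <- list(labels[perm], labels[perm])
  structure(out, kind = matrix_kind(matrix),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of pairs (x_i, y_j) with x_i > y_j, plus half the tied
#' pairs (the U statistic of sample `x`). The two-sided p-value is exact —
#' by enumeration of all \eqn{\binom{n_1+n_2}{n_1}} rank assignments —
#' when \eqn{n_1 + n_2 \le 16} and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   default `NULL` auto-selects as above.
#' @return One-row tibble (`u`, `p_value`, `method`, `n_x`, `n_y`).
#' @examples
#' mann_whitney_u(c(3, 4), c(1, 2)) # U = 4, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1 || anyNA(x) || anyNA(y)) {
    abort("`x` and `y` must be nonempty numeric samples without NA",
          class = "comention_domain_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (n1 + n2 <= 16 && !has_ties)
  if (use_exact && has_ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    # enumerate every assignment of n1 of the N ranks to sample x
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    # two-sided: as or more extreme in |U - n1*n2/2|; integer-safe via 2U
    p <- mean(abs(2 * us - n1 * n2) >= abs(2 * u - n1 * n2))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble(u = u, p_value = p, method = method, n_x = n1, n_y = n2)
}

#' Read / write GMT term libraries
#'
#' GMT: one term per line — term, description, then tab-separated member
#' drug names. Terms and members are normalized; every term must have at
#' least one member.
#'
#' @param path A `.gmt` file.
#' @return `read_gmt()` returns a named list of character vectors
#'   (term -> drug members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "comention_usage_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- trimws(lines) != ""
  lines <- lines[keep]
  lineno <- which(keep)
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3) {
      abort(sprintf("'%s' line %d: GMT lines need term, description and >= 1 member",
                    path, lineno[i]), class = "comention_format_error")
    }
    term <- normalize_name(fields[1L])
    members <- unique(normalize_name(fields[-(1:2)]))
    members <- members[members != ""]
    if (term == "" || length(members) == 0) {
      abort(sprintf("'%s' line %d: empty term or member list", path, lineno[i]),
            class = "comention_format_error")
    }
    out[[term]] <- members
  }
  out
}

#' @param library Named list of character vectors (term -> members).
#' @param descriptions Optional character vector of per-term descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  stopifnot(is.list(library), !is.null(names(library)))
  desc <- descriptions %||% rep("na", length(library))
  lines <- vapply(seq_along(library), function(i) {
    paste(c(names(library)[i], desc[i], library[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Benchmark a similarity matrix over a library of terms
#'
#' Reproduces the full evaluation loop: for every term in the library the
#' corpus is queried, the association table built, the top-`k` unweighted
#' drug set extracted, and [evaluate_term()] run on the real matrix and on
#' `n_shuffles` label-shuffled copies (the permutation null, pooled across
#' shuffles). The observed per-term AUROC and average-precision
#' distributions are then compared with the pooled null distributions by
#' two-sided Mann-Whitney U tests. The positives for each term are the
#' literature-derived drug set itself — the library contributes only the
#' term list.
#'
#' Terms are skipped (and reported) when the corpus query returns no
#' PMIDs, the association table is empty, or fewer than two drug-set
#' members are present in the matrix.
#'
#' @param library Named list (term -> members) from [read_gmt()]; only
#'   `names(library)` is used.
#' @param rif RIF tibble.
#' @param corpus Corpus tibble from [corpus_index()].
#' @param matrix A [similarity_matrix()].
#' @param k Unweighted drug set size per term (default 20).
#' @param rank_by Ranking key for the drug set (default `"score"`).
#' @param n_shuffles Number of label permutations in the null (default 10).
#' @param seed Integer RNG seed driving the shuffles.
#' @return A `drug_benchmark` object: list with `per_term` and
#'   `null_per_term` tibbles, `tests` (one row per metric with U and p),
#'   `skipped` tibble, and `params`. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
run_benchmark <- function(library, rif, corpus, matrix, k = 20L,
                          rank_by = "score", n_shuffles = 10L, seed = 1L) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (length(library) == 0 || is.null(names(library))) {
    abort("term library is empty", class = "comention_usage_error")
  }
  if (!is.numeric(n_shuffles) || n_shuffles < 1) {
    abort("`n_shuffles` must be >= 1", class = "comention_usage_error")
  }
  n_shuffles <- as.integer(n_shuffles)
  shuffle_seeds <- withr::with_seed(as.integer(seed),
                                    sample.int(2147483646L, n_shuffles))
  nulls <- lapply(shuffle_seeds, function(s) shuffled_matrix(matrix, s))

  terms <- sort_c(unique(normalize_name(names(library))))
  per_term <- list()
  null_rows <- list()
  skipped <- list()
  for (term in terms) {
    pmids <- query_pmids(corpus, include = term)
    if (length(pmids) == 0) {
      skipped[[term]] <- "no publications matched"
      next
    }
    assoc <- suppressWarnings(associate(rif, pmids))
    if (nrow(assoc) == 0) {
      skipped[[term]] <- "no drug shares a PMID with the term"
      next
    }
    ds <- suppressWarnings(top_drug_set(assoc, k = k, rank_by = rank_by))
    if (sum(ds %in% rownames(matrix)) < 2) {
      skipped[[term]] <- "fewer than 2 drug-set members in matrix"
      next
    }
    per_term[[term]] <- evaluate_term(ds, matrix) |> mutate(term = term)
    null_rows[[term]] <- purrr::map2(nulls, seq_len(n_shuffles), function(nm, i) {
      if (sum(ds %in% rownames(nm)) < 2) return(NULL)
      evaluate_term(ds, nm) |> mutate(term = term, shuffle = i)
    }) |> purrr::compact() |> bind_rows()
  }
  if (length(per_term) == 0) {
    abort("every term was skipped; nothing to benchmark",
          class = "comention_usage_error")
  }
  per_term <- bind_rows(per_term) |> select("term", "auroc", "avg_precision", "n_positives")
  null_per_term <- bind_rows(null_rows) |>
    select("term", "shuffle", "auroc", "avg_precision", "n_positives")
  mw_auroc <- mann_whitney_u(per_term$auroc, null_per_term$auroc, exact = FALSE)
  mw_ap <- mann_whitney_u(per_term$avg_precision, null_per_term$avg_precision,
                          exact = FALSE)
  tests <- bind_rows(
    mw_auroc |> mutate(metric = "auroc"),
    mw_ap |> mutate(metric = "avg_precision")
  ) |> select("metric", "u", "p_value", "method", "n_x", "n_y")
  structure(
    list(
      per_term = per_term,
      null_per_term = null_per_term,
      tests = tests,
      skipped = if (length(skipped)) {
        tibble(term = names(skipped), reason = unname(unlist(skipped)))
      } else {
        tibble(term = character(), reason = character())
      },
      params = list(k = k, rank_by = rank_by, n_shuffles = n_shuffles,
                    seed = as.integer(seed), matrix_kind = matrix_kind(matrix),
                    n_terms = nrow(per_term))
    ),
    class = "drug_benchmark"
  )
}

#' @export
print.drug_benchmark <- function(x, ...) {
  cat(sprintf(
    "<drug_benchmark: %s matrix, %d terms scored, %d skipped, %d shuffles>\n",
    x$params$matrix_kind, nrow(x$per_term), nrow(x$skipped), x$params$n_shuffles
  ))
  cat(sprintf("  mean AUROC %.3f (null %.3f); mean AP %.3f (null %.3f)\n",
              mean(x$per_term$auroc), mean(x$null_per_term$auroc),
              mean(x$per_term$avg_precision), mean(x$null_per_term$avg_precision)))
  print(x$tests)
  invisible(x)
}

#' Tidy per-term benchmark metrics
#'
#' Long-format tibble of per-term metrics from the observed matrix and the
#' shuffled null (`source` column), ready for violin plots.
#'
#' @param x A `drug_benchmark` object.
#' @param ... Unused.
#' @method tidy drug_benchmark
#' @export
tidy.drug_benchmark <- function(x, ...) {
  obs <- x$per_term |>
    tidyr::pivot_longer(c("auroc", "avg_precision"),
                        names_to = "metric", values_to = "value") |>
    mutate(source = "observed", shuffle = NA_integer_)
  nul <- x$null_per_term |>
    tidyr::pivot_longer(c("auroc", "avg_precision"),
                        names_to = "metric", values_to = "value") |>
    mutate(source = "shuffled null")
  bind_rows(obs, nul) |> select("term", "metric", "value", "source", "shuffle")
}

#' One-row benchmark summary
#'
#' @inheritParams tidy.drug_benchmark
#' @method glance drug_benchmark
#' @export
glance.drug_benchmark <- function(x, ...) {
  tibble(
    matrix_kind = x$params$matrix_kind,
    n_terms = nrow(x$per_term),
    n_skipped = nrow(x$skipped),
    n_shuffles = x$params$n_shuffles,
    mean_auroc = mean(x$per_term$auroc),
    null_mean_auroc = mean(x$null_per_term$auroc),
    mean_avg_precision = mean(x$per_term$avg_precision),
    null_mean_avg_precision = mean(x$null_per_term$avg_precision),
    u_auroc = x$tests$u[x$tests$metric == "auroc"],
    p_auroc = x$tests$p_value[x$tests$metric == "auroc"],
    u_avg_precision = x$tests$u[x$tests$metric == "avg_precision"],
    p_avg_precision = x$tests$p_value[x$tests$metric == "avg_precision"]
  )
}

#' Write benchmark outputs
#'
#' Per-term report as TSV (term, auroc, avg_precision, n_positives), a
#' JSON summary (U statistics, p-values, skip counts), and the long-format
#' violin-plot data.
#'
#' @param result A `drug_benchmark`.
#' @param report_path,summary_path,violin_path Output files; `NULL` skips.
#' @export
write_benchmark <- function(result, report_path = NULL, summary_path = NULL,
                            violin_path = NULL) {
  stopifnot(inherits(result, "drug_benchmark"))
  if (!is.null(report_path)) {
    readr::write_tsv(result$per_term, report_path, progress = FALSE)
  }
  if (!is.null(summary_path)) {
    s <- as.list(glance(result))
    s$skipped <- result$skipped
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(violin_path)) {
    readr::write_tsv(tidy(result), violin_path, progress = FALSE)
  }
  invisible(result)
}
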