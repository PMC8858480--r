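#' Score drugs against a term's publications
#'
#' The core scorer: cross-references the PMIDs returned for a search term
#' with a drug-PMID table. For every drug sharing at least one PMID with
#' the term it reports
#' \describe{
#'   \item{count}{number of publications mentioning both the drug and the
#'     term, \eqn{c = |P_{term} \cap P_{drug}|};}
#'   \item{fraction}{the normalized fraction \eqn{f = c / |P_{drug}|} —
#'     how specific the term is to that drug;}
#'   \item{score}{the ranking key \eqn{c \times f = c^2/|P_{drug}|},
#'     balancing how often a drug is co-mentioned with how specific the
#'     term is to it.}
#' }
#' Rows are sorted by score descending, with deterministic tie-breaking
#' (score desc, then count desc, then drug name ascending).
#'
#' @param rif A RIF tibble from [build_rif()].
#' @param term_pmids Integer vector of PMIDs matching the term (from
#'   [query_pmids()]).
#' @return A tibble (`drug`, `count`, `fraction`, `score`). Empty (with a
#'   warning) when `term_pmids` is empty or no drug overlaps.
#' @examples
#' rif <- build_rif(data.frame(
#'   drug = c(rep("a", 4), "b", "b"),
#'   pmid = c(1, 2, 3, 4, 3, 4)
#' ))
#' associate(rif, c(1, 2, 3))
#' # a: count 3, fraction 0.75, score 2.25; b: count 1, fraction 0.5, score 0.5
#' @export
associate <- function(rif, term_pmids) {
  stopifnot(is.data.frame(rif), all(c("drug", "pmid") %in% names(rif)))
  if (nrow(rif) == 0) {
    abort("RIF table is empty", class = "comention_usage_error")
  }
  empty <- tibble(drug = character(), count = integer(),
                  fraction = double(), score = double())
  if (length(term_pmids) == 0) {
    warn("term matched no publications; association table is empty")
    return(empty)
  }
  term_pmids <- unique(as.integer(term_pmids))
  totals <- rif_totals(rif)
  rif |>
    distinct(.data$drug, .data$pmid) |>
    filter(.data$pmid %in% term_pmids) |>
    count(.data$drug, name = "count") |>
    left_join(totals, by = "drug") |>
    mutate(
      fraction = .data$count / .data$total,
      score = .data$count * .data$fraction
    ) |>
    select("drug", "count", "fraction", "score") |>
    arrange(desc(.data$score), desc(.data$count), .data$drug)
}

#' Fraction and score for one drug
#'
#' `score = count * (count / total) = count^2 / total`: the product of the
#' co-mention count and the normalized fraction of the drug's literature
#' devoted to the term.
#'
#' @param count Publications shared between drug and term, `1 <= count <= total`.
#' @param total Total publications mentioning the drug.
#' @return A list with elements `fraction` and `score`.
#' @examples
#' rank_score(2, 4) # fraction 0.5, score 1
#' @export
rank_score <- function(count, total) {
  if (any(total <= 0)) {
    abort("`total` must be positive", class = "comention_domain_error")
  }
  if (any(count < 1) || any(count > total)) {
    abort("`count` must satisfy 1 <= count <= total", class = "comention_domain_error")
  }
  fraction <- count / total
  list(fraction = fraction, score = count * fraction)
}

#' Take the top-k unweighted drug set from an association table
#'
#' The unweighted drug set is the unordered set of the `k` best drugs
#' under a chosen ranking key; it seeds the similarity-based augmentation
#' step. The default path constrains `k` to 20-200 (the conventional
#' range for this workflow); set `enforce_range = FALSE` for
#' user-supplied sizes.
#'
#' @param table An association tibble from [associate()].
#' @param k Set size; if fewer drugs are available all are returned with a
#'   warning.
#' @param rank_by One of `"score"` (default), `"count"`, `"fraction"`.
#' @param enforce_range Require `20 <= k <= 200` (default `FALSE` so the
#'   function composes freely; the query pipeline turns it on).
#' @return Character vector of drug names, best first.
#' @export
top_drug_set <- function(table, k = 20L, rank_by = c("score", "count", "fraction"),
                         enforce_range = FALSE) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.data.frame(table))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a single integer >= 1", class = "comention_usage_error")
  }
  k <- as.integer(k)
  if (enforce_range && (k < 20L || k > 200L)) {
    abort("`k` must be in [20, 200] on the default path", class = "comention_usage_error")
  }
  if (nrow(table) == 0) {
    warn("association table is empty; returning an empty drug set")
    return(character())
  }
  if (k > nrow(table)) {
    warn(sprintf("requested k = %d but only %d drugs available; returning all",
                 k, nrow(table)))
  }
  ranked <- table |>
    arrange(desc(.data[[rank_by]]), desc(.data$score), desc(.data$count), .data$drug)
  head(ranked$drug, k)
}

#' Export an association table (and its scatter data) as TSV
#'
#' Numeric columns are written at 6 significant digits (display only; the
#' in-memory table keeps full precision). `write_scatter()` exports the
#' (x = count, y = fraction) pairs used for literature-specificity scatter
#' plots.
#'
#' @param table An association tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(table, path) {
  out <- table |>
    mutate(fraction = signif(.data$fraction, 6), score = signif(.data$score, 6))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_association
#' @export
write_scatter <- function(table, path) {
  out <- table |>
    select(drug = "drug", x = "count", y = "fraction") |>
    mutate(y = signif(.data$y, 6))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
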