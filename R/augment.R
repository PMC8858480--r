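#' Augment a seed drug set by average similarity
#'
#' Seeds a drug-drug similarity matrix with an unweighted drug set and
#' ranks drugs by their mean similarity to the seed members. Two modes:
#' \describe{
#'   \item{predict}{rank only non-seed drugs (the augmentation/prediction
#'     tables shown to users): \eqn{\bar s(d) = \frac{1}{m}\sum_{s \in S} M[d, s]}
#'     over the \eqn{m} seed drugs matched in the matrix;}
#'   \item{loo}{rank every drug in the matrix, excluding the self term for
#'     seed members (divisor \eqn{m - 1}); this leave-one-out scoring is
#'     what the benchmark uses, since counting a drug's self-similarity
#'     would trivially inflate its own rank.}
#' }
#' Seed drugs absent from the matrix are dropped with a warning; fewer
#' than two matched seeds is an error.
#'
#' @param seed Character vector of seed drug names (normalized internally)
#'   or a data frame with a `drug` column.
#' @param matrix A [similarity_matrix()].
#' @param top_n Number of rows to return (default 20); `Inf` for all.
#' @param mode `"predict"` (default) or `"loo"`.
#' @return A tibble (`drug`, `mean_similarity`) sorted by mean similarity
#'   descending, ties broken by drug name; attributes `matrix_kind` and
#'   `mode` record provenance.
#' @examples
#' m <- similarity_matrix(
#'   matrix(c(1, .2, .8, .2, 1, .4, .8, .4, 1), 3,
#'     dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
#'   ),
#'   kind = "cosine"
#' )
#' augment(c("a", "b"), m) # c scored (0.8 + 0.4) / 2 = 0.6
#' @export
augment <- function(seed, matrix, top_n = 20L, mode = c("predict", "loo")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (is.data.frame(seed)) seed <- seed$drug
  seed <- unique(normalize_name(seed))
  seed <- seed[seed != ""]
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1) {
    abort("`top_n` must be a single number >= 1", class = "comention_usage_error")
  }
  labels <- rownames(matrix)
  matched <- seed[seed %in% labels]
  missing <- setdiff(seed, matched)
  if (length(matched) < 2) {
    abort(sprintf(
      "need at least 2 seed drugs present in the matrix; unmatched: %s",
      if (length(missing)) paste(missing, collapse = ", ") else "<none>"
    ), class = "comention_usage_error")
  }
  if (length(missing) > 0) {
    warn(sprintf("%d seed drug(s) not in matrix, dropped: %s",
                 length(missing), paste(head(missing, 10L), collapse = ", ")))
  }
  m <- length(matched)
  sums <- rowSums(unclass(matrix)[, matched, drop = FALSE])
  if (mode == "predict") {
    cand <- setdiff(labels, matched)
    scores <- sums[cand] / m
  } else {
    scores <- sums / m
    self <- unclass(matrix)[cbind(matched, matched)]
    scores[matched] <- (sums[matched] - self) / (m - 1)
  }
  out <- tibble(drug = names(scores), mean_similarity = unname(scores)) |>
    arrange(desc(.data$mean_similarity), .data$drug) |>
    head(if (is.finite(top_n)) as.integer(top_n) else nrow(matrix))
  attr(out, "matrix_kind") <- matrix_kind(matrix)
  attr(out, "mode") <- mode
  out
}

#' Read a user-supplied drug set
#'
#' One drug name per line; blank lines and `#` comments are ignored; names
#' are normalized and deduplicated. At least two usable names are
#' required.
#'
#' @param path Text file of drug names.
#' @return Character vector of unique normalized names, in file order.
#' @export
read_drug_set <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "comention_usage_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  names <- unique(normalize_name(lines))
  names <- names[names != ""]
  if (length(names) < 2) {
    abort(sprintf("'%s': a drug set needs at least 2 names (found %d)",
                  path, length(names)), class = "comention_usage_error")
  }
  names
}

#' @param drugs Character vector of drug names.
#' @rdname read_drug_set
#' @export
write_drug_set <- function(drugs, path) {
  readr::write_lines(drugs, path)
  invisible(path)
}

#' Export a prediction table as TSV
#'
#' Columns: drug, mean_similarity (6 significant digits), matrix_kind.
#'
#' @param table Tibble from [augment()].
#' @param path Output file.
#' @export
write_predictions <- function(table, path) {
  out <- table |>
    mutate(mean_similarity = signif(.data$mean_similarity, 6),
           matrix_kind = attr(table, "matrix_kind") %||% NA_character_)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
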