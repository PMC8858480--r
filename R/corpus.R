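#' Build or read a local document-term corpus
#'
#' The corpus is the offline stand-in for a PubMed term search: a table of
#' (PMID, term) postings. `query_pmids()` resolves a query — one or more
#' terms combined with logical AND plus optional exclusion terms — to the
#' set of matching PMIDs with plain set algebra on the postings. Term
#' matching is exact on normalized (lowercased, trimmed) strings; no
#' stemming or synonym expansion is attempted.
#'
#' @param postings A data frame whose first two columns are PMID and term.
#' @return A tibble (`pmid` integer, `term` character), deduplicated.
#' @examples
#' corpus <- corpus_index(data.frame(
#'   pmid = c(1, 2, 1, 3),
#'   term = c("t1", "t1", "t2", "t2")
#' ))
#' query_pmids(corpus, include = c("t1", "t2")) # intersection -> 1
#' query_pmids(corpus, include = "t1", exclude = "t2") # 2
#' @export
corpus_index <- function(postings) {
  stopifnot(is.data.frame(postings), ncol(postings) >= 2)
  if (nrow(postings) == 0) {
    return(tibble(pmid = integer(), term = character()))
  }
  tibble(
    pmid = as_pmid(postings[[1L]], context = "corpus_index"),
    term = normalize_name(postings[[2L]])
  ) |>
    filter(.data$term != "") |>
    distinct(.data$pmid, .data$term) |>
    arrange(.data$term, .data$pmid)
}

#' @param path Tab-separated file with columns (PMID, term); optional
#'   header auto-detected; `.gz` transparent.
#' @rdname corpus_index
#' @export
read_corpus <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) {
    abort(sprintf("'%s': expected at least 2 tab-separated columns", path),
          class = "comention_format_error")
  }
  corpus_index(raw[, 1:2])
}

#' @param corpus A corpus tibble from [corpus_index()].
#' @param include Character vector of required terms (logical AND),
#'   length >= 1.
#' @param exclude Character vector of terms whose publications are removed
#'   from the result; may be empty.
#' @return `query_pmids()` returns a sorted integer vector of PMIDs. A
#'   term absent from the corpus has an empty postings set, so any unknown
#'   include term yields an empty result.
#' @rdname corpus_index
#' @export
query_pmids <- function(corpus, include, exclude = character()) {
  stopifnot(is.data.frame(corpus))
  include <- normalize_name(include)
  include <- include[include != ""]
  if (length(include) == 0) {
    abort("at least one include term is required", class = "comention_usage_error")
  }
  exclude <- normalize_name(exclude)
  postings <- function(term) corpus$pmid[corpus$term == term]
  hits <- Reduce(intersect, lapply(include, postings))
  if (length(exclude) > 0) {
    hits <- setdiff(hits, unique(unlist(lapply(exclude, postings))))
  }
  sort(unique(as.integer(hits)))
}
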