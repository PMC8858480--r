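#' Build a drug-PMID reference table (RIF)
#'
#' A RIF ("references into function") table maps each drug or small
#' molecule to the set of PubMed identifiers (PMIDs) of publications that
#' mention it. This is the core resource the association scorer
#' cross-references against a term's PMIDs. Drug names are normalized
#' (lowercased, trimmed), duplicate (drug, PMID) pairs are collapsed, and
#' drugs associated with fewer than `min_pmids` distinct publications are
#' dropped — literature-mined tables of this kind conventionally require
#' at least two supporting PMIDs per compound.
#'
#' @param pairs A data frame whose first two columns are drug name and
#'   PMID (column names are ignored; extra columns are dropped).
#' @param min_pmids Minimum number of distinct PMIDs a drug must have to
#'   be retained. Default 2.
#'
#' @return A tibble with columns `drug` (character, normalized) and
#'   `pmid` (integer), one row per retained (drug, PMID) pair, sorted by
#'   drug then PMID.
#'
#' @examples
#' pairs <- data.frame(
#'   drug = c("Aspirin", "aspirin", "aspirin", "niacin"),
#'   pmid = c(1, 1, 2, 7)
#' )
#' build_rif(pairs, min_pmids = 2) # niacin (1 PMID) is dropped
#' @export
build_rif <- function(pairs, min_pmids = 2L) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  if (!is.numeric(min_pmids) || length(min_pmids) != 1 || min_pmids < 1) {
    abort("`min_pmids` must be a single integer >= 1", class = "comention_usage_error")
  }
  min_pmids <- as.integer(min_pmids)
  if (nrow(pairs) == 0) {
    return(tibble(drug = character(), pmid = integer()))
  }
  drug <- normalize_name(pairs[[1L]])
  if (any(drug == "")) {
    abort(sprintf("empty drug name at row %d", which(drug == "")[1L]),
          class = "comention_format_error")
  }
  tibble(drug = drug, pmid = as_pmid(pairs[[2L]], context = "build_rif")) |>
    distinct(.data$drug, .data$pmid) |>
    group_by(.data$drug) |>
    filter(n() >= min_pmids) |>
    ungroup() |>
    arrange(.data$drug, .data$pmid)
}

#' Read / write RIF tables as TSV
#'
#' The on-disk format is a two-column tab-separated file (drug name,
#' PMID), one association per row, UTF-8, optionally gzip-compressed
#' (`.gz` extension handled transparently). A header row is auto-detected:
#' if the second field of the first line is not an integer, the line is
#' treated as a header and skipped. Extra columns (e.g. InChIKeys carried
#' alongside names) are accepted and ignored on read.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @param min_pmids Passed on to [build_rif()]; default 2.
#' @return `read_rif()` returns the tibble produced by [build_rif()];
#'   `write_rif()` returns `path` invisibly.
#' @examples
#' rif <- build_rif(data.frame(d = c("a", "a", "b", "b"), p = c(1, 2, 2, 3)))
#' f <- tempfile(fileext = ".tsv")
#' write_rif(rif, f)
#' identical(read_rif(f), rif)
#' @export
read_rif <- function(path, min_pmids = 2L) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) {
    abort(sprintf("'%s': expected at least 2 tab-separated columns", path),
          class = "comention_format_error")
  }
  raw <- raw[!is.na(raw[[1L]]) | !is.na(raw[[2L]]), , drop = FALSE]
  if (nrow(raw) > 0 && any(is.na(raw[[1L]]) | raw[[1L]] == "")) {
    abort(sprintf("'%s': empty drug name at data line %d",
                  path, which(is.na(raw[[1L]]) | raw[[1L]] == "")[1L]),
          class = "comention_format_error")
  }
  build_rif(raw[, 1:2], min_pmids = min_pmids)
}

#' @param rif A RIF tibble as returned by [build_rif()].
#' @rdname read_rif
#' @export
write_rif <- function(rif, path) {
  stopifnot(is.data.frame(rif), all(c("drug", "pmid") %in% names(rif)))
  out <- tibble(drug = rif$drug, pmid = format(rif$pmid, scientific = FALSE, trim = TRUE))
  readr::write_tsv(out, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# readr with header auto-detection: peek at the first line; if field 2
# parses as an integer it is data, otherwise a header.
read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "comention_usage_error")
  }
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  has_header <- FALSE
  if (length(first) == 1L) {
    fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
    if (length(fields) >= 2L && !grepl("^[0-9]+$", trimws(fields[2L]))) {
      has_header <- TRUE
    }
  }
  readr::read_tsv(path, col_names = has_header, col_types = col_types,
                  skip = if (has_header) 0L else 0L, progress = FALSE,
                  show_col_types = FALSE, name_repair = "minimal")
}

#' Per-drug publication totals of a RIF table
#'
#' @param rif A RIF tibble.
#' @return A tibble (`drug`, `total`) with the number of distinct PMIDs
#'   per drug, in ascending drug order.
#' @export
rif_totals <- function(rif) {
  rif |>
    distinct(.data$drug, .data$pmid) |>
    count(.data$drug, name = "total") |>
    arrange(.data$drug)
}
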