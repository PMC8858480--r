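#' Similarity matrix objects
#'
#' A similarity matrix is a square, symmetric, label-aligned numeric
#' matrix of drug-drug similarities of one of two kinds:
#' \describe{
#'   \item{comention}{pairwise absolute counts of shared PMIDs; the
#'     diagonal holds each drug's total PMID count;}
#'   \item{cosine}{pairwise cosine similarity of drug-induced expression
#'     signatures; entries in \[-1, 1\], unit diagonal.}
#' }
#'
#' @param values Square numeric matrix with identical row/column names.
#' @param kind `"comention"` or `"cosine"`.
#' @return A `similarity_matrix` (a base matrix with a `kind` attribute).
#' @export
similarity_matrix <- function(values, kind = c("comention", "cosine")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) != ncol(values)) {
    abort("similarity matrix must be square", class = "comention_format_error")
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || is.null(cn)) {
    abort("similarity matrix must carry row and column labels",
          class = "comention_format_error")
  }
  if (!identical(rn, cn)) {
    i <- which(rn != cn)[1L]
    abort(sprintf("row/column label mismatch at position %d: '%s' vs '%s'",
                  i, rn[i], cn[i]),
          class = "comention_format_error")
  }
  if (anyDuplicated(rn)) {
    abort("duplicate drug labels in similarity matrix", class = "comention_format_error")
  }
  asym <- max(abs(values - t(values)))
  tol <- if (kind == "comention") 0 else 1e-8
  if (asym > tol) {
    abort(sprintf("matrix is not symmetric (max asymmetry %.3g)", asym),
          class = "comention_format_error")
  }
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @param x A `similarity_matrix`.
#' @rdname similarity_matrix
#' @export
matrix_kind <- function(x) attr(x, "kind") %||% "comention"

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %s, %d drugs>\n", matrix_kind(x), nrow(x)))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L), ...)
  invisible(x)
}

#' Pairwise shared-PMID counts between drugs
#'
#' Builds the literature co-mention prediction matrix from a RIF table:
#' entry (i, j) is the number of PMIDs mentioning both drug i and drug j;
#' the diagonal is each drug's total. Computed via a sparse drug-by-PMID
#' incidence matrix, so it scales to full literature-mined tables.
#'
#' @param rif A RIF tibble from [build_rif()].
#' @return A `similarity_matrix` of kind `"comention"`, labels in
#'   ascending order.
#' @examples
#' rif <- build_rif(data.frame(
#'   d = c("a", "a", "a", "b", "b", "b"),
#'   p = c(1, 2, 3, 2, 3, 4)
#' ))
#' comention_matrix(rif) # off-diagonal 2 (shared PMIDs 2 and 3)
#' @export
comention_matrix <- function(rif) {
  stopifnot(is.data.frame(rif), all(c("drug", "pmid") %in% names(rif)))
  if (nrow(rif) == 0) {
    abort("RIF table is empty", class = "comention_usage_error")
  }
  pairs <- distinct(rif, .data$drug, .data$pmid)
  drugs <- sort_c(unique(pairs$drug))
  pmids <- sort(unique(pairs$pmid))
  inc <- Matrix::sparseMatrix(
    i = match(pairs$drug, drugs),
    j = match(pairs$pmid, pmids),
    x = 1,
    dims = c(length(drugs), length(pmids)),
    dimnames = list(drugs, NULL)
  )
  m <- as.matrix(Matrix::tcrossprod(inc))
  storage.mode(m) <- "double"
  dimnames(m) <- list(drugs, drugs)
  similarity_matrix(m, kind = "comention")
}

#' Pairwise cosine similarity between drug signatures
#'
#' Entry (i, j) is \eqn{\langle v_i, v_j\rangle / (\|v_i\| \|v_j\|)} for
#' signature rows \eqn{v_i}. Signatures are used as given — any centering
#' or z-scoring is upstream preprocessing and the caller's responsibility.
#' Rows with zero norm cannot be placed on the unit sphere and are dropped
#' with a warning.
#'
#' @param signatures Numeric matrix, drugs in rows (rownames required),
#'   features in columns.
#' @return A `similarity_matrix` of kind `"cosine"`, labels in ascending
#'   order.
#' @export
cosine_matrix <- function(signatures) {
  stopifnot(is.matrix(signatures), is.numeric(signatures))
  if (is.null(rownames(signatures))) {
    abort("signature matrix must have drug rownames", class = "comention_format_error")
  }
  rownames(signatures) <- normalize_name(rownames(signatures))
  norms <- sqrt(rowSums(signatures^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(sprintf("dropping %d zero-norm signature(s): %s",
                 sum(zero), paste(head(rownames(signatures)[zero], 5L), collapse = ", ")))
    signatures <- signatures[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  if (nrow(signatures) == 0) {
    abort("no nonzero signatures remain", class = "comention_usage_error")
  }
  ord <- order(rownames(signatures), method = "radix")
  signatures <- signatures[ord, , drop = FALSE]
  norms <- norms[ord]
  unit <- signatures / norms
  m <- tcrossprod(unit)
  m <- (m + t(m)) / 2  # enforce exact symmetry against FP round-off
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  similarity_matrix(m, kind = "cosine")
}

#' Read / write labeled similarity matrices as TSV
#'
#' Format: header row of drug labels (first header field names the label
#' column), then one row per drug whose first field is its label. Row and
#' column label sets must match; `.gz` is handled transparently.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @param kind Matrix kind recorded on read; `"comention"` or `"cosine"`.
#' @return `read_similarity_matrix()` returns a `similarity_matrix`;
#'   `write_similarity_matrix()` returns `path` invisibly.
#' @export
read_similarity_matrix <- function(path, kind = c("comention", "cosine")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "comention_usage_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  # first column is the label column regardless of its header name
  labels <- as.character(raw[[1L]])
  vals <- vapply(raw[, -1L, drop = FALSE], as.numeric, numeric(nrow(raw)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw),
                                       dimnames = list(NULL, names(raw)[-1L]))
  if (nrow(vals) != ncol(vals)) {
    abort(sprintf("'%s': matrix is %d x %d, not square", path, nrow(vals), ncol(vals)),
          class = "comention_format_error")
  }
  rownames(vals) <- labels
  if (!identical(labels, colnames(vals))) {
    i <- which(labels != colnames(vals))[1L]
    abort(sprintf("'%s': row label '%s' does not match column label '%s' at position %d",
                  path, labels[i], colnames(vals)[i], i),
          class = "comention_format_error")
  }
  m <- (vals + t(vals)) / 2  # symmetrize away serialization round-off
  similarity_matrix(m, kind = kind)
}

#' @param matrix A `similarity_matrix`.
#' @rdname read_similarity_matrix
#' @export
write_similarity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  out <- as_tibble(as.data.frame(unclass(matrix)), .name_repair = "minimal")
  names(out) <- colnames(matrix)
  out <- dplyr::bind_cols(tibble(drug = rownames(matrix)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a drug-by-feature signature matrix from TSV
#'
#' Header row of feature labels; one row per drug, first field the drug
#' name (normalized on read).
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return Numeric matrix with drug rownames.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "comention_usage_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  labels <- normalize_name(raw[[1L]])
  vals <- vapply(raw[, -1L, drop = FALSE], as.numeric, numeric(nrow(raw)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw),
                                       dimnames = list(NULL, names(raw)[-1L]))
  rownames(vals) <- labels
  vals
}

#' @param signatures Numeric matrix with drug rownames.
#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(signatures, path) {
  stopifnot(is.matrix(signatures), !is.null(rownames(signatures)))
  out <- dplyr::bind_cols(
    tibble(drug = rownames(signatures)),
    as_tibble(as.data.frame(signatures), .name_repair = "minimal")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
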