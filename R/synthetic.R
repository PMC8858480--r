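#' Configuration for a planted-structure synthetic world
#'
#' The generator emulates the statistical structure the co-mention method
#' exploits, without any real text: a corpus of publications each about
#' one term, where publications about a term preferentially mention that
#' term's planted drugs, plus expression signatures in which planted
#' co-term drugs share a cluster centroid. Defaults are the standard
#' study conditions used throughout the package's tests: 200 drugs, 20
#' terms, 5,000 publications, 10 planted drugs per term, a 30% chance
#' that a publication mentions each planted drug of its term versus a 1%
#' background mention rate.
#'
#' @param n_drugs,n_terms,n_pmids World dimensions.
#' @param drugs_per_term Planted drugs per term (a partition of the drug
#'   pool when `drugs_per_term * n_terms <= n_drugs`, otherwise sampled
#'   per term with reuse).
#' @param p_planted Probability a publication mentions each planted drug
#'   of its term.
#' @param p_background Baseline mention probability for all other drugs;
#'   must not exceed `p_planted` (equality gives the signal-free null
#'   world).
#' @param n_genes Signature dimensionality.
#' @param cluster_noise_sd Isotropic noise around each cluster centroid.
#' @param rng_seed Integer seed; the whole world is deterministic given it.
#' @return A `planted_world_config` list.
#' @export
planted_world_config <- function(n_drugs = 200L, n_terms = 20L, n_pmids = 5000L,
                                 drugs_per_term = 10L, p_planted = 0.3,
                                 p_background = 0.01, n_genes = 100L,
                                 cluster_noise_sd = 0.5, rng_seed = 0L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs), n_terms = as.integer(n_terms),
    n_pmids = as.integer(n_pmids), drugs_per_term = as.integer(drugs_per_term),
    p_planted = p_planted, p_background = p_background,
    n_genes = as.integer(n_genes), cluster_noise_sd = cluster_noise_sd,
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    if (n_drugs < 2 || n_terms < 1 || n_pmids < 1 || n_genes < 1) {
      abort("world dimensions must be positive (and n_drugs >= 2)",
            class = "comention_usage_error")
    }
    if (drugs_per_term < 1 || drugs_per_term > n_drugs) {
      abort("`drugs_per_term` must be in [1, n_drugs]", class = "comention_usage_error")
    }
    if (p_background < 0 || p_planted > 1 || p_background > p_planted) {
      abort("need 0 <= p_background <= p_planted <= 1", class = "comention_usage_error")
    }
    if (cluster_noise_sd < 0) {
      abort("`cluster_noise_sd` must be >= 0", class = "comention_usage_error")
    }
  })
  structure(cfg, class = "planted_world_config")
}

#' Generate a synthetic world with planted drug-term structure
#'
#' Simulates, deterministically for the configured seed:
#' 1. each publication (PMID) is assigned one term uniformly at random;
#' 2. a publication mentions each planted drug of its term with
#'    probability `p_planted`, and every other drug with probability
#'    `p_background`;
#' 3. the resulting (drug, PMID) pairs become a RIF table via
#'    [build_rif()] with the standard >= 2 PMID filter;
#' 4. each term's planted drugs form a signature cluster: signatures are
#'    that cluster's centroid plus isotropic Gaussian noise; unplanted
#'    drugs get pure-noise signatures (cluster 0);
#' 5. the term library annotates each term with its planted drugs.
#'
#' @param config A [planted_world_config()].
#' @return A list of class `planted_world`: `corpus` (tibble), `rif`
#'   (tibble), `signatures` (matrix), `library` (named list), `truth`
#'   (list with `planted` term->drugs and `clusters` drug->cluster id),
#'   and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "planted_world_config"))
  withr::with_seed(config$rng_seed, {
    drugs <- sprintf("drug%04d", seq_len(config$n_drugs))
    terms <- sprintf("term%03d", seq_len(config$n_terms))
    pmids <- seq_len(config$n_pmids)

    pmid_term <- sample.int(config$n_terms, config$n_pmids, replace = TRUE)

    if (config$drugs_per_term * config$n_terms <= config$n_drugs) {
      pool <- sample(drugs)
      planted <- split(
        pool[seq_len(config$drugs_per_term * config$n_terms)],
        rep(seq_len(config$n_terms), each = config$drugs_per_term)
      )
    } else {
      planted <- lapply(seq_len(config$n_terms), function(i) {
        sample(drugs, config$drugs_per_term)
      })
    }
    names(planted) <- terms
    planted <- lapply(planted, sort_c)

    # mention probabilities: background everywhere, planted cells upgraded
    prob <- matrix(config$p_background, nrow = config$n_pmids,
                   ncol = config$n_drugs)
    drug_idx <- seq_along(drugs)
    names(drug_idx) <- drugs
    for (t in seq_len(config$n_terms)) {
      rows <- which(pmid_term == t)
      if (length(rows)) prob[rows, drug_idx[planted[[t]]]] <- config$p_planted
    }
    hits <- which(matrix(runif(length(prob)), nrow = nrow(prob)) < prob,
                  arr.ind = TRUE)
    pairs <- tibble(drug = drugs[hits[, 2L]], pmid = pmids[hits[, 1L]])
    rif <- build_rif(pairs, min_pmids = 2L)

    corpus <- corpus_index(tibble(pmid = pmids, term = terms[pmid_term]))

    clusters <- setNames(integer(config$n_drugs), drugs)
    for (t in seq_len(config$n_terms)) {
      unassigned <- planted[[t]][clusters[planted[[t]]] == 0L]
      clusters[unassigned] <- t
    }
    centroids <- matrix(rnorm(config$n_terms * config$n_genes),
                        nrow = config$n_terms)
    signatures <- matrix(
      rnorm(config$n_drugs * config$n_genes, sd = config$cluster_noise_sd),
      nrow = config$n_drugs, dimnames = list(drugs, NULL)
    )
    in_cluster <- clusters > 0L
    if (any(in_cluster)) {
      signatures[in_cluster, ] <- signatures[in_cluster, , drop = FALSE] +
        centroids[clusters[in_cluster], , drop = FALSE]
    }
    # unplanted drugs: unit-variance noise so their norms are comparable
    if (any(!in_cluster)) {
      signatures[!in_cluster, ] <- matrix(
        rnorm(sum(!in_cluster) * config$n_genes),
        nrow = sum(!in_cluster)
      )
    }
    colnames(signatures) <- sprintf("gene%04d", seq_len(config$n_genes))

    structure(
      list(
        corpus = corpus,
        rif = rif,
        signatures = signatures,
        library = planted,
        truth = list(planted = planted, clusters = clusters),
        config = config
      ),
      class = "planted_world"
    )
  })
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf(
    "<planted_world: %d drugs, %d terms, %d publications, seed %d>\n",
    x$config$n_drugs, x$config$n_terms, x$config$n_pmids, x$config$rng_seed
  ))
  cat(sprintf("  rif: %d pairs over %d drugs; p_planted %.3g, p_background %.3g\n",
              nrow(x$rif), dplyr::n_distinct(x$rif$drug),
              x$config$p_planted, x$config$p_background))
  invisible(x)
}

#' Fraction of a term's planted drugs recovered in the top-k
#'
#' `|top-k drugs of the association table ∩ planted(term)| /
#' min(k, |planted(term)|)` — 1 when the top of the table is exactly the
#' planted set, 0 when none of it is.
#'
#' @param table Association tibble from [associate()] for this term.
#' @param truth The `truth` element of a [generate_world()] result.
#' @param term Term name.
#' @param k Depth of the ranking to inspect.
#' @return Recovery rate in \[0, 1\].
#' @export
recovery_rate <- function(table, truth, term, k = 10L) {
  term <- normalize_name(term)
  if (!term %in% names(truth$planted)) {
    abort(sprintf("unknown term '%s'", term), class = "comention_domain_error")
  }
  planted <- truth$planted[[term]]
  topk <- head(table$drug, k)
  length(intersect(topk, planted)) / min(k, length(planted))
}

#' Write every component of a synthetic world to a directory
#'
#' Emits corpus TSV, RIF TSV, signature matrix TSV, term library GMT and
#' a ground-truth JSON; used by the `synthesize` command.
#'
#' @param world A `planted_world`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "planted_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    corpus = file.path(dir, "corpus.tsv"),
    rif = file.path(dir, "rif.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    library = file.path(dir, "library.gmt"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(world$corpus[, c("pmid", "term")], paths[["corpus"]],
                   progress = FALSE)
  write_rif(world$rif, paths[["rif"]])
  write_signature_matrix(world$signatures, paths[["signatures"]])
  write_gmt(world$library, paths[["library"]])
  jsonlite::write_json(
    list(planted = world$truth$planted,
         clusters = as.list(world$truth$clusters),
         config = unclass(world$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
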