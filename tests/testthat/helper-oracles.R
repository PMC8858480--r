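# Definition-level oracles, kept independent of the implementation paths
# they check.

# AUROC by brute-force pair counting: P(pos > neg) + 0.5 * P(pos == neg).
oracle_auroc <- function(scores, positives) {
  pos <- scores[names(scores) %in% positives]
  neg <- scores[!names(scores) %in% positives]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision straight from the definition, using the same
# deterministic tie order (score desc, name asc).
oracle_average_precision <- function(scores, positives) {
  ord <- order(-scores, names(scores), method = "radix")
  hit <- names(scores)[ord] %in% positives
  ranks_of_hits <- which(hit)
  mean(vapply(seq_along(ranks_of_hits), function(i) {
    i / ranks_of_hits[i]
  }, numeric(1)))
}

# Random named ranking with controllable tie mass.
random_ranking <- function(n, n_pos, tie_levels = NULL) {
  nm <- sprintf("d%03d", seq_len(n))
  scores <- if (is.null(tie_levels)) {
    stats::runif(n)
  } else {
    sample(seq_len(tie_levels), n, replace = TRUE) / tie_levels
  }
  names(scores) <- nm
  list(scores = scores, positives = sample(nm, n_pos))
}

# Tiny RIF fixture shared across files: a {1,2,3,4}, b {3,4}.
fixture_rif <- function() {
  build_rif(data.frame(
    drug = c("a", "a", "a", "a", "b", "b"),
    pmid = c(1, 2, 3, 4, 3, 4)
  ))
}

# 3-label similarity matrix with hand-set values.
fixture_matrix <- function(kind = "cosine") {
  v <- matrix(c(
    1.0, 0.2, 0.8,
    0.2, 1.0, 0.4,
    0.8, 0.4, 1.0
  ), nrow = 3, byrow = TRUE, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  similarity_matrix(v, kind = kind)
}

# Small planted world reused by several files (cheap to regenerate).
small_world <- function(seed = 1L) {
  generate_world(planted_world_config(
    n_drugs = 60L, n_terms = 6L, n_pmids = 1200L, drugs_per_term = 10L,
    n_genes = 40L, rng_seed = seed
  ))
}
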