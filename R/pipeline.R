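#' Run the full term-query pipeline and write its outputs
#'
#' Query -> associate -> unweighted drug set -> augmentation against each
#' supplied similarity matrix. Writes the association table, scatter data,
#' drug set, one prediction table per matrix, and a run manifest recording
#' the package version, parameters, seed and MD5 checksums of the inputs
#' (no timestamps, so identical invocations are byte-identical).
#'
#' @param corpus Corpus tibble ([corpus_index()] / [read_corpus()]).
#' @param rif RIF tibble ([build_rif()] / [read_rif()]).
#' @param include,exclude Search terms (AND-combined) and exclusions.
#' @param matrices Named list of [similarity_matrix()] objects keyed by
#'   kind (may be empty).
#' @param k Unweighted drug set size, constrained to 20-200 here.
#' @param rank_by Drug-set ranking key.
#' @param top_n Predictions per matrix.
#' @param output_dir Directory for outputs (created if needed).
#' @param input_paths Optional named character vector of source file paths
#'   to checksum into the manifest.
#' @return Named character vector of output paths, invisibly. An empty
#'   query result writes an empty association table and warns (success,
#'   not an error).
#' @export
run_query <- function(corpus, rif, include, exclude = character(),
                      matrices = list(), k = 20L, rank_by = "score",
                      top_n = 20L, output_dir = ".",
                      input_paths = character()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pmids <- query_pmids(corpus, include, exclude)
  assoc <- associate(rif, pmids)
  paths <- c(association = file.path(output_dir, "association.tsv"),
             scatter = file.path(output_dir, "scatter.tsv"),
             drug_set = file.path(output_dir, "drug_set.txt"))
  write_association(assoc, paths[["association"]])
  write_scatter(assoc, paths[["scatter"]])
  ds <- if (nrow(assoc) > 0) {
    suppressWarnings(top_drug_set(assoc, k = k, rank_by = rank_by,
                                  enforce_range = TRUE))
  } else {
    character()
  }
  write_drug_set(ds, paths[["drug_set"]])
  for (kind in names(matrices)) {
    if (length(ds) >= 2) {
      pred <- augment(ds, matrices[[kind]], top_n = top_n, mode = "predict")
    } else {
      warn(sprintf("drug set too small to augment against '%s' matrix", kind))
      pred <- tibble(drug = character(), mean_similarity = double())
    }
    p <- file.path(output_dir, sprintf("predictions_%s.tsv", kind))
    write_predictions(pred, p)
    paths[[paste0("predictions_", kind)]] <- p
  }
  manifest <- list(
    package = "comention",
    version = as.character(utils::packageVersion("comention")),
    parameters = list(include = as.list(include), exclude = as.list(exclude),
                      k = k, rank_by = rank_by, top_n = top_n),
    n_pmids = length(pmids),
    n_associated = nrow(assoc),
    inputs = as.list(checksums(input_paths)),
    outputs = as.list(basename(paths))
  )
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["manifest"]] <- mp
  invisible(paths)
}

checksums <- function(paths) {
  if (length(paths) == 0) return(character())
  sums <- tools::md5sum(paths[file.exists(paths)])
  setNames(as.character(sums), basename(names(sums)))
}

#' Command-line interface
#'
#' Dispatcher behind the `exec/comention` Rscript. Subcommands:
#' `synthesize`, `query`, `augment`, `benchmark`, `build-rif`,
#' `build-matrix`. Run with no arguments (or `--help`) for usage. Errors
#' never escape: usage problems return exit code 2, runtime failures 1,
#' success (including empty query results) 0.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process's trailing arguments).
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    cli_dispatch(args)
    0L
  },
  comention_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_dispatch <- function(args) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage())
    return(invisible(NULL))
  }
  cmd <- args[1]
  rest <- args[-1]
  switch(cmd,
    "synthesize" = cli_synthesize(rest),
    "query" = cli_query(rest),
    "augment" = cli_augment(rest),
    "benchmark" = cli_benchmark(rest),
    "build-rif" = cli_build_rif(rest),
    "build-matrix" = cli_build_matrix(rest),
    abort(sprintf("unknown subcommand '%s'", cmd), class = "comention_usage_error")
  )
  invisible(NULL)
}

cli_usage <- function() {
  paste0(
    "comention -- literature co-mention drug ranking\n\n",
    "usage: comention <subcommand> [flags]\n\n",
    "subcommands:\n",
    "  synthesize  --out DIR [--seed N] [--n-drugs N] [--n-terms N] [--n-pmids N]\n",
    "              [--drugs-per-term N] [--p-planted X] [--p-background X]\n",
    "  query       --corpus FILE --rif FILE --term T [--term T ...]\n",
    "              [--exclude T ...] [--comention-matrix FILE] [--cosine-matrix FILE]\n",
    "              [--k N] [--rank-by score|count|fraction] [--top-n N] --out DIR\n",
    "  augment     --seed-set FILE --matrix FILE [--kind comention|cosine]\n",
    "              [--top-n N] --out FILE\n",
    "  benchmark   --library FILE.gmt --corpus FILE --rif FILE --matrix FILE\n",
    "              [--kind comention|cosine] [--k N] [--n-shuffles N] [--seed N]\n",
    "              --out DIR\n",
    "  build-rif   --pairs FILE --out FILE [--min-pmids N]\n",
    "  build-matrix --rif FILE --out FILE | --signatures FILE --out FILE\n"
  )
}

# tiny flag parser: --flag value pairs, repeatable flags collected
cli_flags <- function(args, repeatable = character()) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort(sprintf("unexpected argument '%s'", a), class = "comention_usage_error")
    }
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      abort(sprintf("flag --%s needs a value", key), class = "comention_usage_error")
    }
    val <- args[i + 1L]
    if (key %in% repeatable) {
      flags[[key]] <- c(flags[[key]], val)
    } else {
      flags[[key]] <- val
    }
    i <- i + 2L
  }
  flags
}

need_flag <- function(flags, key) {
  if (is.null(flags[[key]])) {
    abort(sprintf("missing required flag --%s", key), class = "comention_usage_error")
  }
  flags[[key]]
}

flag_int <- function(flags, key, default) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  as.integer(v)
}

flag_num <- function(flags, key, default) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  as.numeric(v)
}

cli_synthesize <- function(args) {
  f <- cli_flags(args)
  out <- need_flag(f, "out")
  cfg <- planted_world_config(
    n_drugs = flag_int(f, "n-drugs", 200L),
    n_terms = flag_int(f, "n-terms", 20L),
    n_pmids = flag_int(f, "n-pmids", 5000L),
    drugs_per_term = flag_int(f, "drugs-per-term", 10L),
    p_planted = flag_num(f, "p-planted", 0.3),
    p_background = flag_num(f, "p-background", 0.01),
    n_genes = flag_int(f, "n-genes", 100L),
    cluster_noise_sd = flag_num(f, "cluster-noise-sd", 0.5),
    rng_seed = flag_int(f, "seed", 0L)
  )
  world <- generate_world(cfg)
  paths <- write_world(world, out)
  inform(sprintf("wrote %d files to %s", length(paths), out))
}

cli_query <- function(args) {
  f <- cli_flags(args, repeatable = c("term", "exclude"))
  corpus <- read_corpus(need_flag(f, "corpus"))
  rif_path <- need_flag(f, "rif")
  rif <- read_rif(rif_path)
  matrices <- list()
  inputs <- c(corpus = f[["corpus"]], rif = rif_path)
  if (!is.null(f[["comention-matrix"]])) {
    matrices$comention <- read_similarity_matrix(f[["comention-matrix"]], "comention")
    inputs <- c(inputs, f[["comention-matrix"]])
  }
  if (!is.null(f[["cosine-matrix"]])) {
    matrices$cosine <- read_similarity_matrix(f[["cosine-matrix"]], "cosine")
    inputs <- c(inputs, f[["cosine-matrix"]])
  }
  run_query(
    corpus, rif,
    include = need_flag(f, "term"),
    exclude = f[["exclude"]] %||% character(),
    matrices = matrices,
    k = flag_int(f, "k", 20L),
    rank_by = f[["rank-by"]] %||% "score",
    top_n = flag_int(f, "top-n", 20L),
    output_dir = need_flag(f, "out"),
    input_paths = inputs
  )
  inform(sprintf("query outputs written to %s", f[["out"]]))
}

cli_augment <- function(args) {
  f <- cli_flags(args)
  seed_set <- read_drug_set(need_flag(f, "seed-set"))
  kind <- f[["kind"]] %||% "comention"
  m <- read_similarity_matrix(need_flag(f, "matrix"), kind)
  pred <- augment(seed_set, m, top_n = flag_int(f, "top-n", 20L), mode = "predict")
  write_predictions(pred, need_flag(f, "out"))
  inform(sprintf("wrote %d predictions to %s", nrow(pred), f[["out"]]))
}

cli_benchmark <- function(args) {
  f <- cli_flags(args)
  library <- read_gmt(need_flag(f, "library"))
  corpus <- read_corpus(need_flag(f, "corpus"))
  rif <- read_rif(need_flag(f, "rif"))
  kind <- f[["kind"]] %||% "comention"
  m <- read_similarity_matrix(need_flag(f, "matrix"), kind)
  res <- run_benchmark(
    library, rif, corpus, m,
    k = flag_int(f, "k", 20L),
    n_shuffles = flag_int(f, "n-shuffles", 10L),
    seed = flag_int(f, "seed", 1L)
  )
  out <- need_flag(f, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_benchmark(res,
                  report_path = file.path(out, "benchmark.tsv"),
                  summary_path = file.path(out, "summary.json"),
                  violin_path = file.path(out, "violin_data.tsv"))
  inform(sprintf("benchmark over %d terms written to %s", nrow(res$per_term), out))
}

cli_build_rif <- function(args) {
  f <- cli_flags(args)
  rif <- read_rif(need_flag(f, "pairs"), min_pmids = flag_int(f, "min-pmids", 2L))
  write_rif(rif, need_flag(f, "out"))
  inform(sprintf("rif with %d drugs written to %s",
                 dplyr::n_distinct(rif$drug), f[["out"]]))
}

cli_build_matrix <- function(args) {
  f <- cli_flags(args)
  if (!is.null(f[["rif"]])) {
    m <- comention_matrix(read_rif(f[["rif"]]))
  } else if (!is.null(f[["signatures"]])) {
    m <- cosine_matrix(read_signature_matrix(f[["signatures"]]))
  } else {
    abort("build-matrix needs --rif or --signatures", class = "comention_usage_error")
  }
  write_similarity_matrix(m, need_flag(f, "out"))
  inform(sprintf("%s matrix (%d drugs) written to %s",
                 matrix_kind(m), nrow(m), f[["out"]]))
}
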