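#' Configuration for a full co-occurrence pipeline run
#'
#' Exactly one input source must be given: a matrix file on disk
#' (\code{matrix_path}) or a synthetic \code{\link{generator_spec}}
#' (\code{spec}). Defaults follow the study's analysis settings: alpha
#' 0.05, expected-co-occurrence filter at 1, edge threshold 1 shared
#' sample, 1000 label permutations.
#'
#' @param matrix_path path to an incidence-matrix CSV/TSV.
#' @param metadata_path optional path to a taxon-metadata CSV.
#' @param spec a \code{\link{generator_spec}} (or path to one; see
#'   \code{\link{read_generator_spec}}).
#' @param alpha significance level for pair classification.
#' @param min_expected expected-co-occurrence exclusion threshold.
#' @param edge_threshold minimum shared samples for a network edge.
#' @param n_permutations modularity permutation count.
#' @param seed RNG seed driving generation and permutation.
#' @param out_dir output directory (created if missing).
#' @param format \code{"csv"} or \code{"tsv"} for tabular outputs.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(matrix_path = NULL, metadata_path = NULL, spec = NULL,
                       alpha = 0.05, min_expected = 1, edge_threshold = 1,
                       n_permutations = 1000, seed = NULL,
                       out_dir = "crustnet_out", format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (is.null(matrix_path) == is.null(spec)) {
    stop("provide exactly one of matrix_path or spec")
  }
  if (is.character(spec)) spec <- read_generator_spec(spec)
  if (!is.null(spec) && !inherits(spec, "generator_spec")) {
    stop("spec must be a generator_spec or a path to one")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_expected < 0) stop("min_expected must be non-negative")
  if (edge_threshold < 1) stop("edge_threshold must be >= 1")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(matrix_path = matrix_path, metadata_path = metadata_path,
                 spec = spec, alpha = alpha, min_expected = min_expected,
                 edge_threshold = edge_threshold,
                 n_permutations = n_permutations, seed = seed,
                 out_dir = out_dir, format = format),
            class = "run_config")
}

#' Run the full co-occurrence analysis pipeline
#'
#' Incidence matrix -> pairwise exact tests -> co-occurrence network ->
#' degree/betweenness/density/components/modularity -> modularity
#' permutation test, with all results written to the output directory:
#' \code{pairs.csv}, \code{edges.csv}, \code{network.gml},
#' \code{metrics.csv} and \code{summary.json}. Identical config and seed
#' give identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress progress messages (they go to standard error).
#' @return object of class \code{run_report}: the matrix, the
#'   \code{cooccurrence} fit, the network, its metrics, the permutation
#'   result, the summary list and the written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  sep <- if (config$format == "tsv") "\t" else ","
  ext <- config$format

  if (!is.null(config$matrix_path)) {
    say("reading incidence matrix: ", config$matrix_path)
    mat <- read_incidence_matrix(config$matrix_path, sep = sep)
  } else {
    say("generating incidence matrix from spec")
    mat <- generate_matrix(config$spec, seed = config$seed)
  }
  metadata <- if (!is.null(config$metadata_path)) {
    read_taxon_metadata(config$metadata_path)
  } else NULL

  say(sprintf("testing %d taxon pairs", choose(ncol(mat), 2)))
  fit <- cooccurrence_analysis(mat, alpha = config$alpha,
                               min_expected = config$min_expected)
  say("building co-occurrence network")
  net <- build_network(mat, min_shared_samples = config$edge_threshold)
  metrics <- network_metrics(net, metadata = metadata)
  perm <- if (igraph::ecount(net$graph) > 0) {
    say(sprintf("modularity permutation test (%d shuffles)",
                config$n_permutations))
    modularity_permutation_test(net, n_permutations = config$n_permutations,
                                seed = config$seed)
  } else NULL

  summary_list <- list(
    n_samples = nrow(mat),
    n_taxa = ncol(mat),
    pairs = as.list(fit$counts),
    alpha = config$alpha,
    min_expected = config$min_expected,
    edge_threshold = config$edge_threshold,
    n_edges = nrow(net$edges),
    density = metrics$density,
    n_components = metrics$n_components,
    n_large_modules = metrics$n_large_modules,
    modularity = metrics$modularity,
    permutation_p = if (!is.null(perm)) perm$p_value else NA,
    n_permutations = if (!is.null(perm)) perm$n_permutations else 0L,
    seed = if (is.null(config$seed)) NA else config$seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    pairs = file.path(config$out_dir, paste0("pairs.", ext)),
    edges = file.path(config$out_dir, paste0("edges.", ext)),
    gml = file.path(config$out_dir, "network.gml"),
    metrics = file.path(config$out_dir, paste0("metrics.", ext)),
    summary = file.path(config$out_dir, "summary.json"))
  write_pair_table(fit, files[["pairs"]], sep = sep)
  write_edge_list(net, files[["edges"]], sep = sep)
  write_network_gml(net, files[["gml"]])
  utils::write.table(metrics$nodes, files[["metrics"]], sep = sep,
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary_list, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  say("results written to ", config$out_dir)

  structure(list(matrix = mat, cooccurrence = fit, network = net,
                 metrics = metrics, permutation = perm,
                 summary = summary_list, files = files, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  summarize_run(x)
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param top_k how many top-degree / top-betweenness taxa to list.
#' @return the report, invisibly; the summary is printed.
#' @export
summarize_run <- function(report, top_k = 5) {
  stopifnot(inherits(report, "run_report"))
  s <- report$summary
  cat(sprintf("Co-occurrence pipeline: %d taxa in %d samples\n",
              s$n_taxa, s$n_samples))
  cat(sprintf("  pairs: %d total | %d positive, %d negative, %d random, %d excluded\n",
              s$pairs$total, s$pairs$positive, s$pairs$negative,
              s$pairs$random, s$pairs$excluded))
  cat(sprintf("  network: %d edges, density %.3f, %d component(s), %d module(s) > 2 taxa\n",
              s$n_edges, s$density, s$n_components, s$n_large_modules))
  cat(sprintf("  modularity (component partition): %s; permutation p = %s (%d shuffles)\n",
              format(s$modularity), format(s$permutation_p),
              s$n_permutations))
  nodes <- report$metrics$nodes
  k <- min(top_k, nrow(nodes))
  if (k > 0) {
    by_deg <- nodes[order(-nodes$degree), ][seq_len(k), ]
    by_btw <- nodes[order(-nodes$betweenness), ][seq_len(k), ]
    cat(sprintf("  top %d by degree: %s\n", k,
                paste(sprintf("%s (%d)", by_deg$taxon, by_deg$degree),
                      collapse = ", ")))
    cat(sprintf("  top %d by betweenness: %s\n", k,
                paste(sprintf("%s (%.2f)", by_btw$taxon, by_btw$betweenness),
                      collapse = ", ")))
  }
  invisible(report)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' Recognised keys mirror the \code{\link{run_config}} arguments; a
#' \code{spec} key may inline a generator spec (same structure as
#' \code{\link{read_generator_spec}}) or name a file.
#'
#' @param path config file path.
#' @param ... overrides applied on top of the file's values (e.g. from
#'   command-line flags).
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$spec) && !is.character(cfg$spec)) {
    planted <- cfg$spec$planted_pairs
    if (!is.null(planted) && !is.data.frame(planted)) {
      planted <- do.call(rbind, lapply(planted, as.data.frame,
                                       stringsAsFactors = FALSE))
    }
    cfg$spec <- generator_spec(cfg$spec$n_samples,
                               unlist(cfg$spec$taxon_incidences),
                               planted_pairs = planted, seed = cfg$spec$seed)
  }
  over <- list(...)
  cfg[names(over)] <- over
  keep <- intersect(names(cfg), names(formals(run_config)))
  do.call(run_config, cfg[keep])
}
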