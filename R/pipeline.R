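# End-to-end orchestration: network build, seed resolution, path mining,
# permutation significance, candidate selection, and the optional
# evaluation statistics, from a single validated configuration.

#' Assemble a pipeline configuration
#'
#' Collects input paths and the method's tunable constants. Defaults are the
#' study constants: 2000 permutation replicates, significance threshold
#' 0.05, background of 20000 protein-coding genes, no minimum interaction
#' score.
#'
#' @param edges Path to the STRING-style edge list.
#' @param mapping Path to the gene-to-protein mapping table.
#' @param seeds Path to the seed gene list (one symbol per line).
#' @param reference Optional path to a reference (cancer) gene list.
#' @param annotation Optional path to a gene-to-term annotation table.
#' @param min_score Minimum combined score kept when reading edges.
#' @param n_perm Number of permutation replicates.
#' @param alpha Selection threshold on the raw permutation p-value.
#' @param rng_seed Integer seed governing every random draw of the run.
#' @param background_n Background gene count for the overlap test.
#' @param out_dir Optional directory for stage outputs.
#' @param cost_transform `"linear"` (cost = 1000 - score) or a function.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edges, mapping, seeds, reference = NULL,
                            annotation = NULL, min_score = 0, n_perm = 2000,
                            alpha = 0.05, rng_seed = 1, background_n = 20000,
                            out_dir = NULL, cost_transform = "linear") {
  structure(list(edges = edges, mapping = mapping, seeds = seeds,
                 reference = reference, annotation = annotation,
                 min_score = min_score, n_perm = n_perm, alpha = alpha,
                 rng_seed = rng_seed, background_n = background_n,
                 out_dir = out_dir, cost_transform = cost_transform),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced input exists and every parameter is in its
#' valid range. Returns the problems rather than failing, so configurations
#' can be linted before a long run.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems, each naming the field and the
#'   violated constraint; empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  for (f in c("edges", "mapping", "seeds")) {
    v <- config[[f]]
    need(is.character(v) && length(v) == 1L && file.exists(v),
         sprintf("%s: required input path missing or nonexistent", f))
  }
  for (f in c("reference", "annotation")) {
    v <- config[[f]]
    if (!is.null(v))
      need(file.exists(v), sprintf("%s: path does not exist", f))
  }
  need(is.numeric(config$min_score) && config$min_score >= 0 &&
         config$min_score <= 999, "min_score: must be in [0, 999]")
  need(is.numeric(config$n_perm) && config$n_perm >= 1,
       "n_perm: must be a positive integer")
  need(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
       "alpha: must be in (0, 1)")
  need(is.numeric(config$rng_seed) && length(config$rng_seed) == 1L,
       "rng_seed: must be a single integer")
  need(is.numeric(config$background_n) && config$background_n >= 1,
       "background_n: must be a positive integer")
  need(is.function(config$cost_transform) ||
         identical(config$cost_transform, "linear"),
       "cost_transform: must be \"linear\" or a function")
  problems
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("[stage: %s] %s", stage, conditionMessage(e)), parent = e))
}

#' Run the full shortest-path gene prioritization pipeline
#'
#' Executes network build, seed resolution, all-pairs shortest-path mining,
#' path-occurrence betweenness, permutation significance, and candidate
#' selection; when a reference list and/or annotation are configured, also
#' the hypergeometric overlap test and the functional-profile similarity.
#' Identical configuration and inputs yield identical outputs; every stage
#' failure is reported with a stage label.
#'
#' @param config A `pipeline_config` (validated internally).
#' @return A `run_report`: per-stage counts, the candidate and selection
#'   tables, evaluation statistics, the configuration echo with a content
#'   hash, and the package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems) > 0L)
    abort(c("invalid pipeline configuration", problems))
  transform <- if (is.function(config$cost_transform)) config$cost_transform
               else confidence_to_cost
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  inform(sprintf("run config hash %s, rng_seed %d", cfg_hash,
                 as.integer(config$rng_seed)))

  network <- run_stage("build-network", {
    build_network(read_string_edges(config$edges, config$min_score),
                  cost_transform = transform)
  })
  resolution <- run_stage("resolve-seeds", {
    resolve_seed_proteins(read_gene_list(config$seeds),
                          read_gene_map(config$mapping), network)
  })
  path_set <- run_stage("mine-paths",
                        all_pairs_seed_paths(network, resolution))
  counts <- run_stage("betweenness", betweenness_counts(path_set))
  perm <- run_stage("permute", {
    permutation_pvalues(counts, network,
                        seed_size = length(resolution$proteins),
                        n_perm = config$n_perm, rng_seed = config$rng_seed)
  })
  selected <- run_stage("select", select_candidates(perm, config$alpha))
  gene_map <- read_gene_map(config$mapping)
  candidate_genes <- run_stage("select", {
    g <- gene_map$gene[match(selected$id, gene_map$protein)]
    sort(unique(ifelse(is.na(g), selected$id, g)))
  })

  overlap <- NULL
  if (!is.null(config$reference)) {
    overlap <- run_stage("overlap-test", {
      overlap_test(list(candidates = candidate_genes),
                   read_gene_list(config$reference),
                   background_n = config$background_n)
    })
  }
  similarity <- NULL
  if (!is.null(config$annotation) && !is.null(config$reference)) {
    similarity <- run_stage("profile-sim", {
      ann <- read_annotation(config$annotation)
      universe <- sort(unique(ann$term))
      p_cand <- build_profile(candidate_genes, ann, universe)
      p_ref <- build_profile(read_gene_list(config$reference), ann, universe)
      profile_similarity(p_cand, p_ref)
    })
  }

  report <- structure(list(
    n_nodes = length(network$nodes), n_edges = nrow(network$edges),
    n_seed_genes = length(unique(resolution$mapping$gene)),
    n_seed_proteins = length(resolution$proteins),
    n_paths = nrow(path_set$paths), n_skipped = nrow(path_set$skipped),
    n_path_genes = nrow(counts), n_selected = nrow(selected),
    betweenness = counts, permutation = perm, selected = selected,
    candidate_genes = candidate_genes, overlap = overlap,
    profile_similarity = similarity,
    config = config, config_hash = cfg_hash,
    version = as.character(utils::packageVersion("pathbetween"))
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    run_stage("write-outputs", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_network_edges(network, file.path(config$out_dir, "network.tsv"))
      write_paths(path_set, file.path(config$out_dir, "paths.tsv"))
      write_betweenness(counts, file.path(config$out_dir, "betweenness.tsv"))
      write_permutation(perm, file.path(config$out_dir, "permutation.tsv"))
      readr::write_tsv(selected, file.path(config$out_dir, "selected.tsv"))
      readr::write_lines(candidate_genes,
                         file.path(config$out_dir, "candidate_genes.txt"))
      if (!is.null(overlap))
        readr::write_tsv(overlap, file.path(config$out_dir, "overlap.tsv"))
    })
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  network: %d proteins, %d interactions\n", x$n_nodes, x$n_edges))
  cat(sprintf("  seeds: %d genes -> %d proteins; %d paths (%d pairs skipped)\n",
              x$n_seed_genes, x$n_seed_proteins, x$n_paths, x$n_skipped))
  cat(sprintf("  path genes: %d; selected at alpha %.3g: %d\n",
              x$n_path_genes, x$config$alpha, x$n_selected))
  if (!is.null(x$overlap))
    cat(sprintf("  overlap with reference: %d/%d, p = %.4g\n",
                x$overlap$overlap[1], x$overlap$n[1], x$overlap$p_value[1]))
  if (!is.null(x$profile_similarity))
    cat(sprintf("  profile similarity vs reference: %.4f\n", x$profile_similarity))
  cat(sprintf("  config hash %s (rng_seed %d), pathbetween %s\n",
              x$config_hash, as.integer(x$config$rng_seed), x$version))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
glance.run_report <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
         n_seed_proteins = x$n_seed_proteins, n_paths = x$n_paths,
         n_skipped = x$n_skipped, n_path_genes = x$n_path_genes,
         n_selected = x$n_selected,
         overlap_p = if (is.null(x$overlap)) NA_real_ else x$overlap$p_value[1],
         profile_similarity = x$profile_similarity %||% NA_real_)
}
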