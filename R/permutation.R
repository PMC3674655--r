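# Empirical significance of path-occurrence betweenness by permutation over
# random seed sets of equal size.

#' Permutation p-values for path-occurrence betweenness
#'
#' For each replicate, a random seed set of the same size as the observed one
#' is drawn uniformly without replacement from the sampling universe, all
#' seed-pair shortest paths are mined, and every candidate's path-occurrence
#' count is recomputed. A candidate's p-value is the proportion of replicates
#' whose count STRICTLY exceeds the observed count (no pseudocount), so
#' `p = 0` is attainable and should be read as `< 1/n_perm`. Unreachable
#' pairs are skipped in replicates exactly as in the observed run, and a
#' candidate drawn as a replicate seed scores zero in that replicate (seed
#' nodes are excluded from the tally, matching [betweenness_counts()]).
#'
#' A Benjamini-Hochberg adjusted column is included as supplementary output;
#' candidate selection by [select_candidates()] uses the raw p-value.
#'
#' @param candidates A `betweenness_table` (tibble with `id`, `count`) of
#'   observed counts.
#' @param network The `ppi_network` the counts were mined from.
#' @param seed_size Number of seeds per replicate (the observed seed count).
#' @param n_perm Number of replicates (default 2000).
#' @param rng_seed Optional integer; when given, results are fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param universe Optional character vector of nodes to sample seeds from;
#'   defaults to all network nodes. The observed seeds are not excluded
#'   unless `exclude` is supplied.
#' @param exclude Optional character vector of nodes removed from the
#'   sampling universe (e.g. the observed seeds).
#' @param replicate_sets Optional list of explicit seed sets (character
#'   vectors) used INSTEAD of random sampling — handy for exhaustive
#'   enumeration on small graphs; overrides `n_perm`.
#' @return A `perm_result` tibble: `id`, `observed`, `exceed`, `p_value`,
#'   `p_bh`, with attributes `n_perm`, `seed_size`, `universe_size`,
#'   `rng_seed`.
#' @export
permutation_pvalues <- function(candidates, network, seed_size,
                                n_perm = 2000, rng_seed = NULL,
                                universe = NULL, exclude = NULL,
                                replicate_sets = NULL) {
  stopifnot(is.data.frame(candidates), inherits(network, "ppi_network"))
  if (nrow(candidates) == 0L) abort("`candidates` is empty.")
  cand_ids <- node_ids(network, candidates$id, "candidates")
  observed <- as.integer(candidates$count)

  if (is.null(replicate_sets)) {
    seed_size <- check_count(seed_size, "seed_size", min = 2L)
    n_perm <- check_count(n_perm, "n_perm", min = 1L)
    universe <- universe %||% network$nodes
    if (!is.null(exclude)) universe <- setdiff(universe, exclude)
    uni_ids <- node_ids(network, universe, "universe")
    if (length(uni_ids) < seed_size)
      abort("`seed_size` exceeds the sampling universe.")
    run <- function() cpp_permutation_exceed(
      network$ptr, network$nbr, network$wt,
      as.integer(uni_ids - 1L), seed_size, n_perm,
      as.integer(cand_ids - 1L), observed)
    exceed <- if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
    universe_size <- length(uni_ids)
  } else {
    n_perm <- length(replicate_sets)
    if (n_perm == 0L) abort("`replicate_sets` is empty.")
    exceed <- integer(nrow(candidates))
    for (s in replicate_sets) {
      ps <- suppressMessages(all_pairs_seed_paths(network, s))
      b <- betweenness_counts(ps, include_seeds = FALSE)
      rep_counts <- b$count[match(candidates$id, b$id)]
      rep_counts[is.na(rep_counts)] <- 0L
      exceed <- exceed + (rep_counts > observed)
    }
    seed_size <- length(replicate_sets[[1]])
    universe_size <- NA_integer_
  }

  p <- exceed / n_perm
  out <- tibble(id = candidates$id, observed = observed,
                exceed = as.integer(exceed), p_value = p,
                p_bh = p.adjust(p, method = "BH"))
  new_tbl_subclass(out, "perm_result", n_perm = n_perm, seed_size = seed_size,
                   universe_size = universe_size, rng_seed = rng_seed)
}

#' Select significant candidate genes
#'
#' Keeps candidates with permutation p-value strictly below `alpha` (the raw
#' cutoff used by the method; no multiplicity correction), sorted by p-value
#' ascending, then observed count descending, then identifier.
#'
#' @param result A `perm_result` from [permutation_pvalues()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @return A tibble of selected rows.
#' @export
select_candidates <- function(result, alpha = 0.05) {
  stopifnot(is.data.frame(result))
  alpha <- check_prob(alpha, "alpha")
  as_tibble(result) |>
    filter(.data$p_value < alpha) |>
    arrange(.data$p_value, desc(.data$observed), .data$id)
}

#' @rdname permutation_pvalues
#' @param x A `perm_result`.
#' @param ... Unused.
#' @export
tidy.perm_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "perm_result")
  out
}

#' @rdname permutation_pvalues
#' @export
glance.perm_result <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_perm = attr(x, "n_perm"),
         seed_size = attr(x, "seed_size"),
         min_p = min(x$p_value),
         n_selected_05 = sum(x$p_value < 0.05))
}

#' @rdname permutation_pvalues
#' @param object A `perm_result`.
#' @param alpha Significance threshold drawn on the plot.
#' @export
autoplot.perm_result <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$observed, y = .data$p_value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "observed path-occurrence betweenness",
                  y = "permutation p-value",
                  title = sprintf("Permutation test (%d replicates)",
                                  attr(object, "n_perm")))
}

#' Write a permutation result as tab-separated text
#'
#' Columns: id, observed betweenness, strict-exceedance count, permutation
#' p-value, BH-adjusted p-value.
#'
#' @param result A `perm_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_permutation <- function(result, file) {
  readr::write_tsv(as_tibble(result), file)
  invisible(file)
}
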