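# Shortest-path mining between seed proteins and the path-occurrence
# betweenness tally.

#' Minimum-cost path between two proteins
#'
#' Dijkstra shortest path under the network's edge costs. Among equal-cost
#' optima the lexicographically smallest node sequence (under sorted protein
#' identifiers) is returned, so results are fully deterministic.
#'
#' @param network A `ppi_network`.
#' @param source,target Protein identifiers (network nodes).
#' @return A one-row tibble with columns `source`, `target`, `cost` and a
#'   list-column `path` holding the node sequence, or `NULL` when `target`
#'   is unreachable from `source`.
#' @export
dijkstra_path <- function(network, source, target) {
  stopifnot(inherits(network, "ppi_network"))
  s <- node_ids(network, source, "source")
  t <- node_ids(network, target, "target")
  if (s == t)
    return(tibble(source = source, target = target, cost = 0,
                  path = list(source)))
  dist_t <- cpp_dijkstra_dist(network$ptr, network$nbr, network$wt, t - 1L)
  p <- cpp_reconstruct(network$ptr, network$nbr, network$wt, s - 1L, t - 1L, dist_t)
  if (length(p) == 0L) return(NULL)
  tibble(source = source, target = target, cost = dist_t[s],
         path = list(network$nodes[p + 1L]))
}

#' Mine shortest paths between all pairs of seed proteins
#'
#' Computes one minimum-cost path per unordered pair of seed proteins
#' (deterministic lexicographic tie-break), recording unreachable pairs
#' separately rather than failing: genome-scale interaction networks can be
#' disconnected.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed protein identifiers (>= 2, all
#'   network nodes), or a `seed_resolution` from [resolve_seed_proteins()].
#' @return A `shortest_path_set`: `paths` (tibble `source`, `target`, `cost`,
#'   list-column `path`), `skipped` (tibble of unreachable pairs), `seeds`.
#'   `nrow(paths) + nrow(skipped)` always equals `choose(length(seeds), 2)`.
#' @export
all_pairs_seed_paths <- function(network, seeds) {
  stopifnot(inherits(network, "ppi_network"))
  if (inherits(seeds, "seed_resolution")) seeds <- seeds$proteins
  seeds <- sort(unique(as.character(seeds)))
  if (length(seeds) < 2L) abort("need at least 2 distinct seed proteins")
  ids <- node_ids(network, seeds, "seeds")
  res <- cpp_all_pairs_paths(network$ptr, network$nbr, network$wt,
                             as.integer(sort(ids) - 1L))
  all_pairs <- tibble(
    source = network$nodes[res$source + 1L],
    target = network$nodes[res$target + 1L],
    cost = res$cost,
    path = lapply(res$paths, function(p) network$nodes[p + 1L])
  )
  ok <- !is.na(all_pairs$cost)
  skipped <- all_pairs[!ok, c("source", "target")]
  if (nrow(skipped) > 0L)
    inform(sprintf("%d unreachable seed pair(s) skipped.", nrow(skipped)))
  structure(list(paths = all_pairs[ok, ], skipped = skipped, seeds = seeds),
            class = "shortest_path_set")
}

#' @export
print.shortest_path_set <- function(x, ...) {
  cat(sprintf("<shortest_path_set> %d seeds, %d paths, %d unreachable pair(s)\n",
              length(x$seeds), nrow(x$paths), nrow(x$skipped)))
  invisible(x)
}

#' Path-occurrence betweenness of genes on mined shortest paths
#'
#' For every node, counts the mined seed-pair shortest paths on whose
#' interior (endpoints excluded) it lies. This path-occurrence tally is the
#' ranking statistic of the method — not classical normalized betweenness
#' centrality. With `include_seeds = FALSE` (default) seed nodes are removed
#' from the returned table, so it lists candidate "path genes" only.
#'
#' @param path_set A `shortest_path_set` from [all_pairs_seed_paths()].
#' @param include_seeds Keep seed nodes in the table? Default `FALSE`.
#' @return A `betweenness_table`: tibble with columns `id`, `count`, sorted
#'   by count descending then id, one row per node occurring on at least one
#'   path interior.
#' @export
betweenness_counts <- function(path_set, include_seeds = FALSE) {
  stopifnot(inherits(path_set, "shortest_path_set"))
  interior <- unlist(lapply(path_set$paths$path,
                            function(p) p[-c(1L, length(p))]),
                     use.names = FALSE)
  out <- if (length(interior) == 0L)
    tibble(id = character(), count = integer())
  else {
    tab <- table(interior)
    tibble(id = names(tab), count = as.integer(tab))
  }
  if (!include_seeds) out <- filter(out, !(.data$id %in% path_set$seeds))
  out <- arrange(out, desc(.data$count), .data$id)
  new_tbl_subclass(out, "betweenness_table",
                   seeds = path_set$seeds, n_paths = nrow(path_set$paths),
                   include_seeds = include_seeds)
}

#' Collapse a protein-level betweenness table to gene symbols
#'
#' Maps protein identifiers back through the gene-to-protein table, keeping
#' the maximum count per gene when a gene maps to several proteins.
#'
#' @param counts A `betweenness_table` (or tibble with `id`, `count`).
#' @param map Gene-to-protein tibble (columns `gene`, `protein`).
#' @return Tibble with columns `gene`, `count`, sorted by count descending.
#' @export
collapse_to_genes <- function(counts, map) {
  stopifnot(is.data.frame(counts), is.data.frame(map))
  joined <- dplyr::inner_join(as_tibble(counts), map,
                              by = c(id = "protein"),
                              relationship = "many-to-many")
  joined |>
    group_by(.data$gene) |>
    summarise(count = max(.data$count), .groups = "drop") |>
    arrange(desc(.data$count), .data$gene)
}

#' Write mined paths as tab-separated text
#'
#' One row per path: `source`, `target`, `cost`, and the node sequence
#' joined by `"|"`.
#'
#' @param path_set A `shortest_path_set`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_paths <- function(path_set, file) {
  stopifnot(inherits(path_set, "shortest_path_set"))
  out <- mutate(path_set$paths,
                path = vapply(.data$path, paste, "", collapse = "|"))
  readr::write_tsv(out, file)
  invisible(file)
}

#' Write a betweenness table as tab-separated text
#'
#' @param counts A `betweenness_table` or any tibble with `id`, `count`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_betweenness <- function(counts, file) {
  readr::write_tsv(as_tibble(counts), file)
  invisible(file)
}

#' @rdname betweenness_counts
#' @param object,x A `betweenness_table`.
#' @param top_n Number of top-ranked genes shown by `autoplot`.
#' @param ... Unused.
#' @export
autoplot.betweenness_table <- function(object, top_n = 20, ...) {
  df <- head(as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$id, .data$count),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "shortest-path occurrence count",
                  title = "Path-occurrence betweenness")
}

#' Fast path-occurrence tally for a single seed set
#'
#' Computes the same interior-occurrence counts as
#' `betweenness_counts(all_pairs_seed_paths(network, seeds))` without
#' materialising the paths — the tally the permutation engine uses
#' internally. Useful for calibration and simulation loops where only the
#' counts matter.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed protein identifiers (>= 2).
#' @param include_seeds Keep seed nodes in the table? Default `FALSE`.
#' @return A `betweenness_table` tibble (`id`, `count`), as from
#'   [betweenness_counts()].
#' @export
betweenness_for_seeds <- function(network, seeds, include_seeds = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  seeds <- sort(unique(as.character(seeds)))
  if (length(seeds) < 2L) abort("need at least 2 distinct seed proteins")
  ids <- node_ids(network, seeds, "seeds")
  cnt <- cpp_seed_counts(network$ptr, network$nbr, network$wt,
                         as.integer(ids - 1L))
  out <- tibble(id = network$nodes, count = as.integer(cnt)) |>
    filter(.data$count > 0L)
  if (!include_seeds) out <- filter(out, !(.data$id %in% seeds))
  out <- arrange(out, desc(.data$count), .data$id)
  new_tbl_subclass(out, "betweenness_table", seeds = seeds,
                   n_paths = NA_integer_, include_seeds = include_seeds)
}
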