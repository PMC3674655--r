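# Synthetic study generator: weighted scale-free-like networks, planted
# connector structure, gene-protein maps, annotations and reference lists,
# so every pipeline stage is testable without external downloads.

#' Generate a weighted interaction network
#'
#' Background topology is a connected preferential-attachment graph (PPI
#' degree distributions are heavy-tailed); an Erdos-Renyi alternative is
#' included for null calibration. Each edge receives an integer confidence
#' score drawn from `score_distribution`, by default uniform on 150-999
#' (STRING's practical range above its common 150 floor).
#'
#' @param n_nodes Number of proteins (>= 10).
#' @param edges_per_node Attachment edges per added node (>= 1); `1` yields
#'   a tree.
#' @param score_distribution Function of one argument `n` returning `n`
#'   integer scores in `[1, 999]`.
#' @param rng_seed Integer seed; the generator is a pure function of its
#'   parameters and this seed.
#' @param model `"pa"` (preferential attachment, connected) or `"er"`
#'   (Erdos-Renyi with `n_nodes * edges_per_node` edges, not necessarily
#'   connected).
#' @return A `ppi_network` with nodes named `P0001`, `P0002`, ...
#' @export
generate_network <- function(n_nodes, edges_per_node = 3,
                             score_distribution = NULL, rng_seed = 1,
                             model = c("pa", "er")) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 10L)
  edges_per_node <- check_count(edges_per_node, "edges_per_node", min = 1L)
  model <- match.arg(model)
  score_distribution <- score_distribution %||%
    function(n) sample(150:999, n, replace = TRUE)
  withr::with_seed(rng_seed, {
    g <- if (model == "pa")
      igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
    else
      igraph::sample_gnm(n_nodes, m = n_nodes * edges_per_node, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    nodes <- sprintf("P%04d", seq_len(n_nodes))
    scores <- as.integer(score_distribution(nrow(el)))
    if (any(scores < 1L) || any(scores > 999L))
      abort("`score_distribution` must return scores in [1, 999].")
    edges <- tibble(protein_a = nodes[el[, 1]], protein_b = nodes[el[, 2]],
                    score = scores)
    build_network(edges)
  })
}

#' Plant high-confidence connector nodes between random seeds
#'
#' Selects disjoint seed and connector protein sets, wires every connector
#' to `ceiling(attach_fraction * n_seeds)` random seeds with maximal
#' confidence (score 999, cost 1), so connectors come to lie on many
#' seed-pair shortest paths — the planted ground truth for recovery
#' experiments. A gene-protein map is generated alongside: every protein
#' gets a gene symbol, and when `n_seed_genes < n_seeds` some seed genes map
#' to two proteins (one-to-many mapping, as real symbol-to-protein tables
#' have).
#'
#' @param network A `ppi_network` to plant into.
#' @param n_seeds Number of seed proteins.
#' @param n_connectors Number of planted connectors (0 gives a null
#'   scenario with an empty truth set).
#' @param attach_fraction Fraction of seeds each connector is wired to,
#'   in (0, 1].
#' @param rng_seed Integer seed.
#' @param n_seed_genes Number of seed gene symbols; defaults to `n_seeds`
#'   (one-to-one). Smaller values make the first
#'   `n_seeds - n_seed_genes` seed genes map to two proteins each.
#' @param connector_score Confidence score of planted edges (default 999).
#' @param cost_transform Passed to [build_network()] when rebuilding.
#' @return A `synthetic_scenario`: `network` (with planted edges),
#'   `gene_map`, `seeds` (gene symbols), `seed_proteins`, `true_connectors`
#'   (protein ids), `generator_params`.
#' @export
plant_connectors <- function(network, n_seeds, n_connectors,
                             attach_fraction = 0.5, rng_seed = 1,
                             n_seed_genes = n_seeds, connector_score = 999,
                             cost_transform = confidence_to_cost) {
  stopifnot(inherits(network, "ppi_network"))
  n_seeds <- check_count(n_seeds, "n_seeds", min = 2L)
  n_connectors <- check_count(n_connectors, "n_connectors")
  n_seed_genes <- check_count(n_seed_genes, "n_seed_genes", min = 1L)
  if (n_seed_genes > n_seeds || n_seed_genes < ceiling(n_seeds / 2))
    abort("`n_seed_genes` must be in [ceiling(n_seeds/2), n_seeds].")
  if (!is.numeric(attach_fraction) || attach_fraction <= 0 || attach_fraction > 1)
    abort("`attach_fraction` must be in (0, 1].")
  nodes <- network$nodes
  if (n_seeds + n_connectors > length(nodes))
    abort("`n_seeds` + `n_connectors` exceeds the node count.")

  withr::with_seed(rng_seed, {
    seeds <- sort(sample(nodes, n_seeds))
    connectors <- sort(sample(setdiff(nodes, seeds), n_connectors))
    k_attach <- as.integer(ceiling(attach_fraction * n_seeds))
    planted <- purrr::map_dfr(connectors, function(cn) {
      tibble(protein_a = cn, protein_b = sample(seeds, k_attach),
             score = as.integer(connector_score))
    })
    # planted edges override any existing edge on the same pair
    edges <- canonicalize_edges(dplyr::bind_rows(network$edges[, 1:3], planted))
    if (nrow(planted) > 0L) {
      pl <- canonicalize_edges(planted)
      key <- paste(edges$protein_a, edges$protein_b)
      edges$score[key %in% paste(pl$protein_a, pl$protein_b)] <-
        as.integer(connector_score)
    }
    net <- build_network(edges, cost_transform = cost_transform)

    # gene symbols: seed proteins get SG genes (possibly 2 proteins per
    # gene), every other protein its own G gene
    n_multi <- n_seeds - n_seed_genes
    gene_of_seed <- c(rep(seq_len(n_multi), each = 2L),
                      seq.int(n_multi + 1L, length.out = n_seed_genes - n_multi))
    seed_genes <- sprintf("SG%03d", gene_of_seed)
    others <- setdiff(net$nodes, seeds)
    gene_map <- dplyr::bind_rows(
      tibble(gene = seed_genes, protein = seeds),
      tibble(gene = sprintf("G%05d", seq_along(others)), protein = others)
    )
    structure(list(
      network = net,
      gene_map = gene_map,
      seeds = unique(seed_genes),
      seed_proteins = seeds,
      true_connectors = connectors,
      generator_params = list(n_nodes = length(net$nodes), n_seeds = n_seeds,
                              n_connectors = n_connectors,
                              attach_fraction = attach_fraction,
                              n_seed_genes = n_seed_genes,
                              connector_score = connector_score,
                              rng_seed = rng_seed)
    ), class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario> %d proteins, %d seed genes ",
                     "(%d proteins), %d planted connector(s)\n"),
              length(x$network$nodes), length(x$seeds),
              length(x$seed_proteins), length(x$true_connectors)))
  invisible(x)
}

#' Generate a gene-to-term annotation with planted enrichment
#'
#' Assigns each gene `terms_per_gene` random terms; for every designated
#' enriched set, a dedicated block of `block_size` terms is additionally
#' assigned to its members with probability `enrich_prob`, so profile
#' construction can detect the planted signal. Block terms also receive
#' background assignments, keeping their enrichment statistics
#' non-degenerate.
#'
#' @param genes Character vector of gene identifiers.
#' @param n_terms Total number of terms (>= 1), named `T0001`, ...
#' @param terms_per_gene Random terms per gene (0 allowed).
#' @param enriched_sets List of character vectors (subsets of `genes`), each
#'   receiving its own enriched term block.
#' @param block_size Terms per enriched block.
#' @param enrich_prob Probability a set member receives each block term.
#' @param rng_seed Integer seed.
#' @return A tibble with columns `gene`, `term` (distinct rows).
#' @export
generate_annotation <- function(genes, n_terms, terms_per_gene = 3,
                                enriched_sets = list(), block_size = 5,
                                enrich_prob = 0.9, rng_seed = 1) {
  n_terms <- check_count(n_terms, "n_terms", min = 1L)
  terms_per_gene <- check_count(terms_per_gene, "terms_per_gene")
  terms <- sprintf("T%04d", seq_len(n_terms))
  n_block <- length(enriched_sets) * block_size
  if (n_block > n_terms)
    abort("not enough terms for the requested enriched blocks")
  withr::with_seed(rng_seed, {
    base <- if (terms_per_gene > 0L)
      purrr::map_dfr(genes, function(g)
        tibble(gene = g, term = sample(terms, min(terms_per_gene, n_terms))))
    else
      tibble(gene = character(), term = character())
    planted <- purrr::imap_dfr(enriched_sets, function(set, i) {
      block <- terms[seq.int(n_terms - n_block + (i - 1L) * block_size + 1L,
                             length.out = block_size)]
      grid <- tidyr::expand_grid(gene = set, term = block)
      grid[stats::runif(nrow(grid)) < enrich_prob, ]
    })
    distinct(dplyr::bind_rows(base, planted)) |>
      arrange(.data$gene, .data$term)
  })
}

#' Generate a reference gene list with controlled overlap
#'
#' Draws exactly `size` genes from `universe`, of which exactly `n_overlap`
#' fall inside `overlap_with` — the shape of a curated cancer-gene list with
#' a known overlap against a candidate set.
#'
#' @param universe Character vector to draw from.
#' @param size List size.
#' @param overlap_with Gene set the overlap is controlled against.
#' @param n_overlap Exact overlap with `overlap_with`.
#' @param rng_seed Integer seed.
#' @return Character vector of `size` genes, sorted.
#' @export
generate_reference_list <- function(universe, size, overlap_with = character(),
                                    n_overlap = 0, rng_seed = 1) {
  size <- check_count(size, "size", min = 1L)
  n_overlap <- check_count(n_overlap, "n_overlap")
  universe <- unique(universe)
  inside <- intersect(universe, overlap_with)
  outside <- setdiff(universe, overlap_with)
  if (n_overlap > min(size, length(inside)))
    abort("`n_overlap` exceeds the achievable overlap")
  if (size - n_overlap > length(outside))
    abort("not enough genes outside `overlap_with` for the requested size")
  withr::with_seed(rng_seed, {
    sort(c(sample(inside, n_overlap), sample(outside, size - n_overlap)))
  })
}

#' Write a synthetic scenario in the pipeline's file dialects
#'
#' Emits the edge list, gene map, seed gene list, planted-connector list,
#' plus (when attached to the scenario) a reference list and annotation, and
#' a plain-text parameters manifest for provenance.
#'
#' @param scenario A `synthetic_scenario`; it may carry optional
#'   `cancer_reference` (character) and `annotation` (tibble) elements.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    edges = file.path(dir, "edges.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    seeds = file.path(dir, "seeds.txt"),
    connectors = file.path(dir, "true_connectors.txt"),
    manifest = file.path(dir, "params_manifest.txt")
  )
  write_network_edges(scenario$network, p$edges)
  readr::write_tsv(scenario$gene_map, p$gene_map, col_names = FALSE)
  readr::write_lines(scenario$seeds, p$seeds)
  readr::write_lines(scenario$true_connectors, p$connectors)
  if (!is.null(scenario$cancer_reference)) {
    p$reference <- file.path(dir, "reference.txt")
    readr::write_lines(scenario$cancer_reference, p$reference)
  }
  if (!is.null(scenario$annotation)) {
    p$annotation <- file.path(dir, "annotation.tsv")
    readr::write_tsv(scenario$annotation, p$annotation, col_names = FALSE)
  }
  gp <- scenario$generator_params
  readr::write_lines(paste0(names(gp), ": ", unlist(gp)), p$manifest)
  invisible(p)
}
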