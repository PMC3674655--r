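# Weighted PPI network construction from STRING-style interaction tables.

canonicalize_edges <- function(edges) {
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  tibble(protein_a = a, protein_b = b, score = as.integer(edges$score)) |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$protein_a, .data$protein_b)
}

#' Read a STRING-style interaction edge list
#'
#' Parses a whitespace- or tab-separated table with columns
#' `protein1 protein2 combined_score` (a header row is auto-detected), where
#' the combined score is an integer interaction confidence on STRING's 1-999
#' scale. Edges are canonicalized to sorted endpoint order; duplicate pairs
#' (STRING dumps list both orientations) keep the maximum score; self-loops
#' are dropped with a message.
#'
#' @param file Path to the edge-list file, a connection, or literal text
#'   wrapped in [I()].
#' @param min_score Minimum combined score to keep (default 0: no filtering).
#' @return A tibble with columns `protein_a`, `protein_b`, `score`, one row
#'   per unordered protein pair, sorted.
#' @examples
#' read_string_edges(I("A\tB\t700\nB\tA\t400\nC\tC\t900"))
#' @export
read_string_edges <- function(file, min_score = 0) {
  min_score <- check_count(min_score, "min_score")
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(tibble(protein_a = character(), protein_b = character(),
                  score = integer()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  # header row: recognised column names, never silently skipped data
  has_header <- any(grepl("^(protein|node|gene|source|target|item)",
                          fields[[1]][1:2], ignore.case = TRUE)) ||
    grepl("score|weight|conf", fields[[1]][min(3L, length(fields[[1]]))],
          ignore.case = TRUE)
  if (has_header) {
    fields <- fields[-1]
    lines <- lines[-1]
  }
  offset <- if (has_header) 1L else 0L
  nf <- lengths(fields)
  if (any(nf < 3L))
    abort(sprintf("malformed edge row (fewer than 3 columns) at line %d",
                  which(nf < 3L)[1] + offset))
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s_chr <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_chr))
  bad <- is.na(s) | s != trunc(s)
  if (any(bad))
    abort(sprintf("cannot parse integer score %s at line %d",
                  dQuote(s_chr[bad][1]), which(bad)[1] + offset))
  out_of_range <- s < 1 | s > 999
  if (any(out_of_range))
    abort(sprintf("score %d at line %d outside the STRING confidence range [1, 999]",
                  as.integer(s[out_of_range][1]), which(out_of_range)[1] + offset))
  edges <- tibble(protein_a = a, protein_b = b, score = as.integer(s))
  n_loops <- sum(edges$protein_a == edges$protein_b)
  if (n_loops > 0L) {
    inform(sprintf("Dropped %d self-loop(s).", n_loops))
    edges <- filter(edges, .data$protein_a != .data$protein_b)
  }
  edges <- canonicalize_edges(edges)
  filter(edges, .data$score >= min_score)
}

#' Convert a STRING confidence score to a traversal cost
#'
#' The default edge weight used throughout the package: `cost = 1000 - score`,
#' mapping the 1-999 confidence scale onto strictly positive integer costs so
#' that stronger interactions are cheaper to traverse (the smaller the weight,
#' the stronger the interaction). Strictly decreasing in the score.
#'
#' @param score Integer vector of confidence scores in `[1, 999]`.
#' @return Numeric vector of positive traversal costs.
#' @examples
#' confidence_to_cost(c(999, 500, 1))
#' @export
confidence_to_cost <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score != trunc(score)) ||
      any(score < 1) || any(score > 999))
    abort("`score` must be integer(s) in [1, 999].")
  1000 - as.numeric(score)
}

#' Build a weighted PPI network from a canonical edge table
#'
#' Nodes are the union of edge endpoints; each edge carries a traversal cost
#' derived from its confidence score. Internally the adjacency is stored in
#' compressed sparse form with neighbour lists sorted by protein identifier,
#' which fixes the deterministic tie-break used by the path miner.
#'
#' @param edges Tibble with columns `protein_a`, `protein_b`, `score`, as
#'   returned by [read_string_edges()]. Non-canonical input is canonicalized.
#' @param cost_transform Function mapping scores to strictly positive costs;
#'   defaults to [confidence_to_cost()].
#' @return A `ppi_network` object.
#' @examples
#' net <- build_network(read_string_edges(I("A\tB\t999\nB\tC\t999\nA\tC\t100")))
#' net
#' @export
build_network <- function(edges, cost_transform = confidence_to_cost) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    warn("Building an empty network from an empty edge list.")
    edges2 <- tibble(protein_a = character(), protein_b = character(),
                     score = integer(), cost = numeric())
    return(new_ppi_network(character(), edges2))
  }
  edges <- canonicalize_edges(edges)
  cost <- cost_transform(edges$score)
  if (any(!is.finite(cost)) || any(cost <= 0))
    abort("`cost_transform` must yield strictly positive finite costs.")
  new_ppi_network(sort(unique(c(edges$protein_a, edges$protein_b))),
                  mutate(edges, cost = cost))
}

new_ppi_network <- function(nodes, edges) {
  n <- length(nodes)
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  # symmetric CSR; neighbours sorted ascending within each node
  from <- c(ia, ib)
  to <- c(ib, ia)
  w <- rep(edges$cost, 2L)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  deg <- tabulate(from, nbins = max(n, 1L))
  if (n == 0L) deg <- integer(0)
  ptr <- c(0L, cumsum(deg))
  structure(list(nodes = nodes, edges = edges,
                 ptr = as.integer(ptr), nbr = as.integer(to - 1L),
                 wt = as.numeric(w)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L)
    cat(sprintf("  scores %d-%d, costs %g-%g\n",
                min(x$edges$score), max(x$edges$score),
                min(x$edges$cost), max(x$edges$cost)))
  invisible(x)
}

#' Export a network as a canonical edge list
#'
#' Writes `node_a node_b score cost` as sorted tab-separated text, suitable
#' for reproducible diffing and for re-reading with [read_string_edges()].
#'
#' @param network A `ppi_network`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network_edges <- function(network, file) {
  stopifnot(inherits(network, "ppi_network"))
  readr::write_tsv(network$edges, file, col_names = TRUE)
  invisible(file)
}

#' Read a gene-to-protein identifier mapping
#'
#' Two-column tab-separated text, gene symbol then protein identifier, one
#' row per mapping; genes may map to several proteins (repeated rows).
#'
#' @param file Path, connection, or literal text wrapped in [I()].
#' @return A tibble with columns `gene`, `protein`.
#' @export
read_gene_map <- function(file) {
  map <- readr::read_tsv(file, col_names = c("gene", "protein"),
                         col_types = "cc", comment = "#")
  # tolerate a header row
  if (nrow(map) > 0L && tolower(map$gene[1]) %in% c("gene", "symbol", "gene_symbol"))
    map <- map[-1L, ]
  if (nrow(map) == 0L || any(!nzchar(map$gene)) || any(!nzchar(map$protein)))
    abort("gene map must have non-empty gene and protein columns")
  distinct(map)
}

#' Resolve seed genes to in-network proteins
#'
#' Maps each seed gene symbol through a one-to-many gene-to-protein table and
#' keeps the proteins present in the network. Because mappings are
#' one-to-many, the number of resolved proteins can exceed the number of seed
#' genes; downstream path mining enumerates pairs over resolved proteins.
#'
#' @param genes Character vector of seed gene symbols.
#' @param map Gene-to-protein tibble from [read_gene_map()] (columns `gene`,
#'   `protein`).
#' @param network A `ppi_network`.
#' @return A `seed_resolution` object: `proteins` (sorted character vector of
#'   resolved in-network proteins), `unmapped_genes`, `missing_proteins`
#'   (mapped but absent from the network), and the `gene`/`protein` rows used.
#' @export
resolve_seed_proteins <- function(genes, map, network) {
  stopifnot(is.character(genes), is.data.frame(map),
            inherits(network, "ppi_network"))
  if (length(genes) == 0L) abort("`genes` must be non-empty.")
  genes <- unique(genes)
  hits <- filter(map, .data$gene %in% genes)
  unmapped <- setdiff(genes, hits$gene)
  in_net <- hits$protein %in% network$nodes
  missing <- sort(unique(hits$protein[!in_net]))
  proteins <- sort(unique(hits$protein[in_net]))
  if (length(proteins) == 0L)
    abort("no seed gene resolves to a protein present in the network")
  if (length(unmapped) > 0L)
    inform(sprintf("%d seed gene(s) without a mapping: %s", length(unmapped),
                   paste(head(unmapped, 5L), collapse = ", ")))
  if (length(missing) > 0L)
    inform(sprintf("%d mapped protein(s) absent from the network.", length(missing)))
  structure(list(proteins = proteins, unmapped_genes = sort(unmapped),
                 missing_proteins = missing,
                 mapping = filter(hits, in_net)),
            class = "seed_resolution")
}

#' @export
print.seed_resolution <- function(x, ...) {
  cat(sprintf("<seed_resolution> %d in-network proteins from %d mapped gene(s)\n",
              length(x$proteins), length(unique(x$mapping$gene))))
  if (length(x$unmapped_genes)) cat("  unmapped genes:", length(x$unmapped_genes), "\n")
  if (length(x$missing_proteins)) cat("  mapped proteins not in network:",
                                      length(x$missing_proteins), "\n")
  invisible(x)
}
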