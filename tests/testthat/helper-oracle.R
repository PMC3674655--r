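# Independent oracles and fixture builders used across the suite.

# Exhaustive shortest-path oracle: enumerates every simple path between s and
# t by depth-first search and returns the minimum cost plus the
# lexicographically smallest minimum-cost node sequence. Quadratic blow-up,
# so only for tiny graphs.
brute_force_shortest <- function(edges, s, t) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- lapply(stats::setNames(nodes, nodes), function(u) {
    hit_a <- edges$protein_a == u
    hit_b <- edges$protein_b == u
    data.frame(v = c(edges$protein_b[hit_a], edges$protein_a[hit_b]),
               w = c(edges$cost[hit_a], edges$cost[hit_b]))
  })
  best <- list(cost = Inf, path = NULL)
  walk <- function(u, visited, cost, path) {
    if (u == t) {
      if (cost < best$cost ||
          (cost == best$cost && paste(path, collapse = "\r") <
             paste(best$path, collapse = "\r")))
        best <<- list(cost = cost, path = path)
      return(invisible())
    }
    nb <- adj[[u]]
    for (i in seq_len(nrow(nb))) {
      v <- nb$v[i]
      if (!(v %in% visited))
        walk(v, c(visited, v), cost + nb$w[i], c(path, v))
    }
  }
  walk(s, s, 0, s)
  best
}

# Random small weighted graph for oracle comparisons: n nodes, each pair an
# edge with probability p, integer scores.
random_tiny_graph <- function(n, p = 0.5, rng_seed = 1) {
  withr::with_seed(rng_seed, {
    pairs <- t(utils::combn(sprintf("N%02d", seq_len(n)), 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[1] <- TRUE
    tibble::tibble(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
                   score = sample(1:999, sum(keep), replace = TRUE))
  })
}

# Star network: hub connected to each leaf at maximal confidence.
star_network <- function(n_leaves, hub = "HUB") {
  leaves <- sprintf("L%02d", seq_len(n_leaves))
  build_network(tibble::tibble(protein_a = hub, protein_b = leaves,
                               score = 999L))
}

# Hand-built shortest_path_set for tally tests.
fake_path_set <- function(paths, seeds) {
  tb <- tibble::tibble(
    source = vapply(paths, function(p) p[[1]], ""),
    target = vapply(paths, function(p) p[[length(p)]], ""),
    cost = vapply(paths, length, 1) - 1,
    path = paths
  )
  structure(list(paths = tb,
                 skipped = tb[0, c("source", "target")],
                 seeds = seeds),
            class = "shortest_path_set")
}

edge_text <- function(edges) {
  paste(sprintf("%s\t%s\t%d", edges$protein_a, edges$protein_b, edges$score),
        collapse = "\n")
}

# strip subclass attributes for plain content comparisons
tidy_counts <- function(x) data.frame(id = x$id, count = x$count)
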