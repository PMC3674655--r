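test_that("dijkstra_path handles trivial and forced-route cases", {
  net <- build_network(read_string_edges(I("A\tB\t999\nB\tC\t999\nA\tC\t100")))

  same <- dijkstra_path(net, "A", "A")
  expect_equal(same$cost, 0)
  expect_equal(same$path[[1]], "A")

  via_b <- dijkstra_path(net, "A", "C")
  expect_equal(via_b$path[[1]], c("A", "B", "C"))
  expect_equal(via_b$cost, 2)

  expect_error(dijkstra_path(net, "A", "Z"), "not in network")

  # disconnected target is absent, not an error
  two_comp <- build_network(read_string_edges(I("A\tB\t999\nC\tD\t999")))
  expect_null(dijkstra_path(two_comp, "A", "C"))
})

test_that("equal-cost optima resolve to the lexicographically smallest path", {
  # diamond: A-B-D and A-C-D both cost 2
  net <- build_network(read_string_edges(
    I("A\tB\t999\nA\tC\t999\nB\tD\t999\nC\tD\t999")))
  expect_equal(dijkstra_path(net, "A", "D")$path[[1]], c("A", "B", "D"))
  ps <- all_pairs_seed_paths(net, c("A", "D"))
  expect_equal(ps$paths$path[[1]], c("A", "B", "D"))
})

test_that("mined paths match exhaustive enumeration on random tiny graphs", {
  for (i in 1:60) {
    n <- sample(4:8, 1)
    edges <- random_tiny_graph(n, p = 0.5, rng_seed = 1000 + i)
    net <- build_network(edges)
    seeds <- sample(net$nodes, min(4, length(net$nodes)))
    ps <- suppressMessages(all_pairs_seed_paths(net, seeds))
    for (r in seq_len(nrow(ps$paths))) {
      oracle <- brute_force_shortest(net$edges, ps$paths$source[r],
                                     ps$paths$target[r])
      expect_equal(ps$paths$cost[r], oracle$cost)
      expect_equal(ps$paths$path[[r]], oracle$path)
    }
    for (r in seq_len(nrow(ps$skipped))) {
      oracle <- brute_force_shortest(net$edges, ps$skipped$source[r],
                                     ps$skipped$target[r])
      expect_equal(oracle$cost, Inf)
    }
  }
})

test_that("pair bookkeeping is exact: paths plus skipped covers every pair", {
  # two components: seeds A, B in one, C in the other
  net <- build_network(read_string_edges(I("A\tB\t999\nC\tD\t999")))
  ps <- suppressMessages(all_pairs_seed_paths(net, c("A", "B", "C")))
  expect_equal(nrow(ps$paths), 1L)
  expect_equal(nrow(ps$skipped), 2L)
  expect_equal(nrow(ps$paths) + nrow(ps$skipped), choose(3, 2))
  expect_error(all_pairs_seed_paths(net, "A"), "at least 2")
})

test_that("adjacent seeds joined by the global minimum edge have no interior", {
  net <- build_network(read_string_edges(I("A\tB\t999\nA\tC\t500\nB\tC\t500")))
  ps <- all_pairs_seed_paths(net, c("A", "B"))
  expect_equal(ps$paths$path[[1]], c("A", "B"))
  expect_equal(nrow(betweenness_counts(ps)), 0L)
})

test_that("path mining is deterministic across runs", {
  edges <- random_tiny_graph(8, p = 0.6, rng_seed = 77)
  net <- build_network(edges)
  a <- all_pairs_seed_paths(net, net$nodes[1:5])
  b <- all_pairs_seed_paths(net, net$nodes[1:5])
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("adding an edge never increases any seed-pair cost", {
  edges <- random_tiny_graph(7, p = 0.5, rng_seed = 5)
  net <- build_network(edges)
  seeds <- net$nodes[1:4]
  before <- suppressMessages(all_pairs_seed_paths(net, seeds))
  # add a fresh strong edge between two arbitrary nodes
  extra <- tibble::tibble(protein_a = net$nodes[1], protein_b = net$nodes[6],
                          score = 980L)
  net2 <- build_network(dplyr::bind_rows(edges, extra))
  after <- suppressMessages(all_pairs_seed_paths(net2, seeds))
  shared <- dplyr::inner_join(before$paths[, 1:3], after$paths[, 1:3],
                              by = c("source", "target"))
  expect_true(all(shared$cost.y <= shared$cost.x))
})

test_that("betweenness counts interior occurrences and can exclude seeds", {
  single <- fake_path_set(list(c("A", "X", "B")), seeds = c("A", "B"))
  expect_equal(tidy_counts(betweenness_counts(single)),
               data.frame(id = "X", count = 1L))

  multi <- fake_path_set(list(c("A", "X", "B"), c("A", "X", "C"),
                              c("B", "Y", "C")),
                         seeds = c("A", "B", "C"))
  got <- betweenness_counts(multi)
  expect_equal(got$id, c("X", "Y"))
  expect_equal(got$count, c(2L, 1L))

  # star: C(4,2) leaf pairs all pass through the hub
  net <- star_network(4)
  ps <- all_pairs_seed_paths(net, sprintf("L%02d", 1:4))
  hub <- betweenness_counts(ps)
  expect_equal(tidy_counts(hub), data.frame(id = "HUB", count = 6L))

  # a seed sitting on another pair's interior is visible only when included
  seedy <- fake_path_set(list(c("A", "B", "C")), seeds = c("A", "B", "C"))
  expect_equal(nrow(betweenness_counts(seedy)), 0L)
  expect_equal(tidy_counts(betweenness_counts(seedy, include_seeds = TRUE)),
               data.frame(id = "B", count = 1L))
})

test_that("interior tally conserves total path length over random instances", {
  for (i in 1:25) {
    edges <- random_tiny_graph(8, p = 0.5, rng_seed = 300 + i)
    net <- build_network(edges)
    seeds <- sample(net$nodes, 4)
    ps <- suppressMessages(all_pairs_seed_paths(net, seeds))
    full <- betweenness_counts(ps, include_seeds = TRUE)
    expect_equal(sum(full$count),
                 sum(vapply(ps$paths$path, length, 1L) - 2L))
    expect_true(all(full$count <= nrow(ps$paths)))
    filtered <- betweenness_counts(ps)
    expect_lte(sum(filtered$count), sum(full$count))
  }
})

test_that("protein counts collapse to gene symbols by maximum", {
  counts <- tibble::tibble(id = c("P1", "P2", "P3"), count = c(5L, 3L, 9L))
  map <- tibble::tibble(gene = c("g1", "g1", "g2"),
                        protein = c("P1", "P2", "P3"))
  got <- collapse_to_genes(counts, map)
  expect_equal(got, tibble::tibble(gene = c("g2", "g1"), count = c(9L, 5L)))
})

test_that("path and betweenness exports are valid TSV", {
  net <- star_network(3)
  ps <- all_pairs_seed_paths(net, sprintf("L%02d", 1:3))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_paths(ps, f1)
  write_betweenness(betweenness_counts(ps), f2)
  paths_back <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(paths_back$path,
               paste(ps$paths$source, "HUB", ps$paths$target, sep = "|"))
  expect_equal(readr::read_tsv(f2, show_col_types = FALSE)$count, 3L)
})

test_that("the fast single-seed-set tally matches the path-based tally", {
  for (i in 1:10) {
    net <- generate_network(80, 2, rng_seed = 600 + i)
    seeds <- withr::with_seed(700 + i, sample(net$nodes, 10))
    ps <- suppressMessages(all_pairs_seed_paths(net, seeds))
    slow <- betweenness_counts(ps)
    fast <- betweenness_for_seeds(net, seeds)
    expect_equal(tidy_counts(fast), tidy_counts(slow))
    expect_equal(tidy_counts(betweenness_for_seeds(net, seeds,
                                                   include_seeds = TRUE)),
                 tidy_counts(betweenness_counts(ps, include_seeds = TRUE)))
  }
})

test_that("pairwise costs agree with an independent graph library", {
  edges <- random_tiny_graph(8, p = 0.7, rng_seed = 88)
  net <- build_network(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$protein_a, to = net$edges$protein_b,
               weight = net$edges$cost), directed = FALSE)
  seeds <- net$nodes[1:5]
  ps <- suppressMessages(all_pairs_seed_paths(net, seeds))
  d <- igraph::distances(g, v = seeds, to = seeds)
  for (r in seq_len(nrow(ps$paths)))
    expect_equal(ps$paths$cost[r],
                 d[ps$paths$source[r], ps$paths$target[r]])
})
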