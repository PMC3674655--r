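test_that("network generator honours size, connectivity and determinism", {
  tree <- generate_network(10, 1, rng_seed = 1)
  expect_length(tree$nodes, 10L)
  expect_equal(nrow(tree$edges), 9L)  # m = 1 attachment yields a tree

  a <- generate_network(200, 3, rng_seed = 7)
  b <- generate_network(200, 3, rng_seed = 7)
  expect_identical(a$edges, b$edges)
  expect_true(all(a$edges$score >= 150 & a$edges$score <= 999))

  expect_error(generate_network(5, 1), ">= 10")
  expect_error(generate_network(50, 1,
                                score_distribution = function(n) rep(0L, n)),
               "\\[1, 999\\]")
})

test_that("preferential attachment yields heavy-tailed degrees", {
  ok <- 0L
  for (s in 1:20) {
    net <- generate_network(500, 3, rng_seed = s)
    deg <- tabulate(c(match(net$edges$protein_a, net$nodes),
                      match(net$edges$protein_b, net$nodes)),
                    nbins = length(net$nodes))
    ok <- ok + (max(deg) >= 3 * stats::median(deg))
  }
  expect_equal(ok, 20L)
})

test_that("a fully attached connector lies on every seed pair's path", {
  # background scores capped at 997 so the planted cost-1 edges are the
  # unique strongest: a direct seed-seed edge costs >= 3 and any two-edge
  # detour >= 6, both beaten by the cost-2 route through the connector
  for (s in 1:5) {
    net <- generate_network(40, 2, rng_seed = 50 + s,
                            score_distribution = function(n)
                              sample(150:997, n, replace = TRUE))
    sc <- plant_connectors(net, n_seeds = sample(3:6, 1), n_connectors = 1,
                           attach_fraction = 1, rng_seed = 60 + s)
    ps <- suppressMessages(all_pairs_seed_paths(sc$network, sc$seed_proteins))
    bt <- betweenness_counts(ps)
    m <- length(sc$seed_proteins)
    expect_equal(bt$count[bt$id == sc$true_connectors], choose(m, 2))
    # every mined seed-pair path is exactly (seed, connector, seed), cost 2
    expect_true(all(vapply(ps$paths$path, length, 1L) == 3L))
    expect_true(all(vapply(ps$paths$path, `[[`, "", 2L) == sc$true_connectors))
    expect_equal(ps$paths$cost, rep(2, choose(m, 2)))
  }
})

test_that("planted scenarios are reproducible with valid ground truth", {
  net <- generate_network(100, 3, rng_seed = 2)
  a <- plant_connectors(net, 10, 2, 0.5, rng_seed = 9)
  b <- plant_connectors(net, 10, 2, 0.5, rng_seed = 9)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  expect_length(intersect(a$true_connectors, a$seed_proteins), 0L)
  expect_true(all(a$seed_proteins %in% a$network$nodes))
  expect_true(all(a$gene_map$protein %in% a$network$nodes))

  null_sc <- plant_connectors(net, 10, 0, 0.5, rng_seed = 9)
  expect_length(null_sc$true_connectors, 0L)

  expect_error(plant_connectors(net, 90, 20, 0.5, rng_seed = 1), "exceeds")
})

test_that("seed genes can map one-to-many onto seed proteins", {
  net <- generate_network(120, 3, rng_seed = 4)
  sc <- plant_connectors(net, n_seeds = 59, n_connectors = 0,
                         rng_seed = 5, n_seed_genes = 54)
  expect_length(sc$seeds, 54L)
  expect_length(sc$seed_proteins, 59L)
  res <- resolve_seed_proteins(sc$seeds, sc$gene_map, sc$network)
  expect_equal(res$proteins, sc$seed_proteins)
})

test_that("annotation generator plants detectable enrichment", {
  empty <- generate_annotation(sprintf("g%02d", 1:10), n_terms = 5,
                               terms_per_gene = 0)
  expect_equal(nrow(empty), 0L)

  a <- generate_annotation(sprintf("g%02d", 1:50), 30, rng_seed = 3)
  b <- generate_annotation(sprintf("g%02d", 1:50), 30, rng_seed = 3)
  expect_identical(a, b)

  genes <- sprintf("g%03d", 1:100)
  set <- genes[1:10]
  good <- 0L; total <- 0L
  for (s in 1:20) {
    ann <- generate_annotation(genes, n_terms = 50, terms_per_gene = 3,
                               enriched_sets = list(set), block_size = 5,
                               enrich_prob = 0.9, rng_seed = 200 + s)
    block <- tail(sort(unique(ann$term)), 5)
    bg <- unique(ann$gene)
    eff <- intersect(set, bg)
    for (tm in block) {
      tg <- unique(ann$gene[ann$term == tm])
      p <- term_enrichment_pvalue(length(eff), length(intersect(tg, eff)),
                                  length(tg), length(bg))
      total <- total + 1L
      good <- good + (p < 0.01)
    }
  }
  expect_gte(good / total, 0.95)
})

test_that("reference lists have exactly the requested overlap", {
  universe <- sprintf("g%03d", 1:500)
  set <- universe[1:25]
  ref <- generate_reference_list(universe, 100, set, 6, rng_seed = 11)
  expect_length(ref, 100L)
  expect_length(intersect(ref, set), 6L)

  disjoint <- generate_reference_list(universe, 40, set, 0, rng_seed = 2)
  expect_length(intersect(disjoint, set), 0L)

  inside <- generate_reference_list(universe, 10, set, 10, rng_seed = 2)
  expect_true(all(inside %in% set))

  expect_error(generate_reference_list(universe, 10, set, 26), "achievable")
  expect_error(generate_reference_list(universe[1:30], 20, set[1:25], 0),
               "outside")
})

test_that("written scenarios round-trip through the pipeline readers", {
  net <- generate_network(60, 2, rng_seed = 13)
  sc <- plant_connectors(net, 8, 1, 0.5, rng_seed = 14)
  sc$cancer_reference <- generate_reference_list(sc$gene_map$gene, 20,
                                                 rng_seed = 15)
  sc$annotation <- generate_annotation(sc$gene_map$gene, 30, rng_seed = 16)
  dir <- withr::local_tempdir()
  files <- write_scenario(sc, dir)
  expect_true(all(file.exists(unlist(files))))

  back <- read_string_edges(files$edges)
  expect_equal(back, sc$network$edges[, c("protein_a", "protein_b", "score")])
  expect_equal(read_gene_list(files$seeds), sc$seeds)
  map_back <- read_gene_map(files$gene_map)
  expect_equal(dplyr::arrange(map_back, gene, protein),
               dplyr::arrange(sc$gene_map, gene, protein))
  expect_equal(nrow(read_annotation(files$annotation)), nrow(sc$annotation))
})
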