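# Interactome loading, disease-module extraction, distance metrics and
# the hypergeometric over-representation test.

test_that("interactome loading deduplicates and drops self-loops", {
  g <- suppressMessages(load_interactome(
    data.frame(a = c("A", "B", "A"), b = c("B", "A", "A"))))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  # 10-row fixture with duplicates vs a set-of-sorted-pairs oracle
  set.seed(4)
  el <- data.frame(a = sample(LETTERS[1:6], 10, TRUE),
                   b = sample(LETTERS[1:6], 10, TRUE))
  g2 <- suppressMessages(load_interactome(el))
  keys <- unique(ifelse(el$a < el$b, paste(el$a, el$b),
                        paste(el$b, el$a))[el$a != el$b])
  expect_equal(igraph::ecount(g2), length(keys))
  expect_warning(e <- load_interactome(data.frame(a = character(0),
                                                  b = character(0))),
                 "empty")
  expect_equal(igraph::vcount(e), 0)
  expect_error(load_interactome(data.frame(a = "X", b = "")), "malformed")
})

test_that("LCC extraction picks the largest component with lexicographic ties", {
  g <- path_graph(c("a", "b", "c"))
  g <- igraph::add_vertices(g, 2, name = c("d", "e"))
  g <- igraph::add_edges(g, c("d", "e"))
  mod <- suppressMessages(extract_lcc(c("a", "b", "c", "d", "e"), g))
  expect_equal(mod$lcc_nodes, c("a", "b", "c"))
  # fully connected gene set keeps every present gene
  mod2 <- extract_lcc(c("a", "b"), g)
  expect_equal(mod2$lcc_nodes, c("a", "b"))
  # two singletons: lexicographically smallest wins
  mod3 <- extract_lcc(c("e", "a"), g)
  expect_equal(mod3$lcc_nodes, "a")
  expect_error(extract_lcc(c("zz"), g), "no disease gene")
})

test_that("LCC extraction matches a union-find components oracle", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 15
    syms <- sprintf("G%02d", seq_len(n))
    el <- data.frame(
      from = sample(syms, 18, TRUE), to = sample(syms, 18, TRUE))
    el <- el[el$from != el$to, ]
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = syms)
    genes <- sample(syms, 9)
    mod <- tryCatch(extract_lcc(genes, g), error = function(e) NULL)
    sub_edges <- el[el$from %in% genes & el$to %in% genes, ]
    comps <- uf_components(genes, sub_edges)
    sizes <- vapply(comps, length, 1L)
    biggest <- comps[sizes == max(sizes)]
    firsts <- vapply(biggest, min, character(1))
    oracle <- sort(biggest[[order(firsts)[1]]])
    expect_equal(mod$lcc_nodes, oracle)
  }
})

test_that("distance to module reproduces hand-computed path-graph values", {
  g <- path_graph(c("a", "b", "c", "d"))
  mod <- extract_lcc(c("a", "b"), g)
  expect_equal(mod$lcc_nodes, c("a", "b"))
  res <- distance_to_module(c("c", "d"), mod, g)
  expect_equal(sort(res$per_gene$distance), c(1, 2))
  expect_equal(res$mean, 1.5)
  # membership distance is zero
  expect_equal(distance_to_module(c("a", "b"), mod, g)$mean, 0)
  # unreachable genes are excluded and flagged
  g2 <- igraph::add_vertices(g, 1, name = "z")
  res2 <- distance_to_module(c("c", "z"), mod, g2)
  expect_equal(res2$mean, 1)
  expect_equal(res2$per_gene$status[res2$per_gene$gene == "z"],
               "unreachable")
})

test_that("intra-signature distance averages pairwise hops", {
  g <- path_graph(c("a", "b", "c", "d"))
  expect_equal(intra_signature_distance(c("a", "b"), g)$mean, 1)
  # {a, c, d}: d(a,c)=2, d(a,d)=3, d(c,d)=1
  r <- intra_signature_distance(c("a", "c", "d"), g)
  expect_equal(r$mean, 2)
  expect_equal(r$n_pairs, 3)
  # clique: all pairs adjacent
  kg <- igraph::make_full_graph(5)
  igraph::V(kg)$name <- letters[1:5]
  expect_equal(intra_signature_distance(letters[1:4], kg)$mean, 1)
  expect_error(intra_signature_distance("a", g), "at least two")
})

test_that("distance metrics are invariant under symbol relabeling", {
  toy <- generate_toy_interactome(60, 2, 8, seed = 5)
  g <- toy$graph
  sig <- sort(igraph::V(g)$name)[c(3, 10, 22, 40)]
  mod <- extract_lcc(toy$disease_genes, g)
  base_intra <- intra_signature_distance(sig, g)$mean
  base_mod <- distance_to_module(sig, mod, g)$mean
  # relabel every symbol with a prefix
  g2 <- g
  igraph::V(g2)$name <- paste0("X_", igraph::V(g)$name)
  mod2 <- extract_lcc(paste0("X_", toy$disease_genes), g2)
  expect_equal(intra_signature_distance(paste0("X_", sig), g2)$mean,
               base_intra)
  expect_equal(distance_to_module(paste0("X_", sig), mod2, g2)$mean,
               base_mod)
})

test_that("random reference is seed-determined and exact on edge cases", {
  toy <- generate_toy_interactome(80, 2, 10, seed = 6)
  mod <- extract_lcc(toy$disease_genes, toy$graph)
  r1 <- random_reference(toy$graph, mod, n_genes = 15, seeds = 1:3)
  r2 <- random_reference(toy$graph, mod, n_genes = 15, seeds = 1:3)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$per_seed), 3)
  # n_genes = |V|: the sample is the whole node set
  rall <- random_reference(toy$graph, mod, n_genes = 80, seeds = 1)
  expect_equal(rall$per_seed$intra,
               intra_signature_distance(igraph::V(toy$graph)$name,
                                        toy$graph)$mean)
  # complete graph: intra distance exactly 1
  kg <- igraph::make_full_graph(6)
  igraph::V(kg)$name <- letters[1:6]
  kmod <- extract_lcc(c("a", "b"), kg)
  rk <- random_reference(kg, kmod, n_genes = 4, seeds = 1:2)
  expect_equal(rk$per_seed$intra, c(1, 1))
  expect_error(random_reference(kg, kmod, n_genes = 10, seeds = 1),
               "exceeds")
})

test_that("hypergeometric test reproduces the worked 1/3 example and edges", {
  r <- hypergeom_test(2, 10, 4, 3)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$point_prob, 36 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_test(0, 50, 10, 5)$p_value, 1)
  # every gene a disease gene: overlap forced, p = 1
  expect_equal(hypergeom_test(5, 20, 20, 5)$p_value, 1)
  expect_error(hypergeom_test(6, 10, 4, 5), "cannot exceed")
  expect_error(hypergeom_test(3, 10, 4, 2), "cannot exceed")
})

test_that("hypergeometric pmf sums to one and the tail is monotone", {
  for (M in c(12, 30, 60)) {
    n <- floor(M / 3); N <- floor(M / 4)
    ks <- max(0, N + n - M):min(n, N)
    total <- sum(vapply(ks, function(k)
      hypergeom_test(k, M, n, N)$point_prob, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
    ps <- vapply(ks, function(k) hypergeom_test(k, M, n, N)$p_value,
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("percentage versus random follows the ratio arithmetic", {
  expect_equal(percent_vs_random(2, 2), 0)
  expect_equal(percent_vs_random(3, 2), 50)
  expect_equal(percent_vs_random(1.43, 1.52), -5.921053, tolerance = 1e-6)
  expect_error(percent_vs_random(1, 0), "positive")
})

test_that("the full signature evaluation wrapper is coherent", {
  toy <- generate_toy_interactome(150, 2, 20, seed = 9)
  sig <- c(toy$disease_genes[1:5],
           setdiff(igraph::V(toy$graph)$name, toy$disease_genes)[1:5])
  ev <- suppressMessages(
    evaluate_signature(sig, toy$graph, toy$disease_genes,
                       n_random = 20, seeds = 1:2))
  expect_equal(ev$enrichment$k, 5)
  expect_equal(ev$enrichment$N, 10)
  expect_lte(ev$enrichment$p_value, 1)
  expect_equal(ev$intra_vs_random_pct,
               percent_vs_random(ev$intra$mean, ev$random$grand$intra))
})
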