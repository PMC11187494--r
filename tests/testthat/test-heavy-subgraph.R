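# Heaviest-k-subgraph: induced weight, exact branch and bound, greedy.

triangle_graph <- function(w12 = 1, w13 = 2, w23 = 3) {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- w12
  W["a", "c"] <- W["c", "a"] <- w13
  W["b", "c"] <- W["c", "b"] <- w23
  edges_to_graph(W, c("a", "b", "c"))
}

test_that("induced weight sums exactly the edges inside the subset", {
  g <- triangle_graph()
  expect_equal(induced_weight(g, "a"), 0)
  expect_equal(induced_weight(g, c("a", "b", "c")), 6)
  expect_error(induced_weight(g, "zz"), "not in graph")
  g8 <- random_co_graph(8, 0.6, seed = 12)
  W <- gesel:::co_graph_matrix(g8)
  sub <- c("n01", "n03", "n05", "n08")
  idx <- match(sub, rownames(W))
  expect_equal(induced_weight(g8, sub), sum(W[idx, idx]) / 2)
})

test_that("exact solver handles the trivial and unique-pair cases", {
  g <- triangle_graph()
  all3 <- solve_exact(g, 3)
  expect_setequal(all3$feature_ids, c("a", "b", "c"))
  expect_equal(all3$objective, 6)
  # single positive edge
  W <- matrix(0, 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  W["c", "d"] <- W["d", "c"] <- 5
  gp <- edges_to_graph(W, c("a", "b", "c", "d"))
  s2 <- solve_exact(gp, 2)
  expect_setequal(s2$feature_ids, c("c", "d"))
  expect_equal(s2$objective, 5)
  # k = 1: zero objective, lexicographically smallest id
  s1 <- solve_exact(gp, 1)
  expect_equal(s1$feature_ids, "a")
  expect_equal(s1$objective, 0)
  expect_error(solve_exact(gp, 9), "exceeds")
})

test_that("exact solver matches brute-force enumeration on seeded instances", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(6:14, 1)
    k <- sample(2:min(6, n), 1)
    g <- random_co_graph(n, runif(1, 0.3, 0.9), seed = 1000 + rep)
    ex <- solve_exact(g, k)
    bf <- brute_force_heaviest(g, k)
    expect_equal(ex$objective, bf$objective, tolerance = 1e-9)
    expect_equal(induced_weight(g, ex$feature_ids), ex$objective,
                 tolerance = 1e-12)
  }
})

test_that("exact solver returns the lexicographically smallest co-optimal set", {
  # two disjoint edges of equal weight: {a,b} and {c,d} both optimal
  W <- matrix(0, 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  W["c", "d"] <- W["d", "c"] <- 2
  W["a", "b"] <- W["b", "a"] <- 2
  g <- edges_to_graph(W, letters[1:4])
  expect_equal(solve_exact(g, 2)$feature_ids, c("a", "b"))
})

test_that("greedy is dominated by exact and agrees on easy instances", {
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    k <- sample(2:min(5, n), 1)
    g <- random_co_graph(n, runif(1, 0.3, 0.9), seed = 2000 + rep)
    ge <- solve_greedy(g, k)
    ex <- solve_exact(g, k)
    expect_lte(ge$objective, ex$objective + 1e-9)
    expect_equal(induced_weight(g, ge$feature_ids), ge$objective,
                 tolerance = 1e-12)
  }
  # unique positive pair: both solvers coincide
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 5
  g <- edges_to_graph(W, c("a", "b", "c"))
  expect_setequal(solve_greedy(g, 2)$feature_ids,
                  solve_exact(g, 2)$feature_ids)
  expect_equal(solve_greedy(g, 3)$objective, 5)
})

test_that("optimal objective is monotone in k and scale-equivariant", {
  g <- random_co_graph(10, 0.5, seed = 7)
  objs <- vapply(1:6, function(k) solve_exact(g, k)$objective, numeric(1))
  expect_true(all(diff(objs) >= -1e-12))
  # scaling weights by c > 0 keeps the selected set, scales the objective
  c_ <- 3.7
  g_scaled <- g
  g_scaled$edges$weight <- g$edges$weight * c_
  g_scaled$nodes$strength <- g$nodes$strength * c_
  for (k in c(2, 4)) {
    a <- solve_exact(g, k); b <- solve_exact(g_scaled, k)
    expect_equal(a$feature_ids, b$feature_ids)
    expect_equal(b$objective, a$objective * c_, tolerance = 1e-9)
  }
})

test_that("the branch-and-bound upper bound is admissible", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_co_graph(9, 0.6, seed = 3000 + rep)
    ids <- sort(g$nodes$feature_id)
    k <- 4
    chosen <- ids[1:2]
    eligible <- ids[5:9]
    bound <- gesel:::hks_bound(g, k, chosen, eligible)
    # best completion: chosen plus any 2 eligible nodes
    best <- max(vapply(utils::combn(eligible, 2, simplify = FALSE),
                       function(ad) induced_weight(g, c(chosen, ad)),
                       numeric(1)))
    expect_gte(bound + 1e-9, best)
  }
})

test_that("auto dispatch picks exact under the budget and greedy beyond it", {
  g <- random_co_graph(10, 0.6, seed = 41)
  a <- solve_signature(g, 3, "auto")
  e <- solve_signature(g, 3, "exact")
  expect_identical(a$feature_ids, e$feature_ids)
  expect_equal(a$solver, "exact")
  expect_message(b <- solve_signature(g, 3, "auto", exact_budget = 5),
                 "greedy")
  expect_equal(b$solver, "greedy")
})

test_that("signatures serialize as TSV + JSON and tidy into ranked tables", {
  g <- random_co_graph(8, 0.7, seed = 15)
  s <- solve_exact(g, 3)
  td <- tidy(s)
  expect_equal(nrow(td), 3)
  expect_equal(td$rank, 1:3)
  expect_true(all(diff(td$strength) <= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(s, path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$k, 3)
  expect_equal(meta$objective, s$objective)
  gl <- glance(s)
  expect_equal(gl$objective, s$objective)
})
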