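# Co-selection matrix and co-importance graph construction.

mk_selection <- function(slices, ids) {
  # slices: list of 0/1 vectors, one per (selector, fold) slice laid out
  # as selector-major
  n_f <- length(slices)
  arr <- array(0, dim = c(n_f, 1, length(ids)),
               dimnames = list(paste0("s", seq_len(n_f)), "1", ids))
  for (f in seq_len(n_f)) arr[f, 1, ] <- slices[[f]]
  class(arr) <- c("selection_tensor", "array")
  attr(arr, "budget") <- max(vapply(slices, sum, numeric(1)))
  arr
}

test_that("co-selection counts single and summed co-selection events", {
  B <- mk_selection(list(c(1, 1, 0)), c("A", "B", "C"))
  M <- build_co_selection_matrix(B)
  expect_equal(M$M["A", "B"], 1L)
  expect_equal(M$M["A", "A"], 1L)
  expect_equal(M$M["A", "C"], 0L)
  B2 <- mk_selection(list(c(1, 1, 0), c(1, 1, 0)), c("A", "B", "C"))
  expect_equal(build_co_selection_matrix(B2)$M["A", "B"], 2L)
})

test_that("co-selection matrix equals the triple-loop counting oracle", {
  B <- random_selection_tensor(3, 4, 10, t = 4, seed = 21)
  M <- build_co_selection_matrix(B)
  expect_equal(unclass(M$M), unclass(co_selection_oracle(B)))
})

test_that("co-importance weights are capacity-style minima", {
  I <- array(0, dim = c(1, 1, 2),
             dimnames = list("s", "1", c("i", "j")))
  I[1, 1, ] <- c(0.3, 0.5)
  class(I) <- c("importance_tensor", "array")
  g <- build_co_importance_graph(I)
  expect_equal(g$edges$weight, 0.3)
  # fully-specified 2x2 example: w = 0.5 + 0.1 + 0.3 + 0.2
  I2 <- array(0, dim = c(2, 2, 2),
              dimnames = list(c("s1", "s2"), c("1", "2"), c("i", "j")))
  I2[1, 1, ] <- c(0.8, 0.5); I2[1, 2, ] <- c(0.1, 0.9)
  I2[2, 1, ] <- c(0.4, 0.3); I2[2, 2, ] <- c(0.6, 0.2)
  class(I2) <- c("importance_tensor", "array")
  g2 <- build_co_importance_graph(I2)
  expect_equal(g2$edges$weight, 1.1)
})

test_that("zero-importance features get no node and no edge", {
  I <- array(0, dim = c(1, 2, 3),
             dimnames = list("s", c("1", "2"), c("a", "b", "z")))
  I[1, 1, ] <- c(1, 0.4, 0); I[1, 2, ] <- c(0.2, 1, 0)
  class(I) <- c("importance_tensor", "array")
  g <- build_co_importance_graph(I)
  expect_false("z" %in% g$nodes$feature_id)
  expect_false(any(g$edges$from == "z" | g$edges$to == "z"))
})

test_that("co-importance graph matches the direct-summation oracle", {
  for (seed in 1:8) {
    I <- random_importance_tensor(3, 3, 12, seed = seed)
    g <- build_co_importance_graph(I)
    W <- co_importance_oracle(I)
    for (r in seq_len(nrow(g$edges))) {
      expect_equal(g$edges$weight[r],
                   W[g$edges$from[r], g$edges$to[r]], tolerance = 1e-12)
    }
    # absent edges are true zeros
    ids <- g$nodes$feature_id
    present <- paste(g$edges$from, g$edges$to)
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1)) {
        key <- paste(ids[j], ids[i])
        if (!key %in% present) expect_equal(W[ids[j], ids[i]], 0)
      }
    }
  }
})

test_that("co-importance satisfies capacity bound and positive homogeneity", {
  I <- random_importance_tensor(4, 3, 10, seed = 33)
  g <- build_co_importance_graph(I)
  totals <- apply(I, 3, sum)
  for (r in seq_len(nrow(g$edges))) {
    expect_lte(g$edges$weight[r],
               min(totals[g$edges$from[r]], totals[g$edges$to[r]]) + 1e-12)
  }
  c_ <- 0.37
  Ic <- I * c_
  class(Ic) <- class(I); dimnames(Ic) <- dimnames(I)
  gc <- build_co_importance_graph(Ic)
  expect_equal(gc$edges$weight, g$edges$weight * c_, tolerance = 1e-12)
})

test_that("counts are the co-importance of binary weights, edge for edge", {
  B <- random_selection_tensor(3, 4, 10, t = 4, seed = 44)
  M <- build_co_selection_matrix(B)
  g_counts <- co_graph_from_counts(M)
  Ib <- unclass(B)
  class(Ib) <- c("importance_tensor", "array")
  attr(Ib, "budget") <- NULL
  g_min <- build_co_importance_graph(Ib)
  expect_equal(g_counts$edges$from, g_min$edges$from)
  expect_equal(g_counts$edges$to, g_min$edges$to)
  expect_equal(g_counts$edges$weight, g_min$edges$weight)
})

test_that("count graph transcribes a fixed matrix entry by entry", {
  ids <- c("a", "b", "c", "d", "e")
  M <- matrix(0L, 5, 5, dimnames = list(ids, ids))
  M["a", "b"] <- M["b", "a"] <- 3L
  M["b", "d"] <- M["d", "b"] <- 1L
  diag(M) <- c(4L, 3L, 0L, 2L, 1L)
  msx <- structure(list(feature_ids = ids, M = M, n_slices = 6L),
                   class = "co_selection_matrix")
  g <- co_graph_from_counts(msx)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$weight[g$edges$from == "a"], 3)
  expect_false("c" %in% g$nodes$feature_id)  # never selected
  # all-zero off-diagonal: empty edge set
  M0 <- matrix(0L, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  diag(M0) <- 1L
  g0 <- co_graph_from_counts(
    structure(list(feature_ids = c("x", "y"), M = M0, n_slices = 2L),
              class = "co_selection_matrix"))
  expect_equal(nrow(g0$edges), 0)
})

test_that("pruning keeps the highest-strength nodes and induces the subgraph", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 2
  W["a", "c"] <- W["c", "a"] <- 3  # strengths a=5, b=2, c=3
  g <- edges_to_graph(W, c("a", "b", "c"))
  p <- prune_graph(g, 2)
  expect_setequal(p$nodes$feature_id, c("a", "c"))
  expect_identical(prune_graph(g, 10), g)
  # 50-node random graph vs strength-sorting oracle
  g50 <- random_co_graph(50, 0.2, seed = 5)
  p10 <- prune_graph(g50, 10)
  ord <- order(-g50$nodes$strength, g50$nodes$feature_id)
  expect_setequal(p10$nodes$feature_id,
                  g50$nodes$feature_id[ord[1:10]])
  # induced strengths recomputed within the kept set
  Wm <- gesel:::co_graph_matrix(p10)
  expect_equal(p10$nodes$strength[match(rownames(Wm), p10$nodes$feature_id)],
               unname(rowSums(Wm)))
})

test_that("co-graphs round-trip through the edge-list TSV format", {
  g <- random_co_graph(8, 0.5, seed = 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_co_graph(g, path)
  g2 <- read_co_graph(path)
  expect_equal(as.data.frame(g$edges), as.data.frame(g2$edges))
  expect_equal(as.data.frame(g$nodes), as.data.frame(g2$nodes))
})
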