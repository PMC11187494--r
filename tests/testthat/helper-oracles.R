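# Independent oracles and fixture builders. Everything here stays
# deliberately naive (loops, enumeration, union-find) so the package
# implementation is checked against a different computational route.

random_importance_tensor <- function(n_f, n_s, n_i, seed, sparsity = 0.3) {
  set.seed(seed)
  v <- runif(n_f * n_s * n_i)
  v[runif(length(v)) < sparsity] <- 0
  arr <- array(v, dim = c(n_f, n_s, n_i))
  # renormalize each slice so max == 1 unless all-zero
  for (f in seq_len(n_f)) for (s in seq_len(n_s)) {
    m <- max(arr[f, s, ])
    if (m > 0) arr[f, s, ] <- arr[f, s, ] / m
  }
  dimnames(arr) <- list(selector = paste0("sel", seq_len(n_f)),
                        fold = as.character(seq_len(n_s)),
                        feature = sprintf("f%03d", seq_len(n_i)))
  class(arr) <- c("importance_tensor", "array")
  arr
}

random_selection_tensor <- function(n_f, n_s, n_i, t, seed) {
  I <- random_importance_tensor(n_f, n_s, n_i, seed)
  binarize(I, t)
}

# triple-loop co-importance oracle: dense matrix of
# sum_{f,s} min(I[f,s,i], I[f,s,j])
co_importance_oracle <- function(I) {
  d <- dim(I)
  ids <- dimnames(I)$feature
  W <- matrix(0, d[3], d[3], dimnames = list(ids, ids))
  for (i in seq_len(d[3] - 1)) {
    for (j in (i + 1):d[3]) {
      acc <- 0
      for (f in seq_len(d[1])) for (s in seq_len(d[2])) {
        acc <- acc + min(I[f, s, i], I[f, s, j])
      }
      W[i, j] <- W[j, i] <- acc
    }
  }
  W
}

# triple-loop co-selection counting oracle
co_selection_oracle <- function(B) {
  d <- dim(B)
  ids <- dimnames(B)$feature
  M <- matrix(0L, d[3], d[3], dimnames = list(ids, ids))
  for (i in seq_len(d[3])) for (j in seq_len(d[3])) {
    acc <- 0L
    for (f in seq_len(d[1])) for (s in seq_len(d[2])) {
      acc <- acc + as.integer(B[f, s, i] == 1 && B[f, s, j] == 1)
    }
    M[i, j] <- acc
  }
  M
}

# random weighted co_graph on n nodes; edge kept with prob `density`
random_co_graph <- function(n, density, seed, mode = "co_importance") {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) W[i, j] <- W[j, i] <- runif(1)
  }
  edges_to_graph(W, ids, mode)
}

edges_to_graph <- function(W, ids, mode = "co_importance") {
  from <- character(0); to <- character(0); wt <- numeric(0)
  n <- length(ids)
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    if (n >= 2 && W[i, j] > 0) {
      from <- c(from, ids[i]); to <- c(to, ids[j]); wt <- c(wt, W[i, j])
    }
  }
  nodes <- tibble::tibble(feature_id = ids,
                          strength = unname(rowSums(W)),
                          count = unname(rowSums(W)))
  gesel:::new_co_graph(nodes,
                       tibble::tibble(from = from, to = to, weight = wt),
                       mode)
}

# exhaustive heaviest-k-subgraph search; returns optimum and the
# lexicographically smallest co-optimal subset
brute_force_heaviest <- function(g, k) {
  ids <- sort(g$nodes$feature_id)
  W <- gesel:::co_graph_matrix(g)
  best <- -Inf; best_ids <- NULL
  subsets <- utils::combn(ids, k, simplify = FALSE)
  for (s in subsets) {
    idx <- match(s, ids)
    val <- sum(W[idx, idx]) / 2
    if (val > best + 1e-12) {
      best <- val; best_ids <- s
    }
  }
  list(objective = best, feature_ids = best_ids)
}

# union-find connected components oracle over an edge data frame
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[[1]][r]); rb <- find(edges[[2]][r])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# hypergeometric point mass and upper tail from explicit log-binomials
hyper_point_choose <- function(k, M, n, N) {
  if (k < max(0, N + n - M) || k > min(n, N)) return(0)
  exp(lchoose(n, k) + lchoose(M - n, N - k) - lchoose(M, N))
}

hyper_upper_choose <- function(k, M, n, N) {
  xs <- k:min(n, N)
  if (length(xs) == 0) return(0)
  sum(vapply(xs, hyper_point_choose, numeric(1), M = M, n = n, N = N))
}

# full subset-enumeration oracle (small M only): draws all C(M, N)
# selections from a universe with n marked genes
hyper_upper_enumerate <- function(k, M, n, N) {
  marked <- seq_len(n)
  subsets <- utils::combn(M, N, simplify = FALSE)
  mean(vapply(subsets, function(s) sum(s %in% marked) >= k, logical(1)))
}

# small labeled path/clique interactomes used across network tests
path_graph <- function(syms) {
  igraph::graph_from_data_frame(
    data.frame(from = syms[-length(syms)], to = syms[-1]),
    directed = FALSE)
}
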