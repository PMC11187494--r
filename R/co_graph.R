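# The co-selection matrix and the co-importance graph: how agreement
# between base selectors across folds becomes a weighted feature graph.

new_co_graph <- function(nodes, edges, mode) {
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "co_graph")
}

#' @export
print.co_graph <- function(x, ...) {
  cat(sprintf("<co_graph> mode %s: %d nodes, %d edges\n",
              x$mode, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# symmetric pairwise matrix -> sparse upper-triangle edge tibble
edges_from_matrix <- function(W, ids) {
  ut <- upper.tri(W)
  keep <- which(ut & W > 0, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    return(tibble(from = character(0), to = character(0),
                  weight = numeric(0)))
  }
  e <- tibble(from = ids[keep[, 1]], to = ids[keep[, 2]],
              weight = W[keep])
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  dplyr::arrange(e, .data$from, .data$to)
}

graph_from_pairwise <- function(W, ids, diag_meta, mode) {
  diag(W) <- 0
  strength <- rowSums(W)
  edges <- edges_from_matrix(W, ids)
  nodes <- tibble(feature_id = ids, strength = unname(strength),
                  count = unname(diag_meta))
  nodes <- dplyr::arrange(nodes, .data$feature_id)
  new_co_graph(nodes, edges, mode)
}

#' Count pairwise co-selection events across selectors and folds
#'
#' Entry `M[i, j]` counts, summed over all base selectors `f` and folds
#' `s`, the slices on which `f` selected both features `i` and `j`
#' simultaneously. The diagonal `M[i, i]` is the total selection count of
#' `i` — the quantity classical majority-voting ensembles use alone.
#'
#' @param B a `selection_tensor` from [binarize()].
#' @return an object of class `co_selection_matrix`: list with
#'   `feature_ids`, integer matrix `M`, and `n_slices` (= selectors x
#'   folds, the maximum possible count).
#' @export
build_co_selection_matrix <- function(B) {
  assert_that(inherits(B, "selection_tensor"),
              "`B` must be a selection_tensor")
  d <- dim(B)
  X <- matrix(as.vector(B), nrow = d[1] * d[2], ncol = d[3])
  M <- crossprod(X)                       # M[i,j] = sum_fs B_i B_j
  storage.mode(M) <- "integer"
  ids <- dimnames(B)[[3]]
  dimnames(M) <- list(ids, ids)
  structure(list(feature_ids = ids, M = M, n_slices = d[1] * d[2]),
            class = "co_selection_matrix")
}

#' @export
print.co_selection_matrix <- function(x, ...) {
  cat(sprintf("<co_selection_matrix> %d features, counts in [0, %d]\n",
              length(x$feature_ids), x$n_slices))
  invisible(x)
}

#' Build the co-selection graph from a count matrix
#'
#' Nodes are the features with at least one selection; an edge joins every
#' pair with a positive co-selection count, weighted by that count.
#' Diagonal counts are kept as node metadata only — the heaviest-subgraph
#' objective sums induced *edge* weights.
#'
#' @param M a `co_selection_matrix`.
#' @return a `co_graph` with `mode = "co_selection"`.
#' @export
co_graph_from_counts <- function(M) {
  assert_that(inherits(M, "co_selection_matrix"),
              "`M` must be a co_selection_matrix")
  keep <- diag(M$M) > 0
  W <- M$M[keep, keep, drop = FALSE] * 1.0
  graph_from_pairwise(W, M$feature_ids[keep], diag(M$M)[keep], "co_selection")
}

#' Build the co-importance graph from an importance tensor
#'
#' Generalizes co-selection counts to graded importances: the weight of
#' edge (i, j) is the sum over all (selector, fold) slices of
#' `min(I[f, s, i], I[f, s, j])` — the most limiting of the two
#' importances, a capacity-style notion of shared support. Features with
#' zero importance everywhere are dropped (they can never contribute
#' positive weight); zero-weight edges are omitted.
#'
#' @param I an `importance_tensor` with values in `[0, 1]`.
#' @return a `co_graph` with `mode = "co_importance"`; node `count`
#'   metadata holds each feature's total importance over all slices.
#' @export
build_co_importance_graph <- function(I) {
  validate_importance_tensor(I)
  d <- dim(I)
  X <- matrix(as.vector(I), nrow = d[1] * d[2], ncol = d[3])
  totals <- colSums(X)
  keep <- which(totals > 0)
  ids <- dimnames(I)[[3]][keep]
  X <- X[, keep, drop = FALSE]
  n <- length(keep)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(X))) {
    v <- X[r, ]
    W <- W + outer(v, v, pmin)
  }
  graph_from_pairwise(W, ids, totals[keep], "co_importance")
}

#' Prune a co-graph to its highest-strength nodes
#'
#' Keeps the `max_nodes` nodes with the largest weighted degree
#' (strength), ties broken by lexicographic feature id, and returns the
#' induced subgraph. Used to keep exact heaviest-subgraph solving
#' tractable on sizable graphs.
#'
#' @param g a `co_graph`.
#' @param max_nodes number of nodes to keep.
#' @return the induced `co_graph` (unchanged if `max_nodes >= |V|`).
#' @export
prune_graph <- function(g, max_nodes) {
  assert_that(inherits(g, "co_graph"), "`g` must be a co_graph")
  assert_that(length(max_nodes) == 1 && max_nodes >= 1,
              "`max_nodes` must be a positive integer")
  if (max_nodes >= nrow(g$nodes)) return(g)
  ord <- order_desc_lex(g$nodes$strength, g$nodes$feature_id)
  keep <- sort(g$nodes$feature_id[ord[seq_len(max_nodes)]])
  edges <- dplyr::filter(g$edges, .data$from %in% keep, .data$to %in% keep)
  nodes <- dplyr::filter(g$nodes, .data$feature_id %in% keep)
  # strengths are recomputed on the induced subgraph
  st <- setNames(numeric(length(keep)), keep)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      st[edges$from[i]] <- st[edges$from[i]] + edges$weight[i]
      st[edges$to[i]] <- st[edges$to[i]] + edges$weight[i]
    }
  }
  nodes$strength <- unname(st[nodes$feature_id])
  new_co_graph(nodes, edges, g$mode)
}

# dense symmetric weight matrix over lexicographically sorted node ids
co_graph_matrix <- function(g) {
  ids <- sort(g$nodes$feature_id)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, ids); j <- match(g$edges$to, ids)
    W[cbind(i, j)] <- g$edges$weight
    W[cbind(j, i)] <- g$edges$weight
  }
  W
}

#' Convert a co-graph to an igraph object
#'
#' @param g a `co_graph`.
#' @return an undirected weighted [igraph::graph] with vertex attributes
#'   `strength` and `count`.
#' @export
as_igraph <- function(g) {
  assert_that(inherits(g, "co_graph"), "`g` must be a co_graph")
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  igraph::E(ig)$weight <- g$edges$weight
  ig
}

#' Write / read a co-graph as weighted edge-list and node-metadata TSVs
#'
#' @param g a `co_graph`.
#' @param edge_path path of the 3-column edge TSV (`from`, `to`,
#'   `weight`); the node TSV (feature id, strength, count) is written next
#'   to it as `<edge_path>.nodes.tsv`.
#' @param mode graph mode to record on read-back.
#' @return `edge_path` invisibly (`write_`), or the `co_graph` (`read_`).
#' @export
write_co_graph <- function(g, edge_path) {
  readr::write_tsv(g$edges, edge_path)
  readr::write_tsv(g$nodes, paste0(edge_path, ".nodes.tsv"))
  invisible(edge_path)
}

#' @rdname write_co_graph
#' @export
read_co_graph <- function(edge_path, mode = "co_importance") {
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE,
                           col_types = "ccd")
  nodes <- readr::read_tsv(paste0(edge_path, ".nodes.tsv"),
                           show_col_types = FALSE, col_types = "cdd")
  new_co_graph(nodes, edges, mode)
}

#' Plot a co-graph as a force-directed network
#'
#' @param object a `co_graph`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object: nodes sized by strength, edges shaded by
#'   weight.
#' @export
autoplot.co_graph <- function(object, seed = 1L, ...) {
  ig <- as_igraph(object)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(ig)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::mutate(
    object$edges,
    x = nodes$x[match(.data$from, nodes$feature_id)],
    y = nodes$y[match(.data$from, nodes$feature_id)],
    xend = nodes$x[match(.data$to, nodes$feature_id)],
    yend = nodes$y[match(.data$to, nodes$feature_id)])
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, alpha = .data$weight),
                 colour = "grey40") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$strength),
               colour = "#2c7fb8") +
    labs(title = sprintf("%s graph", gsub("_", "-", object$mode)),
         alpha = "edge weight", size = "strength") +
    theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text = ggplot2::element_blank())
}
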