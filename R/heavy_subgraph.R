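# Heaviest k-Subgraph solvers. The signature is the k-node subset of the
# co-graph maximizing the sum of edge weights in its induced subgraph —
# NP-hard in general, solved exactly by depth-first branch and bound on
# desk-scale graphs and approximately by a deterministic greedy heuristic.

new_signature <- function(feature_ids, k, objective, method, solver,
                          strength = NULL) {
  structure(list(feature_ids = sort(feature_ids), k = as.integer(k),
                 objective = objective, method = method, solver = solver,
                 strength = strength),
            class = "ge_signature")
}

#' @export
print.ge_signature <- function(x, ...) {
  cat(sprintf("<ge_signature> %s (%s): k = %d, objective = %.4f\n",
              x$method, x$solver %||% "rank", x$k, x$objective))
  cat("  ", paste(x$feature_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a signature into a ranked tibble
#'
#' @param x a `ge_signature`.
#' @param ... unused.
#' @return tibble with `rank` (by decreasing per-feature strength, ties by
#'   id), `feature_id`, `strength`.
#' @export
tidy.ge_signature <- function(x, ...) {
  st <- x$strength %||% setNames(rep(NA_real_, x$k), x$feature_ids)
  st <- st[x$feature_ids]
  ord <- order_desc_lex(ifelse(is.na(st), -Inf, st), x$feature_ids)
  tibble(rank = seq_len(x$k),
         feature_id = x$feature_ids[ord],
         strength = unname(st[ord]))
}

#' @rdname tidy.ge_signature
#' @export
glance.ge_signature <- function(x, ...) {
  tibble(k = x$k, method = x$method, solver = x$solver %||% NA_character_,
         objective = x$objective)
}

#' @export
autoplot.ge_signature <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = stats::reorder(.data$feature_id, -.data$rank),
                 y = .data$strength)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = "strength",
         title = sprintf("%s signature (k = %d)", object$method, object$k)) +
    theme_minimal()
}

#' Sum of edge weights induced by a node subset
#'
#' @param g a `co_graph`.
#' @param nodes character vector of feature ids, all present in `g`.
#' @return total weight of edges with both endpoints in `nodes`.
#' @export
induced_weight <- function(g, nodes) {
  assert_that(inherits(g, "co_graph"), "`g` must be a co_graph")
  missing <- setdiff(nodes, g$nodes$feature_id)
  assert_that(length(missing) == 0,
              paste("nodes not in graph:", paste(missing, collapse = ", ")))
  if (nrow(g$edges) == 0) return(0)
  sum(g$edges$weight[g$edges$from %in% nodes & g$edges$to %in% nodes])
}

signature_strengths <- function(g, ids) {
  setNames(g$nodes$strength[match(ids, g$nodes$feature_id)], ids)
}

check_k <- function(g, k) {
  assert_that(length(k) == 1 && is.finite(k) && k >= 1,
              "`k` must be a positive integer")
  assert_that(k <= nrow(g$nodes),
              sprintf("k = %d exceeds the %d graph nodes", k, nrow(g$nodes)))
  as.integer(k)
}

method_for_mode <- function(g) {
  if (identical(g$mode, "co_importance")) "k_w_heavy" else "k_heavy"
}

#' Greedy approximate heaviest-k-subgraph solver
#'
#' Deterministic heuristic: seed with the heaviest edge's endpoints (the
#' strongest single node when `k = 1`), then repeatedly add the node with
#' the largest marginal induced-weight gain. All ties break
#' lexicographically. The greedy objective can never exceed the exact
#' optimum.
#'
#' @param g a `co_graph`.
#' @param k signature size, `1 <= k <= |V|`.
#' @return a `ge_signature` with `solver = "greedy"`.
#' @export
solve_greedy <- function(g, k) {
  k <- check_k(g, k)
  W <- co_graph_matrix(g)
  ids <- rownames(W)
  n <- length(ids)
  if (k == 1) {
    st <- rowSums(W)
    pick <- ids[order_desc_lex(st, ids)[1]]
    return(new_signature(pick, 1, 0, method_for_mode(g), "greedy",
                         signature_strengths(g, pick)))
  }
  if (nrow(g$edges) > 0) {
    e <- g$edges[order(-g$edges$weight, g$edges$from, g$edges$to,
                       method = "radix"), ]
    chosen <- match(c(e$from[1], e$to[1]), ids)
  } else {
    chosen <- seq_len(min(2, n))
  }
  while (length(chosen) < k) {
    cand <- setdiff(seq_len(n), chosen)
    gain <- colSums(W[chosen, cand, drop = FALSE])
    chosen <- c(chosen, cand[order_desc_lex(gain, ids[cand])[1]])
  }
  sel <- ids[chosen]
  new_signature(sel, k, induced_weight(g, sel), method_for_mode(g),
                "greedy", signature_strengths(g, sel))
}

#' Exact heaviest-k-subgraph solver (branch and bound)
#'
#' Depth-first search over include/exclude decisions on nodes ordered by
#' decreasing strength, with the greedy solution as incumbent. At a node
#' with `r` slots left, the admissible upper bound adds, to the current
#' induced weight, the sum of the `r` largest optimistic gains, where a
#' candidate's gain is its weight to the chosen set plus half the sum of
#' its `r - 1` heaviest edges to other still-eligible nodes (halving
#' avoids double counting each within-completion edge). Among co-optimal
#' subsets the lexicographically smallest id sequence is returned.
#'
#' @param g a `co_graph`.
#' @param k signature size, `1 <= k <= |V|`.
#' @param exact_budget refuse instances with more nodes than this
#'   (NP-hard problem; use [solve_greedy()] or [prune_graph()] beyond it).
#' @return a `ge_signature` with `solver = "exact"`, globally optimal
#'   objective.
#' @export
solve_exact <- function(g, k, exact_budget = 500L) {
  k <- check_k(g, k)
  n <- nrow(g$nodes)
  if (n > exact_budget) {
    abort(sprintf(paste0(
      "exact solver refuses |V| = %d > budget %d; ",
      "use solve_greedy() or prune_graph() first"), n, exact_budget))
  }
  if (k == 1) {
    pick <- sort(g$nodes$feature_id)[1]
    return(new_signature(pick, 1, 0, method_for_mode(g), "exact",
                         signature_strengths(g, pick)))
  }
  W0 <- co_graph_matrix(g)
  ids0 <- rownames(W0)
  ord <- order_desc_lex(rowSums(W0), ids0)
  W <- W0[ord, ord]
  ids <- ids0[ord]
  inc <- solve_greedy(g, k)
  best <- inc$objective
  best_ids <- inc$feature_ids
  eps <- 1e-9
  env <- new.env()
  env$best <- best; env$best_ids <- best_ids
  consider <- function(set_idx, value) {
    cand <- sort(ids[set_idx])
    if (value > env$best + eps ||
        (value > env$best - eps && lex_less(cand, env$best_ids))) {
      env$best <- max(env$best, value)
      env$best_ids <- cand
    }
  }
  recurse <- function(pos, chosen, cur) {
    r <- k - length(chosen)
    if (r == 0) { consider(chosen, cur); return(invisible()) }
    avail <- if (pos > n) integer(0) else pos:n
    if (length(avail) < r) return(invisible())
    # admissible optimistic completion bound
    Wae <- W[avail, avail, drop = FALSE]
    to_chosen <- if (length(chosen))
      colSums(W[chosen, avail, drop = FALSE]) else numeric(length(avail))
    if (r >= 2) {
      tops <- apply(Wae, 2, function(col) {
        sum(sort(col, decreasing = TRUE)[seq_len(r - 1)])
      })
    } else tops <- numeric(length(avail))
    gains <- to_chosen + 0.5 * tops
    bound <- cur + sum(sort(gains, decreasing = TRUE)[seq_len(r)])
    if (bound < env$best - eps) return(invisible())
    # include pos, then exclude pos
    add_w <- if (length(chosen)) sum(W[chosen, pos]) else 0
    recurse(pos + 1, c(chosen, pos), cur + add_w)
    recurse(pos + 1, chosen, cur)
    invisible()
  }
  recurse(1, integer(0), 0)
  sel <- env$best_ids
  new_signature(sel, k, induced_weight(g, sel), method_for_mode(g),
                "exact", signature_strengths(g, sel))
}

# exposed for bound-admissibility testing: the optimistic bound at a
# search state (chosen/eligible given as feature ids)
hks_bound <- function(g, k, chosen_ids, eligible_ids) {
  W <- co_graph_matrix(g)
  ids <- rownames(W)
  chosen <- match(chosen_ids, ids)
  avail <- match(eligible_ids, ids)
  r <- k - length(chosen)
  cur <- induced_weight(g, chosen_ids)
  if (r == 0) return(cur)
  if (length(avail) < r) return(-Inf)
  to_chosen <- if (length(chosen))
    colSums(W[chosen, avail, drop = FALSE]) else numeric(length(avail))
  tops <- if (r >= 2) {
    apply(W[avail, avail, drop = FALSE], 2, function(col) {
      sum(sort(col, decreasing = TRUE)[seq_len(r - 1)])
    })
  } else numeric(length(avail))
  cur + sum(sort(to_chosen + 0.5 * tops, decreasing = TRUE)[seq_len(r)])
}

#' Solve for a signature with solver dispatch
#'
#' `solver = "auto"` uses the exact branch and bound when the graph is
#' within the node budget and falls back to the greedy heuristic (with a
#' message) beyond it.
#'
#' @inheritParams solve_exact
#' @param solver `"exact"`, `"greedy"` or `"auto"`.
#' @return a `ge_signature`.
#' @export
solve_signature <- function(g, k, solver = c("auto", "exact", "greedy"),
                            exact_budget = 500L) {
  solver <- match.arg(solver)
  if (solver == "greedy") return(solve_greedy(g, k))
  if (solver == "exact") return(solve_exact(g, k, exact_budget))
  if (nrow(g$nodes) <= exact_budget) {
    solve_exact(g, k, exact_budget)
  } else {
    inform(sprintf("|V| = %d exceeds exact budget %d; using greedy solver",
                   nrow(g$nodes), exact_budget))
    solve_greedy(g, k)
  }
}

#' Write a signature as TSV plus JSON metadata
#'
#' @param x a `ge_signature`.
#' @param path TSV path (`rank`, `feature_id`, `strength`); metadata (k,
#'   method, solver, objective) goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_signature <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  jsonlite::write_json(
    list(k = x$k, method = x$method, solver = x$solver,
         objective = x$objective),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
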