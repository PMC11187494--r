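# Network-based signature evaluation on a protein-protein interactome:
# disease-module extraction (largest connected component of the disease
# genes), intra-signature and signature-to-module shortest-path distances,
# random-gene reference, and the hypergeometric over-representation test.

#' Load an interactome from a two-column edge list
#'
#' Builds an undirected simple graph of gene symbols. Self-loops and
#' duplicate edges are dropped (counts reported); symbols are
#' whitespace-stripped and matched case-sensitively.
#'
#' @param edges a two-column data frame of symbol pairs, or a path to a
#'   headerless two-column TSV.
#' @return an undirected simple [igraph::graph] with gene-symbol vertex
#'   names.
#' @export
load_interactome <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- readr::read_tsv(edges, col_names = c("from", "to"),
                             show_col_types = FALSE, col_types = "cc")
  }
  assert_that(is.data.frame(edges) && ncol(edges) >= 2,
              "`edges` must have two symbol columns")
  a <- trimws(as.character(edges[[1]]))
  b <- trimws(as.character(edges[[2]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad) > 0) {
    abort(sprintf("malformed edge row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (length(a) == 0) {
    warn("empty edge list: returning an empty interactome")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  self <- a == b
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key) & !self
  keep <- !self & !dup
  if (any(self) || any(dup)) {
    inform(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                   sum(self), sum(dup)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep]), directed = FALSE)
  inform(sprintf("interactome: %d nodes, %d edges",
                 igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Extract the disease module (largest connected component)
#'
#' The disease module is the largest connected component (LCC) of the
#' subgraph induced by the disease genes: the biggest induced subgraph in
#' which a path exists between every pair of nodes. Genes absent from the
#' interactome are dropped with a count; a tie between equal-size
#' components goes to the component containing the lexicographically
#' smallest symbol.
#'
#' @param genes character vector of disease gene symbols.
#' @param g interactome graph from [load_interactome()].
#' @return an object of class `disease_module`: list with `seed_genes`,
#'   `lcc_nodes`, `n_absent`.
#' @export
extract_lcc <- function(genes, g) {
  genes <- unique(trimws(as.character(genes)))
  assert_that(length(genes) > 0, "`genes` must be non-empty")
  present <- intersect(genes, igraph::V(g)$name)
  if (length(present) == 0) abort("no disease gene is present in the graph")
  n_absent <- length(genes) - length(present)
  if (n_absent > 0) {
    inform(sprintf("%d disease gene(s) absent from the interactome",
                   n_absent))
  }
  sub <- igraph::induced_subgraph(g, present)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    firsts <- vapply(biggest, function(ci) {
      min(igraph::V(sub)$name[comp$membership == ci])
    }, character(1))
    biggest <- biggest[order(firsts)][1]
  }
  lcc <- sort(igraph::V(sub)$name[comp$membership == biggest])
  structure(list(seed_genes = sort(genes), lcc_nodes = lcc,
                 n_absent = n_absent),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf("<disease_module> LCC of %d nodes from %d seed gene(s) (%d absent)\n",
              length(x$lcc_nodes), length(x$seed_genes), x$n_absent))
  invisible(x)
}

#' Mean shortest-path distance from a signature to the disease module
#'
#' For every signature gene, the distance is the minimum shortest-path
#' length (in hops) to any module LCC node — 0 for genes inside the LCC.
#' Genes absent from the interactome or unreachable from the module are
#' excluded from the mean and flagged in the per-gene table.
#'
#' @param signature character vector of gene symbols.
#' @param module a `disease_module`.
#' @param g the interactome graph.
#' @return list with `mean` (over included genes) and `per_gene`, a
#'   tibble (`gene`, `distance`, `status` in
#'   included/absent/unreachable).
#' @export
distance_to_module <- function(signature, module, g) {
  signature <- unique(trimws(as.character(signature)))
  assert_that(length(signature) > 0, "`signature` must be non-empty")
  assert_that(inherits(module, "disease_module"),
              "`module` must be a disease_module")
  present <- intersect(signature, igraph::V(g)$name)
  tbl <- tibble(gene = signature, distance = NA_real_, status = "absent")
  if (length(present) > 0) {
    D <- igraph::distances(g, v = present, to = module$lcc_nodes)
    dmin <- apply(D, 1, min)
    idx <- match(present, tbl$gene)
    tbl$distance[idx] <- ifelse(is.finite(dmin), dmin, NA_real_)
    tbl$status[idx] <- ifelse(is.finite(dmin), "included", "unreachable")
  }
  ok <- tbl$status == "included"
  if (!any(ok)) abort("no signature gene reaches the disease module")
  list(mean = mean(tbl$distance[ok]), per_gene = tbl)
}

#' Mean pairwise shortest-path distance within a signature
#'
#' Mean shortest-path length (hops) over all unordered pairs of signature
#' genes present in the interactome; unreachable pairs are excluded from
#' the mean and counted. Larger values indicate that the signature covers
#' more diverse network neighbourhoods (mechanistic diversity).
#'
#' @param signature character vector of gene symbols (at least two must
#'   be present and mutually reachable).
#' @param g the interactome graph.
#' @return list with `mean`, `n_pairs` (included), `n_unreachable_pairs`,
#'   `n_absent`.
#' @export
intra_signature_distance <- function(signature, g) {
  signature <- unique(trimws(as.character(signature)))
  present <- intersect(signature, igraph::V(g)$name)
  assert_that(length(present) >= 2,
              "need at least two signature genes in the interactome")
  D <- igraph::distances(g, v = present, to = present)
  d <- D[upper.tri(D)]
  finite <- is.finite(d)
  if (!any(finite)) abort("no reachable signature gene pair")
  list(mean = mean(d[finite]), n_pairs = sum(finite),
       n_unreachable_pairs = sum(!finite),
       n_absent = length(signature) - length(present))
}

#' Random-signature reference distances
#'
#' For each seed, samples `n_genes` interactome nodes without replacement
#' and computes the intra-signature distance and the distance to the
#' disease module; reports per-seed values and across-seed grand means.
#' This is the referential against which observed signature distances are
#' expressed as percentages.
#'
#' @param g the interactome graph.
#' @param module a `disease_module`.
#' @param n_genes random-signature size (default 100).
#' @param seeds integer vector of sampling seeds.
#' @return list with `per_seed` (tibble `seed`, `intra`, `to_module`) and
#'   `grand` (tibble `intra`, `to_module` of across-seed means).
#' @export
random_reference <- function(g, module, n_genes = 100,
                             seeds = 1:4) {
  nodes <- igraph::V(g)$name
  assert_that(n_genes <= length(nodes),
              "`n_genes` exceeds the number of interactome nodes")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  per_seed <- purrr::map(seeds, function(sd) {
    set.seed(derive_seed(sd, "random_reference"))
    sig <- sample(nodes, n_genes, replace = FALSE)
    tibble(seed = sd,
           intra = intra_signature_distance(sig, g)$mean,
           to_module = distance_to_module(sig, module, g)$mean)
  }) |> dplyr::bind_rows()
  list(per_seed = per_seed,
       grand = tibble(intra = mean(per_seed$intra),
                      to_module = mean(per_seed$to_module)))
}

#' Hypergeometric over-representation test
#'
#' Probability model for the overlap between a selected gene set and a
#' disease-associated reference list: drawing `N` genes without
#' replacement from a universe of `M` genes of which `n` are
#' disease-associated, the point probability of observing exactly `k`
#' disease genes is `C(n,k) C(M-n, N-k) / C(M,N)`, and the reported
#' p-value is the upper tail `P(X >= k)` (the probability of an overlap
#' at least as large as observed).
#'
#' @param k observed overlap size.
#' @param M universe size (genes in the interactome).
#' @param n disease-associated genes in the reference list.
#' @param N number of selected genes.
#' @return an object of class `enrichment_result` (also a one-row
#'   tibble): `k`, `M`, `n`, `N`, `point_prob`, `p_value`.
#' @export
hypergeom_test <- function(k, M, n, N) {
  for (v in list(k, M, n, N)) {
    assert_that(length(v) == 1 && is.finite(v) && v >= 0 && v == floor(v),
                "k, M, n, N must be single non-negative integers")
  }
  assert_that(N <= M, "`N` cannot exceed the universe size `M`")
  assert_that(n <= M, "`n` cannot exceed the universe size `M`")
  assert_that(k <= N, "overlap `k` cannot exceed the selection size `N`")
  assert_that(k <= n, "overlap `k` cannot exceed the reference size `n`")
  point <- dhyper(k, n, M - n, N)
  p <- phyper(k - 1, n, M - n, N, lower.tail = FALSE)
  out <- tibble(k = as.integer(k), M = as.integer(M), n = as.integer(n),
                N = as.integer(N), point_prob = point, p_value = p)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
glance.enrichment_result <- function(x, ...) tibble::as_tibble(x)

#' Express a distance as a signed percentage of the random reference
#'
#' @param metric_value observed metric value.
#' @param random_value random-reference value (> 0).
#' @return `100 * (metric_value / random_value - 1)`.
#' @export
percent_vs_random <- function(metric_value, random_value) {
  assert_that(is.numeric(random_value) && all(random_value > 0),
              "`random_value` must be positive")
  100 * (metric_value / random_value - 1)
}

#' Full network evaluation of a gene signature
#'
#' Convenience wrapper: extracts the disease module, computes both
#' distance metrics, the random reference and the hypergeometric overlap
#' test of the signature against the disease gene list.
#'
#' @param signature character vector of selected gene symbols.
#' @param g the interactome graph.
#' @param disease_genes character vector of disease gene symbols.
#' @param n_random random-signature size.
#' @param seeds random-reference seeds.
#' @return list with `module`, `intra`, `to_module`, `random`,
#'   `intra_vs_random_pct`, `to_module_vs_random_pct`, `enrichment`.
#' @export
evaluate_signature <- function(signature, g, disease_genes,
                               n_random = 100, seeds = 1:4) {
  module <- extract_lcc(disease_genes, g)
  intra <- intra_signature_distance(signature, g)
  to_mod <- distance_to_module(signature, module, g)
  rnd <- random_reference(g, module, n_random, seeds)
  present <- intersect(signature, igraph::V(g)$name)
  disease_present <- intersect(disease_genes, igraph::V(g)$name)
  enr <- hypergeom_test(length(intersect(present, disease_present)),
                        igraph::vcount(g), length(disease_present),
                        length(present))
  list(module = module, intra = intra, to_module = to_mod, random = rnd,
       intra_vs_random_pct = percent_vs_random(intra$mean,
                                               rnd$grand$intra),
       to_module_vs_random_pct = percent_vs_random(to_mod$mean,
                                                   rnd$grand$to_module),
       enrichment = enr)
}
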