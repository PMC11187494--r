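# Majority-voting ensemble baselines. Both use only the marginal
# (per-feature) evidence — the diagonal of the co-selection matrix or the
# mean importance — which is exactly what the graph methods add to.

#' Majority-voting feature selection
#'
#' Keeps the `k` features most frequently selected across all
#' (selector, fold) slices; ties break lexicographically. The objective
#' records the sum of the k winning counts.
#'
#' @param B a `selection_tensor`.
#' @param k signature size.
#' @return a `ge_signature` with `method = "mv"`.
#' @export
mv_select <- function(B, k) {
  assert_that(inherits(B, "selection_tensor"),
              "`B` must be a selection_tensor")
  d <- dim(B)
  assert_that(k >= 1 && k <= d[3], "`k` out of range")
  counts <- apply(B, 3, sum)
  ids <- dimnames(B)[[3]]
  ord <- order_desc_lex(counts, ids)
  take <- ord[seq_len(k)]
  new_signature(ids[take], k, sum(counts[take]), "mv", NULL,
                setNames(counts[take], ids[take]))
}

#' Weighted majority-voting feature selection
#'
#' Keeps the `k` features with the highest mean importance over all
#' (selector, fold) slices — slices where a selector grants a feature no
#' importance contribute 0 to the mean. Ties break lexicographically.
#'
#' @param I an `importance_tensor`.
#' @param k signature size.
#' @return a `ge_signature` with `method = "wmv"`.
#' @export
wmv_select <- function(I, k) {
  validate_importance_tensor(I)
  d <- dim(I)
  assert_that(k >= 1 && k <= d[3], "`k` out of range")
  means <- apply(I, 3, mean)
  ids <- dimnames(I)[[3]]
  ord <- order_desc_lex(means, ids)
  take <- ord[seq_len(k)]
  new_signature(ids[take], k, sum(means[take]), "wmv", NULL,
                setNames(means[take], ids[take]))
}
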