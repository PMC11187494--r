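#' Rescale raw selector scores to the unit interval
#'
#' Divides a vector of non-negative raw importance scores by its maximum so
#' that the best feature scores exactly 1. This puts heterogeneous base
#' selectors (F statistics, impurity importances, |r| values, ...) on a
#' common scale before they are summed into co-importance weights. An
#' all-zero vector is returned unchanged.
#'
#' @param raw numeric vector of finite, non-negative raw scores.
#' @return numeric vector in `[0, 1]` with `max == 1` unless all-zero.
#' @examples
#' normalize_importance(c(2, 4, 0))
#' @export
normalize_importance <- function(raw) {
  assert_that(is.numeric(raw), "`raw` must be numeric")
  assert_that(all(is.finite(raw)), "raw importances must be finite")
  assert_that(all(raw >= 0), "raw importances must be non-negative")
  m <- max(raw)
  if (m == 0) return(raw)
  raw / m
}

new_importance_tensor <- function(values, selector_ids, fold_ids, feature_ids) {
  stopifnot(length(dim(values)) == 3)
  dimnames(values) <- list(selector = selector_ids,
                           fold = fold_ids,
                           feature = feature_ids)
  structure(values, class = c("importance_tensor", "array"))
}

validate_importance_tensor <- function(x) {
  assert_that(inherits(x, "importance_tensor") ||
                (is.array(x) && length(dim(x)) == 3),
              "expected a 3-way importance tensor")
  assert_that(all(is.finite(x)), "tensor values must be finite")
  assert_that(all(x >= 0 & x <= 1), "tensor values must lie in [0, 1]")
  invisible(x)
}

#' @export
print.importance_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<importance_tensor> %d selector(s) x %d fold(s) x %d feature(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  values in [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

#' Turn an importance or selection tensor into a long tibble
#'
#' @param x an `importance_tensor` or `selection_tensor`.
#' @param ... unused.
#' @return a tibble with columns `selector`, `fold`, `feature`, `value`.
#' @export
tidy.importance_tensor <- function(x, ...) {
  dn <- dimnames(x)
  grid <- expand.grid(selector = dn[[1]], fold = dn[[2]],
                      feature = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(cbind(grid, value = as.vector(x)))
}

#' @export
tidy.selection_tensor <- function(x, ...) tidy.importance_tensor(x, ...)

#' Binarize an importance tensor into per-fold selection events
#'
#' For every (selector, fold) slice the `t` features with the highest
#' normalized importance are marked selected (value 1). Ties are broken by
#' lexicographic feature id; features with zero importance are never
#' selected, so a slice with fewer than `t` positive scores selects only
#' the positive ones. A selection event is what the co-selection matrix
#' counts: two features co-selected on a slice contribute one count to
#' their pair.
#'
#' @param tensor an `importance_tensor`.
#' @param t per-fold selection budget (positive integer). Values larger
#'   than the number of features are clamped with a warning.
#' @return a `selection_tensor` (0/1 array with the same dimensions), with
#'   the budget stored in attribute `budget`.
#' @export
binarize <- function(tensor, t) {
  validate_importance_tensor(tensor)
  assert_that(length(t) == 1 && is.finite(t) && t >= 1,
              "`t` must be a positive integer")
  t <- as.integer(t)
  d <- dim(tensor)
  if (t > d[3]) {
    warn(sprintf("budget t = %d exceeds %d features; clamped", t, d[3]))
    t <- d[3]
  }
  feature_ids <- dimnames(tensor)[[3]]
  out <- array(0, dim = d)
  for (f in seq_len(d[1])) {
    for (s in seq_len(d[2])) {
      v <- tensor[f, s, ]
      pos <- which(v > 0)
      if (length(pos) == 0) next
      ord <- pos[order_desc_lex(v[pos], feature_ids[pos])]
      take <- ord[seq_len(min(t, length(ord)))]
      out[f, s, take] <- 1
    }
  }
  out <- new_importance_tensor(out, dimnames(tensor)[[1]],
                               dimnames(tensor)[[2]], feature_ids)
  class(out) <- c("selection_tensor", "array")
  attr(out, "budget") <- t
  out
}

#' @export
print.selection_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<selection_tensor> %d selector(s) x %d fold(s) x %d feature(s), budget t = %d\n",
              d[1], d[2], d[3], attr(x, "budget")))
  invisible(x)
}

#' Write / read an importance tensor as long CSV plus a JSON sidecar
#'
#' The tensor is stored as a long-format CSV (`selector,fold,feature,value`)
#' with a JSON sidecar recording the dimension labels, so round-trips
#' preserve dimension order exactly.
#'
#' @param tensor an `importance_tensor` or `selection_tensor`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly (`write_`), or the reconstructed tensor
#'   (`read_`).
#' @export
write_importance_tensor <- function(tensor, path) {
  readr::write_csv(tidy.importance_tensor(tensor), path)
  dn <- dimnames(tensor)
  jsonlite::write_json(
    list(selector_ids = dn[[1]], fold_ids = dn[[2]],
         feature_ids = dn[[3]],
         budget = attr(tensor, "budget")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_importance_tensor
#' @export
read_importance_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- readr::read_csv(path, show_col_types = FALSE)
  arr <- array(0, dim = c(length(meta$selector_ids), length(meta$fold_ids),
                          length(meta$feature_ids)))
  idx <- cbind(match(long$selector, meta$selector_ids),
               match(long$fold, as.character(meta$fold_ids)),
               match(long$feature, meta$feature_ids))
  arr[idx] <- long$value
  out <- new_importance_tensor(arr, meta$selector_ids,
                               as.character(meta$fold_ids), meta$feature_ids)
  if (!is.null(meta$budget)) {
    class(out) <- c("selection_tensor", "array")
    attr(out, "budget") <- meta$budget
  }
  out
}
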