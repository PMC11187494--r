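#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr arrange desc filter mutate summarise group_by ungroup
#'   bind_rows left_join select n_distinct across all_of slice_head pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr imap keep
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_boxplot geom_segment
#'   geom_point labs coord_flip theme_minimal facet_wrap
#' @importFrom generics tidy glance
#' @importFrom stats var sd cor quantile rnorm runif predict coef setNames
#'   dhyper phyper
#' @importFrom utils combn head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Deterministic 31-bit seed derived from a base seed and a mixed key
# (integers and/or strings); used to give every stochastic component its
# own reproducible stream.
derive_seed <- function(seed, ...) {
  key <- list(...)
  x <- as.double(seed %% 2147483647L)
  for (k in key) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = "|")))
    for (ki in as.double(k)) {
      x <- (x * 69069 + ki + 12345) %% 2147483647
    }
  }
  as.integer(x)
}

# TRUE if sorted character vector a precedes b lexicographically
# (element-wise; equal-length assumed).
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Order by decreasing numeric value, ties broken by increasing id.
order_desc_lex <- function(value, id) {
  order(-value, id, method = "radix")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Split a feature-table tibble into its parts. The contract is a sample-id
# column, real-valued feature columns and one categorical label column.
table_parts <- function(data, label_col = "label", id_col = "sample_id") {
  assert_that(is.data.frame(data), "`data` must be a data frame")
  assert_that(label_col %in% names(data),
              paste0("label column '", label_col, "' not found"))
  assert_that(id_col %in% names(data),
              paste0("sample id column '", id_col, "' not found"))
  feat_cols <- setdiff(names(data), c(label_col, id_col))
  assert_that(length(feat_cols) >= 1, "no feature columns found")
  values <- as.matrix(data[feat_cols])
  storage.mode(values) <- "double"
  assert_that(!anyNA(values), "feature values contain missing entries")
  sample_ids <- as.character(data[[id_col]])
  assert_that(!anyDuplicated(sample_ids), "duplicate sample ids")
  assert_that(!anyDuplicated(feat_cols), "duplicate feature ids")
  labels <- factor(data[[label_col]])
  assert_that(nlevels(labels) >= 2, "need at least two distinct label values")
  rownames(values) <- sample_ids
  list(sample_ids = sample_ids, feature_ids = feat_cols,
       values = values, labels = labels)
}
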