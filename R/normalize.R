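#' Fit a z-score normalizer on training rows only
#'
#' Estimates per-feature location (mean) and scale (sample SD) from the
#' training rows alone, so validation and test rows never leak into
#' preprocessing. Constant features get scale 1 (with a warning) and map
#' to 0.
#'
#' @param train_values numeric matrix of training rows (samples x
#'   features) with feature column names.
#' @return an object of class `normalizer` with fields `center`, `scale`,
#'   `feature_ids`.
#' @export
fit_normalizer <- function(train_values) {
  assert_that(is.matrix(train_values) && is.numeric(train_values),
              "`train_values` must be a numeric matrix")
  center <- colMeans(train_values)
  scale <- apply(train_values, 2, sd)
  const <- !is.finite(scale) | scale == 0
  if (any(const)) {
    warn(sprintf("%d constant feature(s); scale set to 1", sum(const)))
    scale[const] <- 1
  }
  structure(list(center = center, scale = scale,
                 feature_ids = colnames(train_values)),
            class = "normalizer")
}

#' Apply a fitted normalizer to any row set
#'
#' @param model a `normalizer` from [fit_normalizer()].
#' @param values numeric matrix whose columns match the fitted feature ids.
#' @return the z-scored matrix.
#' @export
apply_normalizer <- function(model, values) {
  assert_that(inherits(model, "normalizer"), "`model` must be a normalizer")
  assert_that(identical(colnames(values), model$feature_ids),
              "feature ids do not match the fitted normalizer")
  sweep(sweep(values, 2, model$center, "-"), 2, model$scale, "/")
}
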