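#' Define a sanity/efficiency model-selection rule
#'
#' The rule keeps candidates whose fold-averaged train and validation
#' values of the primary metric agree within `sanity_threshold` (the
#' sanity constraint, an overfitting guard) and, among those, picks the
#' best mean validation value (the efficiency constraint).
#'
#' @param primary_metric one of `"BA"`, `"WP"`, `"WR"`, `"WF"`.
#' @param sanity_threshold maximal tolerated |train - validation| gap,
#'   in (0, 1].
#' @param fallback what to do when no candidate passes the sanity
#'   constraint: `"min_gap"` returns the smallest-gap candidate with a
#'   warning, `"error"` aborts.
#' @return an object of class `selection_rule`.
#' @export
selection_rule <- function(primary_metric = "BA", sanity_threshold = 0.10,
                           fallback = c("min_gap", "error")) {
  assert_that(primary_metric %in% c("BA", "WP", "WR", "WF"),
              "unknown primary metric")
  assert_that(sanity_threshold > 0 && sanity_threshold <= 1,
              "`sanity_threshold` must be in (0, 1]")
  structure(list(primary_metric = primary_metric,
                 sanity_threshold = sanity_threshold,
                 fallback = match.arg(fallback)),
            class = "selection_rule")
}

#' Apply the model-selection rule to candidate performances
#'
#' @param candidates per-fold performance tibble from
#'   [train_candidates()] (columns `model_id`, `fold`, `split`, metrics).
#' @param rule a [selection_rule()].
#' @return the selected `model_id` (a string), with the per-model summary
#'   attached as attribute `"summary"`.
#' @export
select_model <- function(candidates, rule = selection_rule()) {
  assert_that(inherits(rule, "selection_rule"),
              "`rule` must be a selection_rule")
  assert_that(is.data.frame(candidates) && nrow(candidates) > 0,
              "`candidates` must be a non-empty performance tibble")
  pm <- rule$primary_metric
  summ <- candidates |>
    dplyr::group_by(.data$model_id, .data$split) |>
    dplyr::summarise(value = mean(.data[[pm]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "split", values_from = "value") |>
    dplyr::mutate(gap = abs(.data$train - .data$validation),
                  pass = .data$gap <= rule$sanity_threshold) |>
    dplyr::arrange(dplyr::desc(.data$validation), .data$gap, .data$model_id)
  passing <- dplyr::filter(summ, .data$pass)
  if (nrow(passing) > 0) {
    pick <- passing$model_id[1]
  } else if (rule$fallback == "min_gap") {
    warn("no candidate satisfies the sanity constraint; falling back to the minimal-gap candidate")
    fallback <- dplyr::arrange(summ, .data$gap, .data$model_id)
    pick <- fallback$model_id[1]
  } else {
    abort(sprintf(
      "no candidate has |train - validation| %s gap <= %.3f",
      pm, rule$sanity_threshold))
  }
  structure(pick, summary = summ)
}
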