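#' Multi-class classification metrics
#'
#' Computes Balanced Accuracy (BA, the unweighted mean of per-class
#' recalls), and support-weighted Precision (WP), Recall (WR) and F1 (WF).
#' Classes never predicted get precision 0 for weighting purposes; classes
#' absent from the truth contribute nothing (zero support).
#'
#' @param true_labels,predicted_labels equal-length label vectors;
#'   predictions must come from the training label set.
#' @return a one-row tibble with columns `BA`, `WP`, `WR`, `WF`, all in
#'   `[0, 1]`.
#' @export
compute_metrics <- function(true_labels, predicted_labels) {
  assert_that(length(true_labels) > 0, "empty label vectors")
  assert_that(length(true_labels) == length(predicted_labels),
              "label vectors differ in length")
  lv <- sort(unique(c(as.character(true_labels),
                      as.character(predicted_labels))))
  truth <- factor(as.character(true_labels), levels = lv)
  pred <- factor(as.character(predicted_labels), levels = lv)
  cm <- table(truth, pred)
  support <- rowSums(cm)
  present <- support > 0
  tp <- diag(cm)
  recall <- ifelse(present, tp / pmax(support, 1), NA_real_)
  pred_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pmax(pred_tot, 1), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  n <- sum(support)
  tibble(
    BA = mean(recall[present]),
    WP = sum(precision[present] * support[present]) / n,
    WR = sum(recall[present] * support[present]) / n,
    WF = sum(f1[present] * support[present]) / n
  )
}
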