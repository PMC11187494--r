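# Candidate classifiers. Each entry is fit(x, y, seed) -> model plus
# prob(model, x) -> class-probability matrix (columns = levels(y)). The
# default roster is small and deterministic: regularized logistic
# regression, a random forest, 5-nearest-neighbours, Gaussian naive
# Bayes, plus a soft-voting ensemble of the top validation performers.

classifier_registry <- new.env(parent = emptyenv())

#' Register or list candidate classifiers
#'
#' A classifier is a list with `fit(x, y, seed)` returning a fitted
#' object and `prob(model, x)` returning an `n x nlevels(y)` probability
#' matrix with columns named by class.
#'
#' @param classifier_id model name.
#' @param fit,prob the two functions described above.
#' @return `register_classifier()` returns the id invisibly;
#'   `list_classifiers()` the registered ids; `default_classifier_roster()`
#'   the default ids (the soft-voting ensemble `soft_vote` is assembled by
#'   [train_candidates()] from the top base models).
#' @export
register_classifier <- function(classifier_id, fit, prob) {
  assign(classifier_id, list(fit = fit, prob = prob),
         envir = classifier_registry)
  invisible(classifier_id)
}

#' @rdname register_classifier
#' @export
list_classifiers <- function() sort(ls(classifier_registry))

#' @rdname register_classifier
#' @export
default_classifier_roster <- function() {
  c("logistic", "random_forest", "knn5", "naive_bayes", "soft_vote")
}

fit_logistic <- function(x, y, seed) {
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  list(fit = glmnet::glmnet(x, y, family = fam, alpha = 0,
                            standardize = FALSE),
       levels = levels(y), family = fam)
}

prob_logistic <- function(model, x) {
  p <- predict(model$fit, newx = x, s = 0.01, type = "response")
  if (model$family == "binomial") {
    p <- drop(p)
    out <- cbind(1 - p, p)
    colnames(out) <- model$levels
  } else {
    out <- p[, , 1]
    out <- out[, model$levels, drop = FALSE]
  }
  out
}

fit_random_forest <- function(x, y, seed) {
  df <- data.frame(x, check.names = FALSE)
  list(fit = ranger::ranger(x = df, y = y, num.trees = 300,
                            probability = TRUE, seed = seed,
                            num.threads = 1),
       levels = levels(y))
}

prob_random_forest <- function(model, x) {
  p <- predict(model$fit, data = data.frame(x, check.names = FALSE),
               num.threads = 1)$predictions
  p[, model$levels, drop = FALSE]
}

# lazy learner: the "model" is the training data; the prediction seed
# fixes k-NN tie-breaking
fit_knn5 <- function(x, y, seed) {
  list(x = x, y = y, seed = seed, levels = levels(y))
}

prob_knn5 <- function(model, x) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(model$seed)
  k <- min(5, nrow(model$x))
  pred <- class::knn(model$x, x, model$y, k = k, prob = TRUE)
  p_win <- attr(pred, "prob")
  lv <- model$levels
  out <- matrix((1 - p_win) / max(length(lv) - 1, 1), nrow = length(pred),
                ncol = length(lv), dimnames = list(NULL, lv))
  out[cbind(seq_along(pred), match(as.character(pred), lv))] <- p_win
  out
}

fit_naive_bayes <- function(x, y, seed) {
  list(fit = e1071::naiveBayes(data.frame(x, check.names = FALSE), y),
       levels = levels(y))
}

prob_naive_bayes <- function(model, x) {
  p <- predict(model$fit, data.frame(x, check.names = FALSE), type = "raw",
               threshold = 1e-3, eps = 1e-8)
  p[, model$levels, drop = FALSE]
}

register_default_classifiers <- function() {
  register_classifier("logistic", fit_logistic, prob_logistic)
  register_classifier("random_forest", fit_random_forest, prob_random_forest)
  register_classifier("knn5", fit_knn5, prob_knn5)
  register_classifier("naive_bayes", fit_naive_bayes, prob_naive_bayes)
}

prob_to_class <- function(p) {
  lv <- colnames(p)
  # lexicographic tie-break: max.col on the lexicographically ordered
  # columns with ties.method "first"
  p <- p[, sort(lv), drop = FALSE]
  factor(sort(lv)[max.col(p, ties.method = "first")], levels = lv)
}

#' Train candidate classifiers over the cross-validation folds
#'
#' Fits each roster classifier per fold on the normalized,
#' signature-restricted training rows and records train and validation
#' metrics. If the roster contains `"soft_vote"`, a soft-voting ensemble
#' of the (up to) 3 base models with the best mean validation BA is
#' evaluated as an additional candidate by averaging their class
#' probabilities. Fully deterministic given `seed`; a classifier failing
#' on a fold is dropped with a warning.
#'
#' @param data feature-table tibble.
#' @param plan a `split_plan`.
#' @param signature a `ge_signature`, a character vector of feature ids,
#'   or `NULL` to use all features.
#' @param roster character vector of classifier ids.
#' @param seed integer seed.
#' @param keep_models if `TRUE`, attach the per-fold fitted objects as
#'   attribute `"models"` (used for leakage audits).
#' @param label_col,id_col column names.
#' @return a tibble of per-fold performance: `model_id`, `fold`, `split`
#'   (`train`/`validation`), `BA`, `WP`, `WR`, `WF`.
#' @export
train_candidates <- function(data, plan, signature = NULL,
                             roster = default_classifier_roster(),
                             seed = 1L, keep_models = FALSE,
                             label_col = "label", id_col = "sample_id") {
  parts <- table_parts(data, label_col, id_col)
  feats <- signature_features(signature, parts$feature_ids)
  want_vote <- "soft_vote" %in% roster
  base <- setdiff(roster, "soft_vote")
  assert_that(length(base) >= 1, "roster needs at least one base classifier")
  unknown <- setdiff(base, list_classifiers())
  assert_that(length(unknown) == 0,
              paste("unknown classifier(s):", paste(unknown, collapse = ", ")))
  rows <- list(); probs <- list(); models <- list()
  truths <- list()
  for (s in seq_len(plan$n_folds)) {
    tr <- plan$folds[[s]]$train
    va <- plan$folds[[s]]$validation
    xtr <- parts$values[tr, feats, drop = FALSE]
    norm <- suppressWarnings(fit_normalizer(xtr))
    xtr_n <- apply_normalizer(norm, xtr)
    xva_n <- apply_normalizer(norm, parts$values[va, feats, drop = FALSE])
    ytr <- parts$labels[tr]; yva <- parts$labels[va]
    truths[[s]] <- list(train = ytr, validation = yva)
    for (m in base) {
      entry <- get(m, envir = classifier_registry)
      res <- tryCatch({
        fit <- entry$fit(xtr_n, ytr, derive_seed(seed, m, s))
        list(fit = fit,
             p_tr = entry$prob(fit, xtr_n),
             p_va = entry$prob(fit, xva_n))
      }, error = function(e) {
        warn(sprintf("classifier '%s' failed on fold %d: %s",
                     m, s, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      probs[[m]][[s]] <- list(train = res$p_tr, validation = res$p_va)
      if (keep_models) models[[m]][[s]] <- res$fit
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(model_id = m, fold = s, split = "train"),
        compute_metrics(ytr, prob_to_class(res$p_tr)))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(model_id = m, fold = s, split = "validation"),
        compute_metrics(yva, prob_to_class(res$p_va)))
    }
  }
  perf <- dplyr::bind_rows(rows)
  vote_members <- character(0)
  if (want_vote && nrow(perf) > 0) {
    ok <- names(probs)[vapply(probs, function(pl)
      sum(!vapply(pl, is.null, TRUE)) == plan$n_folds, TRUE)]
    rank_tbl <- perf |>
      dplyr::filter(.data$split == "validation", .data$model_id %in% ok) |>
      dplyr::group_by(.data$model_id) |>
      dplyr::summarise(val = mean(.data$BA), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$val), .data$model_id)
    vote_members <- head(rank_tbl$model_id, 3)
    if (length(vote_members) >= 2) {
      for (s in seq_len(plan$n_folds)) {
        p_tr <- Reduce(`+`, lapply(vote_members, function(m)
          probs[[m]][[s]]$train)) / length(vote_members)
        p_va <- Reduce(`+`, lapply(vote_members, function(m)
          probs[[m]][[s]]$validation)) / length(vote_members)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(model_id = "soft_vote", fold = s, split = "train"),
          compute_metrics(truths[[s]]$train, prob_to_class(p_tr)))
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(model_id = "soft_vote", fold = s, split = "validation"),
          compute_metrics(truths[[s]]$validation, prob_to_class(p_va)))
      }
      perf <- dplyr::bind_rows(rows)
    }
  }
  perf <- dplyr::arrange(perf, .data$model_id, .data$fold, .data$split)
  attr(perf, "vote_members") <- vote_members
  if (keep_models) attr(perf, "models") <- models
  perf
}

signature_features <- function(signature, feature_ids) {
  feats <- if (is.null(signature)) feature_ids
  else if (inherits(signature, "ge_signature")) signature$feature_ids
  else as.character(signature)
  missing <- setdiff(feats, feature_ids)
  assert_that(length(missing) == 0,
              paste("signature features not in table:",
                    paste(missing, collapse = ", ")))
  feats
}
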