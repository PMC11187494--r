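# Base feature-selection techniques. Each scorer maps a (normalized)
# training matrix and its labels to one non-negative raw score per feature;
# scores are only compared within a (selector, fold) slice, so scale does
# not matter before normalize_importance().

selector_registry <- new.env(parent = emptyenv())

#' Register or list base feature selectors
#'
#' A selector is a function `f(x, y, seed)` taking a numeric training
#' matrix `x` (samples x features), a factor `y` of labels and an integer
#' seed, returning one finite non-negative score per feature. Co-graph
#' ensembling aggregates *complementary* per-split selections, so the
#' default roster is dominated by sparse and multivariate techniques that
#' avoid scoring redundant copies of the same signal equally: lasso
#' path-entry order, lasso coefficient magnitudes, greedy
#' minimum-redundancy maximum-relevance, forward selection by partial
#' correlation, gradient-boosted-tree gain, random-forest impurity, plus
#' one univariate filter (the F statistic). Additional registered scorers
#' (`abs_cor`, `mutual_info`, `variance`, `chi2`) can be swapped in
#' freely.
#'
#' @param selector_id selector name.
#' @param fn scorer function (see above).
#' @return `register_selector()` returns `selector_id` invisibly;
#'   `list_selectors()` the registered ids; `default_selector_roster()` the
#'   seven default ids.
#' @export
register_selector <- function(selector_id, fn) {
  assert_that(is.character(selector_id) && length(selector_id) == 1,
              "`selector_id` must be a single string")
  assert_that(is.function(fn), "`fn` must be a function")
  assign(selector_id, fn, envir = selector_registry)
  invisible(selector_id)
}

#' @rdname register_selector
#' @export
list_selectors <- function() sort(ls(selector_registry))

#' @rdname register_selector
#' @export
default_selector_roster <- function() {
  c("l1_path", "l1_coef", "mrmr", "pcor_step", "xgb_gain",
    "rf_impurity", "f_stat")
}

#' Run one registered selector on fold-training data
#'
#' @param selector_id registered selector name.
#' @param train_values numeric matrix of fold-training rows.
#' @param train_labels factor of matching labels.
#' @param seed integer seed threaded into stochastic selectors.
#' @return raw non-negative importance vector, one score per feature.
#' @export
run_selector <- function(selector_id, train_values, train_labels, seed = 1L) {
  if (!exists(selector_id, envir = selector_registry, inherits = FALSE)) {
    abort(sprintf("unknown selector '%s'; see list_selectors()", selector_id))
  }
  y <- factor(train_labels)
  assert_that(all(table(y) >= 2), "need at least 2 samples per class")
  if (all(apply(train_values, 2, function(v) max(v) == min(v)))) {
    warn(sprintf("constant feature matrix: selector '%s' returns all zeros",
                 selector_id))
    return(numeric(ncol(train_values)))
  }
  fn <- get(selector_id, envir = selector_registry)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, selector_id))
  raw <- fn(train_values, y, derive_seed(seed, selector_id))
  assert_that(length(raw) == ncol(train_values),
              "selector returned wrong number of scores")
  raw[!is.finite(raw) | raw < 0] <- 0
  raw
}

# --- default scorers ------------------------------------------------------

# one-way ANOVA F statistic per feature, vectorized over columns
score_f_stat <- function(x, y, seed) {
  n <- nrow(x); g <- nlevels(y)
  grand <- colMeans(x)
  ssb <- numeric(ncol(x)); ssw <- numeric(ncol(x))
  for (cl in levels(y)) {
    rows <- y == cl
    m <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  f <- (ssb / (g - 1)) / pmax(ssw / (n - g), .Machine$double.eps)
  f[ssb == 0] <- 0
  f
}

# plug-in mutual information after equal-frequency binning
score_mutual_info <- function(x, y, seed, n_bins = 5) {
  apply(x, 2, function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(0)  # (near-)constant feature
    b <- cut(v, breaks = br, include.lowest = TRUE)
    tab <- table(b, y)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    idx <- p > 0
    sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
  })
}

score_abs_cor <- function(x, y, seed) {
  r <- suppressWarnings(cor(x, as.numeric(y)))
  r[!is.finite(r)] <- 0
  abs(drop(r))
}

# lasso path-entry order: a feature's score is the largest lambda at
# which its coefficient becomes nonzero. Correlated copies of a signal
# enter late (or never), so per-split rankings are complementary and
# nearly redundancy-free — the property co-graph ensembling aggregates.
score_l1_path <- function(x, y, seed) {
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(x, y, family = fam, alpha = 1, standardize = FALSE)
  nz <- if (fam == "multinomial") {
    Reduce(`|`, lapply(fit$beta, function(m) as.matrix(m) != 0))
  } else {
    as.matrix(fit$beta) != 0
  }
  entry <- apply(nz, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  unname(ifelse(is.na(entry), 0, fit$lambda[entry]))
}

# greedy minimum-redundancy maximum-relevance ranking: relevance is the
# absolute label correlation, redundancy the mean absolute correlation
# with already-picked features; the first `m` picks get linearly
# decaying scores, the rest 0
score_mrmr <- function(x, y, seed, m = 20) {
  rel <- suppressWarnings(abs(cor(x, as.numeric(y))))
  rel[!is.finite(rel)] <- 0
  rel <- drop(rel)
  p <- ncol(x)
  score <- numeric(p)
  picked <- integer(0)
  cand <- which(apply(x, 2, var) > 0)  # constant features never ranked
  m <- min(m, length(cand))
  for (j in seq_len(m)) {
    crit <- if (j == 1) rel[cand] else {
      red <- rowMeans(abs(suppressWarnings(
        cor(x[, cand, drop = FALSE], x[, picked, drop = FALSE]))),
        na.rm = TRUE)
      red[!is.finite(red)] <- 1
      rel[cand] - red
    }
    b <- cand[which.max(crit)]
    score[b] <- (m + 1 - j) / m
    picked <- c(picked, b)
    cand <- setdiff(cand, b)
  }
  score
}

# forward selection by partial correlation: pick the feature most
# correlated with the (residualized) label, project it out of the
# remaining features and the label, repeat; conditioning makes
# consecutive picks complementary
score_pcor_step <- function(x, y, seed, m = 20) {
  ry <- as.numeric(y)
  p <- ncol(x)
  xs <- x
  score <- numeric(p)
  cand <- which(apply(x, 2, var) > 0)  # constant features never ranked
  m <- min(m, length(cand))
  for (j in seq_len(m)) {
    r <- suppressWarnings(abs(cor(xs[, cand, drop = FALSE], ry)))
    r[!is.finite(r)] <- 0
    b <- cand[which.max(r)]
    score[b] <- (m + 1 - j) / m
    cand <- setdiff(cand, b)
    v <- xs[, b]
    ss <- sum(v^2)
    if (ss > 1e-12 && length(cand) > 0) {
      beta <- drop(crossprod(xs[, cand, drop = FALSE], v)) / ss
      xs[, cand] <- xs[, cand, drop = FALSE] - outer(v, beta)
      ry <- ry - v * sum(ry * v) / ss
    }
  }
  score
}

# gradient-boosted-tree gain importance; boosting reuses one
# representative of a correlated group, keeping per-split selections sparse
score_xgb_gain <- function(x, y, seed) {
  n_cls <- nlevels(y)
  params <- list(max_depth = 3, eta = 0.3, nthread = 1, seed = seed)
  if (n_cls == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- n_cls
  }
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1)
  fit <- xgboost::xgb.train(params = params, data = d, nrounds = 50,
                            verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  sc <- setNames(numeric(ncol(x)), colnames(x))
  sc[imp$Feature] <- imp$Gain
  unname(sc)
}

# lasso coefficient magnitudes taken one decade down the lambda path
score_l1_coef <- function(x, y, seed) {
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(x, y, family = fam, alpha = 1, standardize = FALSE)
  s <- fit$lambda[1] * 0.1
  cf <- coef(fit, s = s)
  if (is.list(cf)) {
    beta <- Reduce(`+`, lapply(cf, function(m) abs(as.matrix(m)[-1, 1])))
  } else {
    beta <- abs(as.matrix(cf)[-1, 1])
  }
  unname(beta)
}

score_rf_impurity <- function(x, y, seed) {
  df <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = y, num.trees = 300,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  pmax(fit$variable.importance, 0)
}

score_variance <- function(x, y, seed) apply(x, 2, var)

# chi-squared statistic on class-wise sums of min-shifted values
score_chi2 <- function(x, y, seed) {
  xs <- sweep(x, 2, apply(x, 2, min), "-")
  obs <- rowsum(xs, y)                      # classes x features
  feat_tot <- colSums(obs)
  cls_tot <- rowSums(obs)
  grand <- sum(feat_tot)
  if (grand == 0) return(numeric(ncol(x)))
  expd <- outer(cls_tot, feat_tot) / grand
  chi <- colSums(ifelse(expd > 0, (obs - expd)^2 / expd, 0))
  chi[feat_tot == 0] <- 0
  chi
}

register_default_selectors <- function() {
  register_selector("l1_path", score_l1_path)
  register_selector("l1_coef", score_l1_coef)
  register_selector("mrmr", score_mrmr)
  register_selector("pcor_step", score_pcor_step)
  register_selector("xgb_gain", score_xgb_gain)
  register_selector("rf_impurity", score_rf_impurity)
  register_selector("f_stat", score_f_stat)
  register_selector("abs_cor", score_abs_cor)
  register_selector("mutual_info", score_mutual_info)
  register_selector("variance", score_variance)
  register_selector("chi2", score_chi2)
}

#' Build the selector x fold x feature importance tensor
#'
#' Runs every selector of `roster` on each cross-validation fold's
#' training rows (z-scored with a normalizer fitted on those rows only)
#' and stores the min-max normalized importances. Validation and test rows
#' never touch selector fitting, and the result is fully determined by
#' `seed`. A selector failing on a fold yields an all-zero slice with a
#' warning rather than an error.
#'
#' @param data feature-table tibble.
#' @param plan a `split_plan` from [make_split_plan()].
#' @param roster character vector of registered selector ids.
#' @param seed integer seed.
#' @param label_col,id_col column names of label and sample id.
#' @return an `importance_tensor` with dimensions (selector, fold,
#'   feature), values in `[0, 1]`.
#' @export
build_importance_tensor <- function(data, plan,
                                    roster = default_selector_roster(),
                                    seed = 1L,
                                    label_col = "label",
                                    id_col = "sample_id") {
  assert_that(inherits(plan, "split_plan"), "`plan` must be a split_plan")
  assert_that(length(roster) >= 1, "`roster` must be non-empty")
  parts <- table_parts(data, label_col, id_col)
  n_f <- length(roster); n_s <- plan$n_folds
  arr <- array(0, dim = c(n_f, n_s, length(parts$feature_ids)))
  for (s in seq_len(n_s)) {
    tr <- plan$folds[[s]]$train
    xtr <- parts$values[tr, , drop = FALSE]
    norm <- suppressWarnings(fit_normalizer(xtr))
    xn <- apply_normalizer(norm, xtr)
    ytr <- parts$labels[tr]
    for (f in seq_len(n_f)) {
      raw <- tryCatch(
        run_selector(roster[f], xn, ytr, seed = derive_seed(seed, "fold", s)),
        error = function(e) {
          warn(sprintf("selector '%s' failed on fold %d (%s); all-zero slice",
                       roster[f], s, conditionMessage(e)))
          numeric(ncol(xn))
        })
      arr[f, s, ] <- normalize_importance(raw)
    }
  }
  new_importance_tensor(arr, roster, as.character(seq_len(n_s)),
                        parts$feature_ids)
}
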