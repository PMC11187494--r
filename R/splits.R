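#' Build a stratified split plan: test holdout plus cross-validation folds
#'
#' Draws a stratified test holdout and partitions the remaining samples
#' into `n_folds` stratified cross-validation folds. The plan is fully
#' determined by `seed`; the test set is disjoint from every fold and is
#' touched exactly once, after model selection.
#'
#' @param data feature-table tibble (sample id column, feature columns,
#'   label column).
#' @param seed integer seed controlling the whole plan.
#' @param n_folds number of cross-validation folds (>= 2).
#' @param test_fraction fraction of samples held out for the final test,
#'   in (0, 0.5).
#' @param label_col,id_col column names of the label and sample id.
#' @return an object of class `split_plan`: list with `folds` (each a list
#'   with `train` and `validation` integer row indices), `test` (integer
#'   row indices), `seed`, `n_folds`.
#' @export
make_split_plan <- function(data, seed, n_folds = 5, test_fraction = 0.25,
                            label_col = "label", id_col = "sample_id") {
  assert_that(n_folds >= 2, "`n_folds` must be at least 2")
  assert_that(test_fraction > 0 && test_fraction < 0.5,
              "`test_fraction` must be in (0, 0.5)")
  parts <- table_parts(data, label_col, id_col)
  y <- parts$labels
  n <- length(y)
  test_idx <- integer(0)
  fold_of <- rep(NA_integer_, n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, "split_plan"))
  for (cl in levels(y)) {
    members <- which(y == cl)
    members <- members[sample.int(length(members))]
    n_test <- round(test_fraction * length(members))
    cl_test <- members[seq_len(n_test)]
    cl_rest <- setdiff(members, cl_test)
    if (length(cl_rest) < n_folds) {
      abort(sprintf(
        "class '%s' has %d non-test samples but %d folds are requested",
        cl, length(cl_rest), n_folds))
    }
    test_idx <- c(test_idx, cl_test)
    # round-robin assignment keeps per-fold class counts within +/- 1
    fold_of[cl_rest] <- rep_len(seq_len(n_folds), length(cl_rest))
  }
  test_idx <- sort(test_idx)
  rest <- which(!is.na(fold_of))
  folds <- lapply(seq_len(n_folds), function(s) {
    val <- rest[fold_of[rest] == s]
    list(train = setdiff(rest, val), validation = val)
  })
  structure(list(seed = seed, n_folds = n_folds, folds = folds,
                 test = test_idx, n_samples = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> seed %d: %d folds, %d test samples of %d total\n",
              x$seed, x$n_folds, length(x$test), x$n_samples))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
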