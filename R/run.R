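# End-to-end orchestration: split -> normalize -> importance tensor ->
# ensemble feature selection -> candidate training -> rule-based model
# selection -> one-shot test evaluation. The held-out test rows are
# touched exactly once, after the model is chosen.

#' Run the full graphical-ensembling experiment
#'
#' Executes the leakage-free pipeline on a labeled feature table:
#' stratified test holdout and cross-validation folds; per-fold
#' normalization fitted on fold-training rows only; base selectors run on
#' every fold to form the importance tensor; ensemble feature selection
#' (`k_w_heavy` on the co-importance graph, `k_heavy` on the co-selection
#' graph, `mv`/`wmv` baselines, or `none` for the all-features sanity
#' check); candidate classifiers trained on the signature; model selection
#' by the sanity/efficiency rule; finally, the selected model is refitted
#' on all non-test rows and evaluated once on the test set.
#'
#' @param data feature-table tibble (sample id column, feature columns,
#'   label column).
#' @param method ensemble method: `"k_w_heavy"`, `"k_heavy"`, `"mv"`,
#'   `"wmv"` or `"none"`.
#' @param k signature size (ignored for `method = "none"`).
#' @param seed integer master seed; every stochastic component derives its
#'   stream from it.
#' @param n_folds,test_fraction split-plan parameters.
#' @param selectors base selector roster.
#' @param t per-fold selection budget; default `2 * k`.
#' @param solver heaviest-subgraph solver (`"auto"`, `"exact"`,
#'   `"greedy"`).
#' @param max_nodes co-graph is pruned to this many highest-strength nodes
#'   before solving; must be at least `k`.
#' @param classifiers candidate classifier roster.
#' @param rule a [selection_rule()].
#' @param keep_models keep fitted per-fold objects (for audits).
#' @param label_col,id_col column names.
#' @return an object of class `ge_run`: list with `signature`,
#'   `candidates` (per-fold performance tibble), `selected_model`,
#'   `test_metrics` (one-row tibble), `timings`, and the configuration.
#' @export
run_experiment <- function(data,
                           method = c("k_w_heavy", "k_heavy", "mv", "wmv",
                                      "none"),
                           k = 5, seed = 1L, n_folds = 5,
                           test_fraction = 0.25,
                           selectors = default_selector_roster(),
                           t = NULL,
                           solver = c("auto", "exact", "greedy"),
                           max_nodes = 50,
                           classifiers = default_classifier_roster(),
                           rule = selection_rule(),
                           keep_models = FALSE,
                           label_col = "label", id_col = "sample_id") {
  method <- match.arg(method)
  solver <- match.arg(solver)
  if (method != "none") {
    assert_that(max_nodes >= k, "`max_nodes` must be at least `k`")
  }
  t <- as.integer(t %||% (2 * k))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  plan <- make_split_plan(data, seed, n_folds, test_fraction,
                          label_col, id_col)
  timings["split"] <- tic() - t0

  signature <- NULL; tensor <- NULL; graph <- NULL
  if (method != "none") {
    t0 <- tic()
    tensor <- build_importance_tensor(data, plan, selectors, seed,
                                      label_col, id_col)
    timings["importance_tensor"] <- tic() - t0
    t0 <- tic()
    signature <- switch(
      method,
      mv = mv_select(binarize(tensor, t), k),
      wmv = wmv_select(tensor, k),
      k_heavy = {
        graph <- co_graph_from_counts(
          build_co_selection_matrix(binarize(tensor, t)))
        solve_signature(prune_graph(graph, max_nodes), k, solver)
      },
      k_w_heavy = {
        graph <- build_co_importance_graph(tensor)
        solve_signature(prune_graph(graph, max_nodes), k, solver)
      })
    timings["feature_selection"] <- tic() - t0
  }

  t0 <- tic()
  candidates <- train_candidates(data, plan, signature, classifiers, seed,
                                 keep_models, label_col, id_col)
  timings["candidates"] <- tic() - t0

  t0 <- tic()
  selected <- select_model(candidates, rule)
  rule_summary <- attr(selected, "summary")
  selected <- as.character(selected)
  timings["model_selection"] <- tic() - t0

  # one-shot test evaluation: refit on all non-test rows, predict test
  t0 <- tic()
  parts <- table_parts(data, label_col, id_col)
  feats <- signature_features(signature, parts$feature_ids)
  rest <- setdiff(seq_along(parts$sample_ids), plan$test)
  xtr <- parts$values[rest, feats, drop = FALSE]
  norm <- suppressWarnings(fit_normalizer(xtr))
  xtr_n <- apply_normalizer(norm, xtr)
  xte_n <- apply_normalizer(norm, parts$values[plan$test, feats,
                                               drop = FALSE])
  ytr <- parts$labels[rest]
  members <- if (selected == "soft_vote")
    attr(candidates, "vote_members") else selected
  p_te <- Reduce(`+`, lapply(members, function(m) {
    entry <- get(m, envir = classifier_registry)
    fit <- entry$fit(xtr_n, ytr, derive_seed(seed, m, "final"))
    entry$prob(fit, xte_n)
  })) / length(members)
  test_metrics <- compute_metrics(parts$labels[plan$test],
                                  prob_to_class(p_te))
  timings["test_evaluation"] <- tic() - t0

  structure(list(method = method, k = if (method == "none") NA_integer_
                 else as.integer(k),
                 seed = seed, plan = plan, tensor = tensor,
                 graph = graph, signature = signature,
                 candidates = candidates, rule = rule,
                 rule_summary = rule_summary,
                 selected_model = selected,
                 test_metrics = test_metrics,
                 n_test = length(plan$test),
                 timings = timings),
            class = "ge_run")
}

#' @export
print.ge_run <- function(x, ...) {
  cat(sprintf("<ge_run> method %s, seed %d\n", x$method, x$seed))
  if (!is.null(x$signature)) {
    cat(sprintf("  signature (k = %d): %s\n", x$signature$k,
                paste(x$signature$feature_ids, collapse = ", ")))
  }
  cat(sprintf("  selected model: %s\n", x$selected_model))
  tm <- x$test_metrics
  cat(sprintf("  test: BA %.3f | WP %.3f | WR %.3f | WF %.3f (n = %d)\n",
              tm$BA, tm$WP, tm$WR, tm$WF, x$n_test))
  invisible(x)
}

#' Tidy / summarise a pipeline run
#'
#' `tidy()` returns the per-fold candidate performance table; `glance()` a
#' one-row summary with the selected model and test metrics.
#'
#' @param x a `ge_run`.
#' @param ... unused.
#' @export
tidy.ge_run <- function(x, ...) x$candidates

#' @rdname tidy.ge_run
#' @export
glance.ge_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(method = x$method, k = x$k, seed = x$seed,
           selected_model = x$selected_model, n_test = x$n_test),
    x$test_metrics)
}

#' Plot per-model validation performance of a run
#'
#' @param object a `ge_run`.
#' @param metric which metric to plot.
#' @param ... unused.
#' @return a ggplot: per-fold train/validation boxplots by model.
#' @export
autoplot.ge_run <- function(object, metric = "BA", ...) {
  ggplot(object$candidates,
         aes(x = .data$model_id, y = .data[[metric]],
             fill = .data$split)) +
    geom_boxplot() +
    labs(x = NULL, y = metric,
         title = sprintf("Candidate performance (%s, seed %d)",
                         object$method, object$seed)) +
    theme_minimal()
}

#' Write a run report to disk
#'
#' Writes the metric report as JSON (`report.json`), the per-fold
#' candidate table as TSV (`candidates.tsv`) and, when a signature exists,
#' the signature TSV + JSON via [write_signature()].
#'
#' @param run a `ge_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    method = run$method, k = run$k, seed = run$seed,
    selected_model = run$selected_model,
    n_test = run$n_test,
    test_metrics = as.list(run$test_metrics),
    signature = run$signature$feature_ids,
    objective = run$signature$objective,
    validation_summary = run$rule_summary
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  readr::write_tsv(run$candidates, file.path(dir, "candidates.tsv"))
  if (!is.null(run$signature)) {
    write_signature(run$signature, file.path(dir, "signature.tsv"))
  }
  invisible(dir)
}

#' Run an experiment from a YAML/JSON configuration file
#'
#' Keys: `data` (feature-table CSV/TSV path), `label_col`, `id_col`,
#' `method`, `k`, `seed` (or `seeds`, a list — one run each), `n_folds`,
#' `test_fraction`, `selectors`, `t`, `solver`, `max_nodes`,
#' `classifiers`, `rule` (`metric`, `sanity_threshold`, `fallback`),
#' `output_dir`.
#'
#' @param path configuration file path.
#' @return a list of `ge_run` objects, one per seed; reports are written
#'   under `output_dir/seed_<seed>` when `output_dir` is set.
#' @export
run_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$data), "config must name a `data` file")
  data <- read_feature_table(cfg$data)
  rule <- selection_rule(
    primary_metric = cfg$rule$metric %||% "BA",
    sanity_threshold = cfg$rule$sanity_threshold %||% 0.10,
    fallback = cfg$rule$fallback %||% "min_gap")
  seeds <- unlist(cfg$seeds %||% cfg$seed %||% 1L)
  runs <- lapply(seeds, function(sd) {
    run <- run_experiment(
      data,
      method = cfg$method %||% "k_w_heavy",
      k = cfg$k %||% 5,
      seed = as.integer(sd),
      n_folds = cfg$n_folds %||% 5,
      test_fraction = cfg$test_fraction %||% 0.25,
      selectors = unlist(cfg$selectors %||% default_selector_roster()),
      t = cfg$t,
      solver = cfg$solver %||% "auto",
      max_nodes = cfg$max_nodes %||% 50,
      classifiers = unlist(cfg$classifiers %||%
                             default_classifier_roster()),
      rule = rule,
      label_col = cfg$label_col %||% "label",
      id_col = cfg$id_col %||% "sample_id")
    if (!is.null(cfg$output_dir)) {
      write_run_report(run, file.path(cfg$output_dir,
                                      paste0("seed_", sd)))
    }
    run
  })
  names(runs) <- paste0("seed_", seeds)
  runs
}

#' Read / write a feature table as delimited text
#'
#' The contract: first column is the sample id, the last column the
#' label, the header row carries feature ids. Comma- or tab-delimited by
#' extension.
#'
#' @param path CSV or TSV path.
#' @param data feature-table tibble.
#' @return the tibble (`read_`) or `path` invisibly (`write_`).
#' @export
read_feature_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  data <- reader(path, show_col_types = FALSE)
  names(data)[1] <- "sample_id"
  names(data)[ncol(data)] <- "label"
  table_parts(data)  # validate
  data
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(data, path) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(data, path)
  invisible(path)
}
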