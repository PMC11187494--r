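# Synthetic study generator: labeled feature tables with planted
# informative groups, redundant correlated copies and pure-noise features,
# plus toy interactomes with a planted connected disease module. Every
# other component of the package is testable on these fixtures without
# external data.

#' Generate a labeled feature table with planted structure
#'
#' Labels are two (or more) classes at the given balance. Each of the
#' `n_groups` informative groups has a latent standard-normal signal
#' shifted by `effect_size` (in SD units) between classes; the group's
#' `group_size` features are redundant noisy copies
#' `sqrt(rho) * z_g + sqrt(1 - rho) * eps` hitting the target within-group
#' correlation `rho` in closed form. Noise features are independent
#' standard normals. Fully determined by `seed`.
#'
#' Informative features are named `gXX_fYY` (group, copy) and noise
#' features `noise_ZZZ`.
#'
#' @param n_samples number of samples.
#' @param n_groups number of informative groups.
#' @param group_size redundant copies per group.
#' @param n_noise number of pure-noise features.
#' @param effect_size class separation of the latent group signal, in SD
#'   units.
#' @param within_group_correlation target correlation `rho` between
#'   copies of a group, in `[0, 1)`.
#' @param class_balance fraction of samples in the first class, in
#'   (0, 1).
#' @param n_classes number of classes (2 by default; additional classes
#'   shift the latent signal by successive multiples of `effect_size`).
#' @param seed integer seed.
#' @return list with `data` (feature-table tibble: `sample_id`, feature
#'   columns, `label`) and `truth` (tibble `feature_id`, `group`,
#'   `informative`).
#' @export
generate_dataset <- function(n_samples = 300, n_groups = 5, group_size = 3,
                             n_noise = 150, effect_size = 1.5,
                             within_group_correlation = 0.9,
                             class_balance = 0.5, n_classes = 2,
                             seed = 1L) {
  assert_that(n_samples >= 4, "`n_samples` too small")
  assert_that(n_groups >= 0 && group_size >= 1 && n_noise >= 0,
              "invalid feature counts")
  assert_that(n_groups * group_size + n_noise >= 1, "no features requested")
  assert_that(within_group_correlation >= 0 && within_group_correlation < 1,
              "`within_group_correlation` must be in [0, 1)")
  assert_that(class_balance > 0 && class_balance < 1,
              "`class_balance` must be in (0, 1)")
  assert_that(n_classes >= 2, "need at least two classes")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, "generate_dataset"))
  classes <- paste0("class_", seq_len(n_classes))
  n1 <- round(class_balance * n_samples)
  rest <- n_samples - n1
  per <- c(n1, rep(rest %/% (n_classes - 1), n_classes - 1))
  per[n_classes] <- n_samples - sum(per[-n_classes])
  y <- factor(rep(classes, per), levels = classes)
  rho <- within_group_correlation
  cols <- list(); ids <- character(0)
  group_of <- integer(0)
  shift <- effect_size * (as.integer(y) - 1)
  for (g in seq_len(n_groups)) {
    z <- rnorm(n_samples) + shift
    for (j in seq_len(group_size)) {
      ids <- c(ids, sprintf("g%02d_f%02d", g, j))
      group_of <- c(group_of, g)
      cols[[length(cols) + 1]] <-
        sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
    }
  }
  for (i in seq_len(n_noise)) {
    ids <- c(ids, sprintf("noise_%03d", i))
    group_of <- c(group_of, NA_integer_)
    cols[[length(cols) + 1]] <- rnorm(n_samples)
  }
  values <- do.call(cbind, cols)
  colnames(values) <- ids
  data <- dplyr::bind_cols(
    tibble(sample_id = sprintf("s%04d", seq_len(n_samples))),
    tibble::as_tibble(values),
    tibble(label = y))
  truth <- tibble(feature_id = ids, group = group_of,
                  informative = !is.na(group_of))
  list(data = data, truth = truth)
}

#' Generate a toy interactome with a planted disease module
#'
#' Grows a connected scale-free-style graph by preferential attachment
#' (each new node attaches to `attach_param` existing nodes) and marks a
#' connected module of `module_size` nodes, collected by breadth-first
#' search from the highest-degree node, as the disease gene set. Node
#' names are `GENE0001`, `GENE0002`, ...
#'
#' @param n_nodes number of genes.
#' @param attach_param preferential-attachment edges per new node (>= 1).
#' @param module_size size of the planted disease module
#'   (`< n_nodes`).
#' @param seed integer seed.
#' @return list with `graph` (igraph) and `disease_genes` (character).
#' @export
generate_toy_interactome <- function(n_nodes = 500, attach_param = 2,
                                     module_size = 30, seed = 1L) {
  assert_that(n_nodes >= 3, "`n_nodes` too small")
  assert_that(attach_param >= 1, "`attach_param` must be >= 1")
  assert_that(module_size >= 1 && module_size < n_nodes,
              "`module_size` must be positive and smaller than `n_nodes`")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, "toy_interactome"))
  g <- igraph::sample_pa(n_nodes, m = attach_param, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("GENE%04d", seq_len(n_nodes))
  hub <- which.max(igraph::degree(g))
  bfs_order <- igraph::bfs(g, root = hub, order = TRUE)$order
  module <- sort(igraph::V(g)$name[as.integer(bfs_order)[seq_len(module_size)]])
  list(graph = g, disease_genes = module)
}

#' Complementarity / redundancy score of a signature against the truth
#'
#' Counts how many distinct planted informative groups the signature
#' covers (`n_groups_hit`) and how many unordered pairs of signature
#' features share a group (`n_within_group_duplicate_pairs`). A perfectly
#' complementary signature hits many groups with zero duplicate pairs.
#'
#' @param signature a `ge_signature` or character vector of feature ids.
#' @param truth ground-truth tibble from [generate_dataset()].
#' @return tibble with `n_groups_hit` and
#'   `n_within_group_duplicate_pairs`.
#' @export
redundancy_score <- function(signature, truth) {
  feats <- if (inherits(signature, "ge_signature"))
    signature$feature_ids else as.character(signature)
  missing <- setdiff(feats, truth$feature_id)
  assert_that(length(missing) == 0,
              paste("features absent from truth:",
                    paste(missing, collapse = ", ")))
  grp <- truth$group[match(feats, truth$feature_id)]
  grp <- grp[!is.na(grp)]
  tab <- table(grp)
  tibble(n_groups_hit = length(tab),
         n_within_group_duplicate_pairs = sum(choose(tab, 2)))
}

#' Write the synthetic study to disk
#'
#' Writes the feature table CSV, ground-truth TSV and a toy-interactome
#' edge-list TSV plus disease-gene list (one symbol per line).
#'
#' @param dir output directory.
#' @param dataset result of [generate_dataset()].
#' @param interactome result of [generate_toy_interactome()] or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(dir, dataset,
                                  interactome = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$data, file.path(dir, "features.csv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  if (!is.null(interactome)) {
    el <- igraph::as_data_frame(interactome$graph, what = "edges")
    readr::write_tsv(el, file.path(dir, "interactome.tsv"),
                     col_names = FALSE)
    writeLines(interactome$disease_genes,
               file.path(dir, "disease_genes.txt"))
  }
  invisible(dir)
}
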