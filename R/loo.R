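#' Majority vote over one signal's peak predictions
#'
#' The signal-level label is the mode of the per-peak predicted labels. When
#' several classes tie for the mode, the tie is resolved deterministically
#' by a cascade: the tied class with the largest summed classifier score
#' (when scores are available), then the tied class most frequent among the
#' training signals, then the lexicographically first tied class.
#'
#' @param peak_labels Character/factor vector of one signal's peak
#'   predictions (length >= 1).
#' @param scores Optional per-peak score matrix/tibble with one column per
#'   class (columns may be prefixed `.score_`).
#' @param train_labels Optional signal-level labels of the training signals,
#'   used as tie-break priors.
#' @return A list with `label` (character) and `tie` (logical).
#' @export
majority_vote <- function(peak_labels, scores = NULL, train_labels = NULL) {
  peak_labels <- as.character(peak_labels)
  if (!length(peak_labels)) abort("`peak_labels` must be non-empty.")
  tab <- table(peak_labels)
  top <- names(tab)[tab == max(tab)]
  tie <- length(top) > 1L
  if (tie && !is.null(scores)) {
    sc <- as.matrix(as.data.frame(scores))
    colnames(sc) <- sub("^\\.score_", "", colnames(sc))
    have <- intersect(top, colnames(sc))
    if (length(have)) {
      sums <- colSums(sc[, have, drop = FALSE])
      top <- have[sums == max(sums)]
    }
  }
  if (length(top) > 1L && !is.null(train_labels)) {
    prior <- table(as.character(train_labels))[top]
    prior[is.na(prior)] <- 0
    top <- top[prior == max(prior)]
  }
  list(label = sort(top)[1], tie = tie)
}

#' Signal-level leave-one-out classification with peak voting
#'
#' Runs one cross-validation fold per signal: all peaks of the held-out
#' signal form the test set, every other signal's peaks the training set, so
#' peak rows of a signal never inform their own prediction. Per-peak
#' predictions are aggregated into the signal label by [majority_vote()].
#'
#' Standardization follows `standardize`: `"whole_dataset"` computes z-score
#' statistics once over all rows before splitting (the protocol replicated
#' from the original analysis, which leaks test statistics into training —
#' see the vignette), `"train_only"` recomputes them inside each fold from
#' the training rows, `"none"` leaves the features as given.
#'
#' @param features Feature tibble from [build_feature_table()] (needs
#'   `signal_id`, `label` and the 12 variables).
#' @param config A [classifier_config()].
#' @param standardize `"whole_dataset"`, `"train_only"` or `"none"`.
#' @return A `ct_loo` object: `$signals` (per-signal truth, prediction, tie
#'   flag, peak count), `$peaks` (per-peak predictions by fold), `$audit`
#'   (per-fold hygiene record), plus the config and standardization mode.
#' @export
loo_classify <- function(features, config,
                         standardize = c("whole_dataset", "train_only",
                                         "none")) {
  standardize <- match.arg(standardize)
  ids <- unique(features$signal_id)
  if (length(ids) < 2L) abort("need at least 2 signals for leave-one-out.")
  if (length(unique(features$label)) < 2L) {
    abort("need at least 2 classes for classification.")
  }
  if (standardize == "whole_dataset") {
    features <- zscore_standardize(features)
  }
  sig_truth <- features |>
    dplyr::distinct(.data$signal_id, .data$label)

  sig_rows <- list(); peak_rows <- list(); audit_rows <- list()
  for (id in ids) {
    is_test <- features$signal_id == id
    train <- features[!is_test, , drop = FALSE]
    test <- features[is_test, , drop = FALSE]
    if (standardize == "train_only") {
      train <- zscore_standardize(train)
      test <- zscore_standardize(test, stats = attr(train, "scaling"))
    }
    lost <- setdiff(unique(features$label), unique(train$label))
    if (length(lost)) {
      warn(sprintf("fold '%s': class(es) %s absent from training; proceeding with the rest.",
                   id, paste(lost, collapse = ", ")))
    }
    pred <- if (length(unique(train$label)) < 2L) {
      # degenerate fold: only one class left to predict
      tibble::tibble(.pred = factor(rep(train$label[1], nrow(test))))
    } else {
      fit_predict(config, train, test)
    }
    score_cols <- grep("^\\.score_", names(pred), value = TRUE)
    train_sig_labels <- sig_truth$label[sig_truth$signal_id != id]
    vote <- majority_vote(
      pred$.pred,
      scores = if (length(score_cols)) pred[score_cols] else NULL,
      train_labels = train_sig_labels
    )
    sig_rows[[id]] <- tibble::tibble(
      signal_id = id,
      truth = test$label[1],
      pred = vote$label,
      tie = vote$tie,
      n_peaks = nrow(test)
    )
    peak_rows[[id]] <- tibble::tibble(
      signal_id = id, peak = test$peak %||% seq_len(nrow(test)),
      truth = test$label, pred = as.character(pred$.pred)
    )
    audit_rows[[id]] <- tibble::tibble(
      signal_id = id,
      n_train_rows = nrow(train),
      n_test_rows = nrow(test),
      train_overlap = any(train$signal_id == id)
    )
  }
  structure(
    list(signals = dplyr::bind_rows(sig_rows),
         peaks = dplyr::bind_rows(peak_rows),
         audit = dplyr::bind_rows(audit_rows),
         config = config, standardize = standardize),
    class = "ct_loo"
  )
}

#' @export
print.ct_loo <- function(x, ...) {
  acc <- mean(x$signals$pred == x$signals$truth)
  cat(sprintf(
    "<ct_loo> %s | %d signals, %d peaks | signal accuracy %.1f%% | %d tie(s)\n",
    x$config$family, nrow(x$signals), nrow(x$peaks), 100 * acc,
    sum(x$signals$tie)
  ))
  invisible(x)
}

# ---- hyperparameter grids -------------------------------------------------

#' Enumerate a family's hyperparameter grid
#'
#' Builds the full hyperparameter table searched for a family: KNN crosses
#' its metrics and weightings with the 19 odd neighbourhood sizes 1-37;
#' random forests sweep the tree count 1-100; LS-SVM sweeps C over the 30
#' powers 2^-12..2^17 and, for the RBF kernel, the 900 (C, sigma)
#' combinations of the same grid for both parameters.
#'
#' @param family `"knn"`, `"random_forest"` or `"lssvm"`.
#' @param metrics,weightings KNN subsets (defaults: all 8 metrics, all 3
#'   weightings).
#' @param K Odd KNN neighbourhood sizes.
#' @param n_trees Random-forest tree counts.
#' @param kernel LS-SVM kernel.
#' @param C,sigma LS-SVM parameter values.
#' @return A tibble with one row per candidate configuration.
#' @export
classifier_grid <- function(family = c("knn", "random_forest", "lssvm"),
                            metrics = ct_knn_metrics,
                            weightings = ct_knn_weightings,
                            K = seq(1L, 37L, by = 2L),
                            n_trees = 1:100,
                            kernel = "rbf",
                            C = 2^(-12:17), sigma = 2^(-12:17)) {
  family <- match.arg(family)
  switch(family,
    knn = tidyr::expand_grid(family = "knn", metric = metrics,
                             weighting = weightings, K = as.integer(K)),
    random_forest = tibble::tibble(family = "random_forest",
                                   n_trees = as.integer(n_trees)),
    lssvm = if (kernel == "rbf") {
      tidyr::expand_grid(family = "lssvm", kernel = kernel, C = C,
                         sigma = sigma)
    } else {
      tibble::tibble(family = "lssvm", kernel = kernel, C = C)
    }
  )
}

grid_row_config <- function(row, seed) {
  args <- as.list(row[!vapply(row, is.na, logical(1))])
  fam <- args$family
  args$family <- NULL
  do.call(classifier_config, c(list(family = fam), args, list(seed = seed)))
}

#' Leave-one-out hyperparameter search
#'
#' Runs the full signal-level LOO procedure for every row of a
#' hyperparameter grid and selects the configuration with the highest LOO
#' accuracy; ties go to the less complex model (smaller K, fewer trees,
#' smaller C then sigma). Note that the selection criterion is the same LOO
#' accuracy that is reported, replicating the published protocol (see the
#' vignette for the caveat).
#'
#' @param features Feature tibble as for [loo_classify()].
#' @param grid Grid tibble from [classifier_grid()] (or hand-built, with a
#'   `family` column).
#' @param standardize Passed to [loo_classify()].
#' @param seed Seed stored into each candidate config.
#' @return A `ct_grid` object with `$results` (the accuracy table, in
#'   percent), `$best_config` and `$best` (the winning row).
#' @export
grid_search <- function(features, grid,
                        standardize = c("whole_dataset", "train_only",
                                        "none"),
                        seed = 20200504L) {
  standardize <- match.arg(standardize)
  if (!nrow(grid)) abort("`grid` must be non-empty.")
  if (standardize == "whole_dataset") {
    features <- zscore_standardize(features)
    standardize <- "none"
  }
  acc <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    cfg <- grid_row_config(grid[i, ], seed)
    res <- loo_classify(features, cfg, standardize = standardize)
    mean(res$signals$pred == res$signals$truth) * 100
  })
  results <- dplyr::mutate(grid, loo_accuracy = acc)
  ord <- do.call(order, c(
    list(-results$loo_accuracy),
    lapply(intersect(c("K", "n_trees", "C", "sigma"), names(results)),
           function(cn) results[[cn]])
  ))
  best <- results[ord[1], ]
  structure(
    list(results = results, best = best,
         best_config = grid_row_config(best[setdiff(names(best), "loo_accuracy")],
                                       seed),
         standardize = standardize),
    class = "ct_grid"
  )
}

#' @export
print.ct_grid <- function(x, ...) {
  cat(sprintf("<ct_grid> %d configuration(s); best LOO accuracy %.1f%%\n",
              nrow(x$results), x$best$loo_accuracy))
  print(x$best)
  invisible(x)
}
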