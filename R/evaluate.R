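# canonical display order for signal classes and their merged variants
ct_label_order <- c("B", "A", "R", "SR", "NR", "RSR", "SNR",
                    "baseline", "adrenaline", "responder", "semi_responder",
                    "non_responder")

order_labels <- function(labels) {
  known <- intersect(ct_label_order, labels)
  c(known, sort(setdiff(labels, known)))
}

#' Build a labelled confusion matrix
#'
#' Rows are true classes, columns predicted classes; entry (i, j) counts the
#' signals of true class i predicted as class j.
#'
#' @param truth,pred Equal-length label vectors.
#' @param labels Optional class order; defaults to the package's canonical
#'   display order (baseline, adrenaline, responder, semi-responder,
#'   non-responder and merged variants) restricted to the observed labels.
#' @return A `ct_confusion` integer matrix.
#' @export
confusion_matrix <- function(truth, pred, labels = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have the same length.")
  }
  labels <- labels %||% order_labels(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), labels)
  if (length(unknown)) {
    abort(sprintf("label(s) not in `labels`: %s.", paste(unknown, collapse = ", ")))
  }
  m <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  out <- matrix(as.integer(m), nrow = length(labels),
                dimnames = list(true = labels, predicted = labels))
  structure(out, class = c("ct_confusion", "matrix"))
}

#' @export
print.ct_confusion <- function(x, ...) {
  cat(sprintf("<ct_confusion> %d signals, accuracy %.1f%%\n", sum(x),
              accuracy(x)))
  print(unclass(x))
  invisible(x)
}

#' Assemble a confusion matrix directly from printed counts
#'
#' Convenience constructor for worked examples and reported result tables:
#' takes the counts row by row (true class by true class).
#'
#' @param counts Numeric vector of length `length(labels)^2`, row-major.
#' @param labels Class labels in display order.
#' @return A `ct_confusion` matrix.
#' @export
as_confusion <- function(counts, labels) {
  k <- length(labels)
  if (length(counts) != k * k) abort("`counts` must have length(labels)^2 entries.")
  if (any(counts < 0)) abort("confusion counts must be non-negative.")
  out <- matrix(as.integer(counts), nrow = k, byrow = TRUE,
                dimnames = list(true = labels, predicted = labels))
  structure(out, class = c("ct_confusion", "matrix"))
}

#' Classification accuracy of a confusion matrix
#'
#' 100 x trace / total, reported half-up to 1 decimal as a percentage.
#'
#' @param cm A `ct_confusion`.
#' @param digits Decimals to report.
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "ct_confusion"))
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix.")
  round_half_up(100 * sum(diag(cm)) / total, digits)
}

#' Per-class sensitivity (true positive rate)
#'
#' The diagonal count of a class divided by its true (row) count, in
#' percent, half-up to 1 decimal.
#'
#' @param cm A `ct_confusion`.
#' @param class_label One class, or `NULL` for all classes.
#' @param digits Decimals to report.
#' @return Named numeric vector (or scalar) of sensitivities in percent.
#' @export
sensitivity <- function(cm, class_label = NULL, digits = 1) {
  stopifnot(inherits(cm, "ct_confusion"))
  labels <- rownames(cm)
  if (!is.null(class_label)) {
    if (!class_label %in% labels) {
      abort(sprintf("class '%s' is not in the confusion matrix.", class_label))
    }
    labels <- class_label
  }
  out <- vapply(labels, function(cl) {
    rs <- sum(cm[cl, ])
    if (rs == 0) abort(sprintf("class '%s' has no true cases.", cl))
    round_half_up(100 * cm[cl, cl] / rs, digits)
  }, numeric(1))
  if (!is.null(class_label)) unname(out) else out
}

#' Class-merging schemes
#'
#' Returns the label mapping for the reported merging analyses:
#' `"rsr"` unites responders and semi-responders (RSR) against
#' non-responders (NR); `"snr"` unites semi-responders and non-responders
#' (SNR) against responders (R); `"none"` keeps the five classes, mapped to
#' their display abbreviations (B, A, R, SR, NR).
#'
#' @param scheme `"rsr"`, `"snr"` or `"none"`.
#' @return Named character vector mapping original to merged labels.
#' @export
merge_scheme <- function(scheme = c("rsr", "snr", "none")) {
  scheme <- match.arg(scheme)
  base <- c(baseline = "B", adrenaline = "A", responder = "R",
            semi_responder = "SR", non_responder = "NR")
  switch(scheme,
    none = base,
    rsr = replace(base, c("responder", "semi_responder"), c("RSR", "RSR")),
    snr = replace(base, c("semi_responder", "non_responder"), c("SNR", "SNR"))
  )
}

#' Apply a merging scheme to a label vector
#'
#' @param labels Character vector of class labels.
#' @param scheme A mapping from [merge_scheme()] (or any named character
#'   vector); labels already equal to a mapped value pass through.
#' @return The merged label vector.
#' @export
merge_classes <- function(labels, scheme = merge_scheme("rsr")) {
  labels <- as.character(labels)
  out <- unname(scheme[labels])
  passthrough <- is.na(out) & labels %in% scheme
  out[passthrough] <- labels[passthrough]
  if (anyNA(out)) {
    abort(sprintf("unmapped label(s): %s.",
                  paste(unique(labels[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Evaluate a leave-one-out run
#'
#' Builds the signal-level confusion matrix of a [loo_classify()] result,
#' optionally after merging classes.
#'
#' @param result A `ct_loo`.
#' @param scheme `NULL`, or a mapping from [merge_scheme()].
#' @return A `ct_confusion`.
#' @export
loo_confusion <- function(result, scheme = NULL) {
  stopifnot(inherits(result, "ct_loo"))
  truth <- result$signals$truth
  pred <- result$signals$pred
  if (!is.null(scheme)) {
    truth <- merge_classes(truth, scheme)
    pred <- merge_classes(pred, scheme)
  }
  confusion_matrix(truth, pred)
}

#' Per-class feature summaries
#'
#' Means and sample (n-1) standard deviations of the 12 peak variables per
#' class, the summary-table view of a feature dataset. A class with a single
#' peak reports sd 0; empty classes are simply absent.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param group Column to group by (default `label`).
#' @return A tidy tibble with columns `variable`, `class`, `n`, `mean`,
#'   `sd`, the variables in their fixed order.
#' @export
summarize_features <- function(features, group = "label") {
  if (!group %in% names(features)) {
    abort(sprintf("grouping column '%s' not found.", group))
  }
  features |>
    dplyr::select(dplyr::all_of(c(group, ct_feature_names))) |>
    tidyr::pivot_longer(dplyr::all_of(ct_feature_names),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(class = .data[[group]], .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = ct_feature_names)) |>
    dplyr::arrange(.data$variable, .data$class) |>
    dplyr::mutate(variable = as.character(.data$variable)) |>
    dplyr::relocate("variable")
}
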