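#' Tidy a leave-one-out result
#'
#' @param x A `ct_loo` from [loo_classify()].
#' @param ... Unused.
#' @return Per-signal tibble with `signal_id`, `truth`, `pred`, `tie`,
#'   `n_peaks`.
#' @method tidy ct_loo
#' @export
tidy.ct_loo <- function(x, ...) x$signals

#' One-row summary of a leave-one-out result
#'
#' @param x A `ct_loo`.
#' @param ... Unused.
#' @return Tibble with the classifier family, signal-level accuracy (in
#'   percent, as reported from the confusion matrix), counts of signals,
#'   peaks and voting ties.
#' @method glance ct_loo
#' @export
glance.ct_loo <- function(x, ...) {
  tibble::tibble(
    family = x$config$family,
    accuracy = accuracy(loo_confusion(x)),
    n_signals = nrow(x$signals),
    n_peaks = nrow(x$peaks),
    n_ties = sum(x$signals$tie),
    standardize = x$standardize
  )
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `ct_confusion`.
#' @param ... Unused.
#' @return Tibble with `truth`, `pred`, `n`.
#' @method tidy ct_confusion
#' @export
tidy.ct_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "pred", "n")
  tibble::as_tibble(df)
}

#' One-row summary of a confusion matrix
#'
#' @param x A `ct_confusion`.
#' @param ... Unused.
#' @return Tibble with `accuracy` (percent), `n` and one
#'   `sensitivity_<class>` column per class.
#' @method glance ct_confusion
#' @export
glance.ct_confusion <- function(x, ...) {
  sens <- sensitivity(x)
  out <- tibble::tibble(accuracy = accuracy(x), n = sum(x))
  dplyr::bind_cols(out, tibble::as_tibble(as.list(
    setNames(sens, paste0("sensitivity_", names(sens)))
  )))
}

#' Tidy a grid search
#'
#' @param x A `ct_grid` from [grid_search()].
#' @param ... Unused.
#' @return The per-configuration accuracy table.
#' @method tidy ct_grid
#' @export
tidy.ct_grid <- function(x, ...) x$results

#' One-row summary of a grid search
#'
#' @param x A `ct_grid`.
#' @param ... Unused.
#' @return The winning configuration row with its LOO accuracy.
#' @method glance ct_grid
#' @export
glance.ct_grid <- function(x, ...) x$best
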