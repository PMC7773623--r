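#' z-score standardization of the feature columns
#'
#' Centres and scales the 12 peak-variable columns to mean 0, sd 1 so all
#' variables weigh equally in distance-based classifiers. By default the
#' statistics are computed from the rows given (the "whole dataset"
#' protocol); pass `stats` to apply previously computed statistics, e.g.
#' training-fold statistics to test rows. Zero-variance columns are mapped
#' to all zeros with a warning.
#'
#' @param features Feature tibble containing the columns in
#'   [peak_feature_names()].
#' @param stats Optional tibble with columns `column`, `mean`, `sd` as
#'   returned in the `"scaling"` attribute.
#' @return The standardized tibble, with the statistics used attached as
#'   attribute `"scaling"`.
#' @export
zscore_standardize <- function(features, stats = NULL) {
  cols <- ct_feature_names
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    abort(sprintf("missing feature column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (anyNA(features[cols])) abort("feature columns contain missing values.")
  if (is.null(stats)) {
    stats <- tibble::tibble(
      column = cols,
      mean = purrr::map_dbl(cols, ~ mean(features[[.x]])),
      sd = purrr::map_dbl(cols, ~ sd(features[[.x]]))
    )
  }
  zero <- stats$column[stats$sd == 0 | !is.finite(stats$sd)]
  if (length(zero)) {
    warn(sprintf("zero-variance column(s) mapped to 0: %s.",
                 paste(zero, collapse = ", ")))
  }
  for (i in seq_len(nrow(stats))) {
    cn <- stats$column[i]
    if (cn %in% zero) {
      features[[cn]] <- rep(0, nrow(features))
    } else {
      features[[cn]] <- (features[[cn]] - stats$mean[i]) / stats$sd[i]
    }
  }
  attr(features, "scaling") <- stats
  features
}
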