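#' Locate the derivative extremes of one peak
#'
#' Finds the landmark positions used by the peak variables: `L1` = argmax of
#' the first derivative on the rising flank `[start, max]`, `L2` = argmin of
#' the first derivative on the decaying flank `[max, end]`, and `L3` / `L4`
#' = argmin / argmax of the second derivative, both on the decaying flank.
#' Ties go to the earliest index.
#'
#' @param signal The [ct_signal()] the peak belongs to.
#' @param peak One-row peak tibble (or list) with `start_index`,
#'   `max_index`, `end_index`.
#' @param d1,d2 Optional precomputed first and second derivative series;
#'   the second derivative is the segment-slope operator applied to the
#'   first derivative.
#' @param segment_length Passed to [first_derivative()] when `d1`/`d2` are
#'   not supplied.
#' @return A list with integer positions `L1`, `L2`, `L3`, `L4`.
#' @export
locate_derivative_extremes <- function(signal, peak, d1 = NULL, d2 = NULL,
                                       segment_length = 5L) {
  s <- peak$start_index; m <- peak$max_index; e <- peak$end_index
  if (is.na(s) || is.na(m) || is.na(e) || !(s < m && m < e)) {
    abort(sprintf(
      "degenerate peak (start %s, max %s, end %s): apex must lie strictly inside the peak.",
      s, m, e
    ))
  }
  if (is.null(d1)) d1 <- first_derivative(signal, segment_length)
  if (is.null(d2)) {
    d2 <- first_derivative(d1, segment_length,
                           sample_interval = attr(signal, "sample_interval"))
  }
  left <- s:m
  right <- m:e
  list(
    L1 = left[which_max_first(d1[left])],
    L2 = right[which_min_first(d1[right])],
    L3 = right[which_min_first(d2[right])],
    L4 = right[which_max_first(d2[right])]
  )
}

#' Compute the 12 variables of one peak
#'
#' For a peak with onset, apex and end at times \eqn{t_s < t_m < t_e}:
#' amplitudes `A_l = s(max) - s(start)`, `A_r = s(max) - s(end)`; durations
#' `D_l = t_m - t_s`, `D_r = t_e - t_m`; `max_d1` and `abs_min_d1` are the
#' first-derivative extremes at `L1` (rising flank) and `L2` (decaying
#' flank); `max_d2` and `abs_min_d2` the second-derivative extremes on the
#' decaying flank; `R` is the trapezoidal integral of the signal above the
#' chord joining (t_s, s(start)) to (t_e, s(end)); `delta` the interval from
#' this apex back to the previous apex, or to the first sample of the signal
#' when there is no preceding peak; `d_l` and `d_r` the times from onset to
#' `L1` and from apex to `L2`.
#'
#' @inheritParams locate_derivative_extremes
#' @param previous_peak The preceding peak (one row) or `NULL`.
#' @return A one-row tibble with the 12 variables in fixed column order
#'   ([peak_feature_names()]).
#' @export
compute_peak_variables <- function(signal, peak, previous_peak = NULL,
                                   d1 = NULL, d2 = NULL,
                                   segment_length = 5L) {
  if (is.null(d1)) d1 <- first_derivative(signal, segment_length)
  if (is.null(d2)) {
    d2 <- first_derivative(d1, segment_length,
                           sample_interval = attr(signal, "sample_interval"))
  }
  L <- locate_derivative_extremes(signal, peak, d1 = d1, d2 = d2)
  y <- signal$value
  tt <- signal$time
  s <- peak$start_index; m <- peak$max_index; e <- peak$end_index

  idx <- s:e
  chord <- y[s] + (y[e] - y[s]) * (tt[idx] - tt[s]) / (tt[e] - tt[s])
  excess <- y[idx] - chord
  R <- sum((excess[-1] + excess[-length(excess)]) / 2 * diff(tt[idx]))

  prev_apex_time <- if (!is.null(previous_peak)) {
    tt[previous_peak$max_index]
  } else {
    tt[1]
  }

  tibble::tibble(
    A_l = y[m] - y[s],
    A_r = y[m] - y[e],
    D_l = tt[m] - tt[s],
    D_r = tt[e] - tt[m],
    max_d1 = d1[L$L1],
    abs_min_d1 = abs(d1[L$L2]),
    max_d2 = d2[L$L4],
    abs_min_d2 = abs(d2[L$L3]),
    R = R,
    delta = tt[m] - prev_apex_time,
    d_l = tt[L$L1] - tt[s],
    d_r = tt[L$L2] - tt[m]
  )
}

#' All peak variables of one signal
#'
#' @param signal A [ct_signal()].
#' @param peaks Peak tibble from [detect_peaks()] (after
#'   [filter_small_peaks()]).
#' @param segment_length Derivative segment length in samples.
#' @return Tibble with one row per peak: `peak` (index within the signal)
#'   plus the 12 variables.
#' @export
peak_features <- function(signal, peaks, segment_length = 5L) {
  if (!nrow(peaks)) {
    out <- tibble::as_tibble(setNames(
      rep(list(numeric()), length(ct_feature_names)), ct_feature_names
    ))
    return(dplyr::bind_cols(tibble::tibble(peak = integer()), out))
  }
  d1 <- first_derivative(signal, segment_length)
  d2 <- first_derivative(d1, segment_length,
                         sample_interval = attr(signal, "sample_interval"))
  rows <- purrr::map(seq_len(nrow(peaks)), function(i) {
    compute_peak_variables(
      signal, peaks[i, ],
      previous_peak = if (i > 1L) peaks[i - 1L, ] else NULL,
      d1 = d1, d2 = d2
    )
  })
  dplyr::bind_cols(tibble::tibble(peak = seq_len(nrow(peaks))),
                   dplyr::bind_rows(rows))
}

#' Run detection and featurization over a whole dataset
#'
#' The standard preprocessing path for classification: each signal is
#' amplitude-scaled (default x1000), beats are detected and noise-filtered,
#' and the 12 variables are computed for every retained peak. Signals whose
#' peaks were all filtered away cannot vote and are dropped with a warning.
#'
#' The `label` column holds the classification target: the response class
#' for dantrolene signals and the condition (baseline/adrenaline) otherwise.
#'
#' @param dataset Tibble with a `signal` list-column plus `signal_id`,
#'   `cell_line`, `condition`, `response_class` (as returned by
#'   [read_ct_dataset()] or [generate_dataset()]).
#' @param params A [detection_params()].
#' @param scale_factor Amplitude scaling applied before detection.
#' @param segment_length Derivative segment length in samples.
#' @return A feature tibble with columns `signal_id`, `cell_line`,
#'   `condition`, `response_class`, `label`, `peak`, then the 12 variables.
#' @export
build_feature_table <- function(dataset, params = detection_params(),
                                scale_factor = 1000, segment_length = 5L) {
  stopifnot(is.data.frame(dataset), "signal" %in% names(dataset))
  res <- purrr::map(seq_len(nrow(dataset)), function(i) {
    sig <- scale_amplitudes(dataset$signal[[i]], scale_factor)
    pk <- filter_small_peaks(detect_peaks(sig, params), sig, params)
    if (!nrow(pk)) return(NULL)
    feats <- peak_features(sig, pk, segment_length = segment_length)
    dplyr::bind_cols(
      tibble::tibble(
        signal_id = dataset$signal_id[i],
        cell_line = dataset$cell_line[i],
        condition = dataset$condition[i],
        response_class = dataset$response_class[i]
      ),
      feats
    )
  })
  empty <- purrr::map_lgl(res, is.null)
  if (any(empty)) {
    warn(sprintf(
      "dropping %d signal(s) with no retained peaks: %s",
      sum(empty), paste(dataset$signal_id[empty], collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(res)
  out$label <- ifelse(out$condition == "dantrolene",
                      out$response_class, out$condition)
  dplyr::relocate(out, "label", .after = "response_class")
}
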