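#' Peak detection parameters
#'
#' Controls the derivative-phase beat recogniser. The first derivative is a
#' least-squares slope over short successive segments of `segment_length`
#' samples. Derivative values with magnitude at most `zero_band` (scaled
#' units/s) count as "roughly zero"; by default the band is 5% of a robust
#' derivative amplitude (the 98th percentile of the absolute derivative),
#' floored at 3.5 standard deviations of the derivative noise so that
#' sample noise cannot masquerade as beat onsets. Candidate
#' peaks shorter than `min_peak_duration` seconds are discarded. After
#' detection, peaks whose amplitude is below `noise_fraction` (default 8%)
#' of a reference amplitude are dropped as potential noise; the reference is
#' chosen by `reference_stat`: the median of the upper half of peak
#' amplitudes (`"upper_median"`, robust to a single outlier), the maximum, or
#' the plain median.
#'
#' @param segment_length Samples per derivative segment (>= 2).
#' @param zero_band Derivative magnitude treated as zero, scaled units/s, or
#'   `NULL` to derive it from the signal.
#' @param min_peak_duration Minimum onset-to-end duration, seconds.
#' @param noise_fraction Amplitude fraction below which peaks are noise.
#' @param reference_stat `"upper_median"`, `"max"` or `"median"`.
#' @return A `ct_detection_params` list.
#' @export
detection_params <- function(segment_length = 5L, zero_band = NULL,
                             min_peak_duration = 0.1, noise_fraction = 0.08,
                             reference_stat = c("upper_median", "max",
                                                "median")) {
  reference_stat <- match.arg(reference_stat)
  if (segment_length < 2) abort("`segment_length` must be >= 2.")
  if (!is.null(zero_band) && zero_band < 0) abort("`zero_band` must be >= 0.")
  if (noise_fraction < 0 || noise_fraction >= 1) {
    abort("`noise_fraction` must be in [0, 1).")
  }
  structure(
    list(segment_length = as.integer(segment_length), zero_band = zero_band,
         min_peak_duration = min_peak_duration,
         noise_fraction = noise_fraction, reference_stat = reference_stat),
    class = "ct_detection_params"
  )
}

#' Segment-wise first derivative of a signal
#'
#' Estimates s'(t) at every sample as the least-squares slope of the signal
#' over a centred window of `segment_length` samples; windows are truncated
#' at the signal edges, so the series has the same length as the signal.
#'
#' @param signal A [ct_signal()], or a numeric vector (then `sample_interval`
#'   must be given).
#' @param segment_length Samples per window (>= 2, <= signal length).
#' @param sample_interval Sample spacing in seconds for vector input.
#' @return Numeric vector of derivative values, scaled units per second.
#' @export
first_derivative <- function(signal, segment_length = 5L,
                             sample_interval = NULL) {
  if (inherits(signal, "ct_signal")) {
    y <- signal$value
    dt <- attr(signal, "sample_interval")
  } else {
    y <- as.numeric(signal)
    dt <- sample_interval
    if (is.null(dt)) abort("`sample_interval` is required for vector input.")
  }
  n <- length(y)
  L <- as.integer(segment_length)
  if (L < 2L || L > n) {
    abort("`segment_length` must be between 2 and the signal length.")
  }
  half_lo <- (L - 1L) %/% 2L
  half_hi <- L - 1L - half_lo
  out <- numeric(n)
  # interior: fixed centred window -> convolution with linear LS weights
  k <- seq(-half_lo, half_hi)
  w <- (k - mean(k)) / (sum((k - mean(k))^2) * dt)
  interior <- (half_lo + 1L):(n - half_hi)
  if (length(interior)) {
    for (j in seq_along(k)) {
      out[interior] <- out[interior] + w[j] * y[interior + k[j]]
    }
  }
  # edges: truncated windows, explicit least squares
  edge <- setdiff(seq_len(n), interior)
  for (i in edge) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    idx <- lo:hi
    tt <- (idx - 1) * dt
    out[i] <- sum((tt - mean(tt)) * (y[idx] - mean(y[idx]))) /
      sum((tt - mean(tt))^2)
  }
  out
}

# "Roughly zero" band for the derivative: 5% of the beat-scale derivative
# amplitude, floored at 3.5 sd of the derivative noise. The sample noise sd
# is estimated robustly from successive differences (flat stretches dominate
# the median), then propagated through the least-squares slope analytically:
# var(slope) = sigma^2 * 12 / (L (L^2 - 1) dt^2).
auto_zero_band <- function(d1, y = NULL, dt = NULL, segment_length = 5L) {
  band <- 0.05 * as.numeric(quantile(abs(d1), 0.98, names = FALSE))
  if (!is.null(y)) {
    sigma <- median(abs(diff(y))) / 0.6745 / sqrt(2)
    L <- segment_length
    slope_sd <- sigma * sqrt(12 / (L * (L^2 - 1))) / dt
    band <- max(band, 3.5 * slope_sd)
  }
  band
}

#' Detect beats by tracking derivative phases
#'
#' Follows the first derivative of the transient through its phase sequence:
#' near zero, then rapidly positive (peak onset), back through zero at the
#' apex, then clearly negative on the decaying flank, and finally back into
#' the zero band (peak end). The apex is the signal argmax between the onset
#' and the first negative-derivative sample, ties to the earliest sample.
#' Candidates that never develop a negative flank, or are shorter than
#' `min_peak_duration`, are discarded. A flat signal yields zero peaks.
#'
#' @param signal A [ct_signal()], normally after [scale_amplitudes()].
#' @param params A [detection_params()].
#' @return A tibble with one row per peak: `start_index`, `max_index`,
#'   `end_index` (1-based, inclusive) and the corresponding times in
#'   seconds.
#' @export
detect_peaks <- function(signal, params = detection_params()) {
  y <- signal$value
  tt <- signal$time
  n <- length(y)
  dt <- attr(signal, "sample_interval")
  d1 <- first_derivative(signal, params$segment_length)
  band <- params$zero_band %||% auto_zero_band(d1, y, dt,
                                               params$segment_length)

  peaks <- list()
  i <- 2L
  min_start <- 1L
  while (i <= n) {
    # onset: derivative leaves the +band upward
    if (d1[i] > band && d1[i - 1L] <= band && i - 1L >= min_start) {
      start <- i - 1L
      # first non-positive derivative after the rise = apex region
      j <- i
      while (j <= n && d1[j] > 0) j <- j + 1L
      if (j > n) break
      # require a clearly negative flank before returning into the band;
      # bail out if the derivative climbs back above +band first (chatter)
      k <- j
      ok <- FALSE
      while (k <= n) {
        if (d1[k] < -band) { ok <- TRUE; break }
        if (d1[k] > band) break
        k <- k + 1L
      }
      if (!ok) { i <- k; next }
      # end: derivative re-enters the band from below
      e <- k
      while (e <= n && d1[e] < -band) e <- e + 1L
      if (e > n) break
      apex <- start + which_max_first(y[start:j]) - 1L
      if (apex > start && apex < e &&
          (tt[e] - tt[start]) >= params$min_peak_duration) {
        peaks[[length(peaks) + 1L]] <-
          c(start = start, max = apex, end = e)
        min_start <- e + 1L
      }
      i <- e + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) {
    return(tibble::tibble(
      start_index = integer(), max_index = integer(), end_index = integer(),
      start_time = numeric(), max_time = numeric(), end_time = numeric()
    ))
  }
  p <- do.call(rbind, peaks)
  tibble::tibble(
    start_index = as.integer(p[, "start"]),
    max_index = as.integer(p[, "max"]),
    end_index = as.integer(p[, "end"]),
    start_time = tt[p[, "start"]],
    max_time = tt[p[, "max"]],
    end_time = tt[p[, "end"]]
  )
}

peak_amplitudes <- function(peaks, signal) {
  y <- signal$value
  pmax(y[peaks$max_index] - y[peaks$start_index],
       y[peaks$max_index] - y[peaks$end_index])
}

#' Drop small-amplitude noise peaks
#'
#' Peaks whose amplitude (the larger of the left and right amplitude) is
#' strictly below `noise_fraction` of the reference amplitude of the large
#' peaks in the signal are removed as potential noise; a peak exactly at the
#' boundary is retained. The reference amplitude is defined by
#' `reference_stat` in [detection_params()].
#'
#' @param peaks Peak tibble from [detect_peaks()] on the same signal.
#' @param signal The [ct_signal()] the peaks were detected on.
#' @param params A [detection_params()].
#' @return The filtered peak tibble, original order preserved.
#' @export
filter_small_peaks <- function(peaks, signal, params = detection_params()) {
  if (!nrow(peaks)) return(peaks)
  amps <- peak_amplitudes(peaks, signal)
  ref <- switch(params$reference_stat,
    max = max(amps),
    median = median(amps),
    upper_median = median(amps[amps >= median(amps)])
  )
  peaks[amps >= params$noise_fraction * ref, , drop = FALSE]
}
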