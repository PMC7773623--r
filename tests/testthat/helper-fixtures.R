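# Shared in-code fixtures.

# Triangular beat: onset t=0 value 0, apex t=0.2 value `amp`, end t=0.6
# value 0, on a 0.01 s grid. Closed forms: A_l = A_r = amp, D_l = 0.2,
# D_r = 0.4, R = 0.5 * 0.6 * amp.
triangle_signal <- function(amp = 300, dt = 0.01) {
  tt <- seq(0, 0.6, by = dt)
  y <- ifelse(tt <= 0.2, amp * tt / 0.2, amp * (0.6 - tt) / 0.4)
  ct_signal(tt, y, signal_id = "triangle")
}

triangle_peak <- function(dt = 0.01) {
  tibble::tibble(
    start_index = 1L,
    max_index = as.integer(round(0.2 / dt)) + 1L,
    end_index = as.integer(round(0.6 / dt)) + 1L
  )
}

# Feature tibble of two well-separated Gaussian clouds in the 12-variable
# space (class means 0 and `sep` standard deviations apart in every
# coordinate), `n` rows per class, grouped into signals of `peaks_per_signal`
# rows.
cloud_features <- function(n = 50, sep = 10, peaks_per_signal = 5, seed = 11,
                           classes = c("a", "b")) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      m <- matrix(rnorm(n * 12, mean = (ci - 1) * sep), ncol = 12)
      colnames(m) <- peak_feature_names()
      df <- tibble::as_tibble(m)
      df$label <- classes[ci]
      df$signal_id <- paste0(classes[ci],
                             rep(seq_len(ceiling(n / peaks_per_signal)),
                                 each = peaks_per_signal)[seq_len(n)])
      df
    })
    out <- dplyr::bind_rows(rows)
    out$peak <- stats::ave(seq_len(nrow(out)), out$signal_id, FUN = seq_along)
    dplyr::relocate(out, "signal_id", "label", "peak")
  })
}

# A fast, quiet generator config for unit tests.
test_gen_config <- function(label = "responder", n_signals = 3,
                            abnormal_fraction = 0, noise_sd = 0,
                            duration = 15, seed = 5, ...) {
  class_gen_config(
    label = label, n_signals = n_signals,
    shape_means = peak_shape_params(300, 0.2, 0.4, 1.0, 100),
    shape_sds = list(amplitude = 15, rise_duration = 0.015,
                     decay_duration = 0.03, interval = 0.08),
    abnormal_fraction = abnormal_fraction, noise_sd = noise_sd,
    duration = duration, seed = seed, ...
  )
}
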