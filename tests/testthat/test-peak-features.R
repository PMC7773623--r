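test_that("triangular beat features match closed-form geometry", {
  sig <- triangle_signal(300)
  fv <- compute_peak_variables(sig, triangle_peak())
  expect_equal(fv$A_l, 300)
  expect_equal(fv$A_r, 300)
  expect_equal(fv$D_l, 0.2)
  expect_equal(fv$D_r, 0.4)
  # chord is the baseline, so R is the triangle area 0.5 * 0.6 * 300 = 90,
  # within trapezoid tolerance 2 * dt * amplitude
  expect_lt(abs(fv$R - 90), 2 * 0.01 * 300)
  # first peak of the signal: delta runs back to the first sample
  expect_equal(fv$delta, 0.2)
  # constant rise slope: L1 tie broken to the earliest left-side index
  L <- locate_derivative_extremes(sig, triangle_peak())
  d1 <- first_derivative(sig)
  left <- 1:21
  expect_equal(L$L1, left[which(d1[left] == max(d1[left]))[1]])
})

test_that("mirror-symmetric beats have equal left/right amplitude and duration", {
  dt <- 0.01
  tt <- seq(0, 0.4, by = dt)
  y <- 300 * exp(-((tt - 0.2)^2) / (2 * 0.05^2))
  sig <- ct_signal(tt, y)
  pk <- tibble::tibble(start_index = 1L, max_index = 21L, end_index = 41L)
  fv <- compute_peak_variables(sig, pk)
  expect_equal(fv$A_l, fv$A_r, tolerance = 1e-10)
  expect_equal(fv$D_l, fv$D_r, tolerance = 1e-10)
  # symmetric flanks: max slope magnitudes agree within 1%
  expect_lt(abs(fv$max_d1 - fv$abs_min_d1) / fv$max_d1, 0.01)
})

test_that("delta falls back to the signal start for the first peak", {
  dt <- 0.02
  tt <- seq(0, 3, by = dt)
  y <- 300 * exp(-((tt - 1.2)^2) / (2 * 0.05^2))
  sig <- ct_signal(tt, y)
  pk <- detect_peaks(sig, detection_params(zero_band = 5))
  expect_equal(nrow(pk), 1L)
  fv <- compute_peak_variables(sig, pk[1, ])
  expect_equal(fv$delta, 1.2, tolerance = dt)
})

test_that("derivative-extreme locations agree with a dense-grid scan", {
  # smooth generated beat, compared on a 10x oversampled grid
  p <- peak_shape_params(amplitude = 300, rise_duration = 0.2,
                         decay_duration = 0.4)
  coarse <- sample_peak_shape(p, sample_rate = 50)
  fine <- sample_peak_shape(p, sample_rate = 500)
  sig <- ct_signal(coarse$time, coarse$value)
  n <- length(coarse$value)
  apex <- which.max(coarse$value)
  pk <- tibble::tibble(start_index = 1L, max_index = apex,
                       end_index = as.integer(n))
  L <- locate_derivative_extremes(sig, pk)
  # same 0.1 s physical smoothing window on the dense grid, so the scan
  # checks the locator rather than the estimator bandwidth
  d1f <- first_derivative(fine$value, 51, sample_interval = 1 / 500)
  t_L1_fine <- fine$time[which.max(d1f[fine$time <= fine$time[which.max(fine$value)]])]
  t_L2_fine <- fine$time[which.min(d1f)]
  expect_lt(abs(sig$time[L$L1] - t_L1_fine), 1.5 / 50)
  expect_lt(abs(sig$time[L$L2] - t_L2_fine), 1.5 / 50)
})

test_that("d_l and d_r stay inside their half-peaks on generated data", {
  g <- generate_signal(test_gen_config(noise_sd = 2, duration = 20), seed = 21)
  sig <- scale_amplitudes(g$signal, 1000)
  pk <- filter_small_peaks(detect_peaks(sig), sig)
  ft <- peak_features(sig, pk)
  expect_true(all(ft$d_l <= ft$D_l + 1e-12))
  expect_true(all(ft$d_r <= ft$D_r + 1e-12))
  expect_true(all(ft$A_l >= 0 & ft$A_r >= 0))
  expect_true(all(is.finite(as.matrix(ft[peak_feature_names()]))))
})

test_that("degenerate peaks are rejected by name", {
  sig <- triangle_signal()
  bad <- tibble::tibble(start_index = 21L, max_index = 21L, end_index = 61L)
  expect_error(compute_peak_variables(sig, bad), "degenerate")
})

test_that("feature tables count rows per retained peak and propagate labels", {
  cfgs <- list(
    test_gen_config("responder", n_signals = 2, noise_sd = 0),
    test_gen_config("non_responder", n_signals = 2, noise_sd = 0,
                    abnormal_fraction = 0.4)
  )
  out <- generate_dataset(cfgs, seed = 8)
  ft <- build_feature_table(out$dataset)
  expect_equal(sort(unique(ft$label)), c("non_responder", "responder"))
  # labels constant within each signal
  per_sig <- tapply(ft$label, ft$signal_id, function(x) length(unique(x)))
  expect_true(all(per_sig == 1L))
  # all 12 variables present in fixed order after the metadata columns
  expect_equal(tail(names(ft), 12), peak_feature_names())
  # feature computation is independent of dataset row order
  ft2 <- build_feature_table(out$dataset[rev(seq_len(nrow(out$dataset))), ])
  expect_equal(
    dplyr::arrange(ft, signal_id, peak),
    dplyr::arrange(ft2, signal_id, peak)
  )
})

test_that("signals with no retained peaks are dropped with a warning", {
  g <- generate_signal(test_gen_config(n_signals = 1, noise_sd = 0), seed = 3)
  flat <- ct_signal(g$signal$time, rep(0.1, nrow(g$signal)),
                    signal_id = "flat")
  dataset <- tibble::tibble(
    signal_id = c("good", "flat"),
    cell_line = "x", condition = "baseline", response_class = "none",
    signal = list(g$signal, flat)
  )
  expect_warning(ft <- build_feature_table(dataset), "flat")
  expect_false("flat" %in% ft$signal_id)
})
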