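#' Beat shape parameters
#'
#' Mean morphology of one calcium transient beat in the synthetic generator:
#' a sigmoidal (raised-cosine) rise of `rise_duration` seconds from baseline
#' to `baseline_level + amplitude`, followed by an exponential decay that
#' falls to 2% of the amplitude over `decay_duration` seconds. `interval` is
#' the mean apex-to-apex spacing. Amplitudes are in scaled units (ratio x
#' 1000).
#'
#' @param amplitude Peak amplitude above baseline, scaled units.
#' @param rise_duration Onset-to-apex duration, seconds.
#' @param decay_duration Apex-to-end duration, seconds.
#' @param interval Mean apex-to-apex interval, seconds.
#' @param baseline_level Resting level, scaled units.
#' @return A `ct_peak_shape` list.
#' @export
peak_shape_params <- function(amplitude = 277, rise_duration = 0.212,
                              decay_duration = 0.438, interval = 1.038,
                              baseline_level = 100) {
  for (nm in c("amplitude", "rise_duration", "decay_duration", "interval",
               "baseline_level")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(amplitude = amplitude, rise_duration = rise_duration,
         decay_duration = decay_duration, interval = interval,
         baseline_level = baseline_level),
    class = "ct_peak_shape"
  )
}

ct_abnormality_kinds <- c("double_hump", "amplitude_alternation",
                          "plateau", "irregular_interval")

#' Per-class generator configuration
#'
#' Describes how to synthesise one class of labelled signals. Beat-level
#' shape parameters are drawn hierarchically: each signal gets its own mean
#' shape (Gaussian around `shape_means` with sd `signal_sd_frac *
#' shape_sds`), and each beat jitters around the signal mean (sd
#' `beat_sd_frac * shape_sds`). Draws are truncated to keep the beat geometry
#' valid. A fraction `abnormal_fraction` of beats is deformed, with the kind
#' of deformation sampled from `abnormality_mix`:
#'
#' * `double_hump`: a secondary bump on the decaying flank (two local maxima
#'   within one beat),
#' * `amplitude_alternation`: the beat fires at 40% of its drawn amplitude,
#' * `plateau`: the transient holds near its maximum before decaying,
#' * `irregular_interval`: a premature beat (the preceding interval is
#'   shortened to 30-60% of its drawn value).
#'
#' @param label Signal-level class label (e.g. `"responder"`).
#' @param n_signals Number of signals to generate.
#' @param shape_means A [peak_shape_params()].
#' @param shape_sds Named list/vector of dispersions for `amplitude`,
#'   `rise_duration`, `decay_duration`, `interval` (same units as the means).
#' @param abnormal_fraction Proportion of abnormal beats in `[0, 1]`.
#' @param abnormality_mix Named non-negative weights over the four
#'   abnormality kinds; normalised to sum to 1.
#' @param noise_sd Additive Gaussian noise, scaled units.
#' @param duration Signal duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param condition Recording condition tag for the generated signals.
#' @param cell_line Cell line tag.
#' @param signal_sd_frac,beat_sd_frac Split of `shape_sds` into
#'   between-signal and within-signal components.
#' @param seed Integer seed; generation is reproducible from (config, seed).
#' @return A `ct_gen_config` list.
#' @export
class_gen_config <- function(label, n_signals,
                             shape_means = peak_shape_params(),
                             shape_sds = list(amplitude = 90,
                                              rise_duration = 0.05,
                                              decay_duration = 0.1,
                                              interval = 0.3),
                             abnormal_fraction = 0,
                             abnormality_mix = c(double_hump = 0.4,
                                                 amplitude_alternation = 0.2,
                                                 plateau = 0.2,
                                                 irregular_interval = 0.2),
                             noise_sd = 0.02 * shape_means$amplitude,
                             duration = 20, sample_rate = 50,
                             condition = "dantrolene",
                             cell_line = "synthetic",
                             signal_sd_frac = 0.5, beat_sd_frac = 0.5,
                             seed = 1L) {
  if (!inherits(shape_means, "ct_peak_shape")) {
    abort("`shape_means` must come from peak_shape_params().")
  }
  if (abnormal_fraction < 0 || abnormal_fraction > 1) {
    abort("`abnormal_fraction` must be in [0, 1].")
  }
  if (n_signals < 1) abort("`n_signals` must be >= 1.")
  mix <- abnormality_mix[ct_abnormality_kinds]
  mix[is.na(mix)] <- 0
  names(mix) <- ct_abnormality_kinds
  if (any(mix < 0) || sum(mix) <= 0) {
    abort("`abnormality_mix` weights must be non-negative with positive sum.")
  }
  structure(
    list(label = label, n_signals = as.integer(n_signals),
         shape_means = shape_means, shape_sds = as.list(shape_sds),
         abnormal_fraction = abnormal_fraction,
         abnormality_mix = mix / sum(mix),
         noise_sd = noise_sd, duration = duration,
         sample_rate = sample_rate, condition = condition,
         cell_line = cell_line,
         signal_sd_frac = signal_sd_frac, beat_sd_frac = beat_sd_frac,
         seed = as.integer(seed)),
    class = "ct_gen_config"
  )
}

# Deterministic beat waveform on a uniform grid starting at the onset.
# Returns the values *above baseline_level* plus the intended landmark times
# relative to the onset.
beat_waveform <- function(amplitude, rise, decay, plateau = 0, dt,
                          bump = NULL) {
  total <- rise + plateau + decay
  t <- seq(0, total, by = dt)
  y <- numeric(length(t))
  in_rise <- t <= rise
  y[in_rise] <- amplitude * 0.5 * (1 - cos(pi * t[in_rise] / rise))
  in_plat <- t > rise & t <= rise + plateau
  y[in_plat] <- amplitude
  in_dec <- t > rise + plateau
  k <- log(50) / decay  # decays to 2% of amplitude at `decay`
  y[in_dec] <- amplitude * exp(-k * (t[in_dec] - rise - plateau))
  if (!is.null(bump)) {
    y <- y + bump$height * exp(-(t - bump$center)^2 / (2 * bump$width^2))
  }
  list(t = t, y = y, apex_time = rise + plateau / 2, end_time = total)
}

#' Sample one beat waveform with ground truth
#'
#' Draws nothing itself unless `abnormality` requires it; the shape comes
#' straight from `params`, so the constructed maximum-minus-onset equals
#' `params$amplitude` (within grid resolution) for normal beats.
#'
#' @param params A [peak_shape_params()].
#' @param abnormality `NULL` for a normal beat, or one of `"double_hump"`,
#'   `"amplitude_alternation"`, `"plateau"`, `"irregular_interval"`.
#' @param sample_rate Sampling rate in Hz.
#' @return A list with `time` (from onset), `value` (including
#'   `baseline_level`), and `annotation` (onset/apex/end times relative to
#'   the onset, plus the abnormality flag).
#' @export
sample_peak_shape <- function(params, abnormality = NULL, sample_rate = 50) {
  if (!inherits(params, "ct_peak_shape")) {
    abort("`params` must come from peak_shape_params().")
  }
  if (!is.null(abnormality) && !abnormality %in% ct_abnormality_kinds) {
    abort(sprintf("unknown abnormality kind '%s'.", abnormality))
  }
  dt <- 1 / sample_rate
  amp <- params$amplitude
  plateau <- 0
  bump <- NULL
  kind <- abnormality %||% "none"
  if (kind == "amplitude_alternation") amp <- 0.4 * amp
  if (kind == "plateau") plateau <- 0.5 * params$decay_duration
  if (kind == "double_hump") {
    bump <- list(height = 0.45 * amp,
                 center = params$rise_duration + 0.55 * params$decay_duration,
                 width = params$decay_duration / 8)
  }
  w <- beat_waveform(amp, params$rise_duration, params$decay_duration,
                     plateau = plateau, dt = dt, bump = bump)
  list(
    time = w$t,
    value = params$baseline_level + w$y,
    annotation = tibble::tibble(
      onset_time = 0, apex_time = w$apex_time, end_time = w$end_time,
      amplitude = amp, abnormal = kind != "none", kind = kind
    )
  )
}

rtrunc_norm <- function(n, mean, sd, lower) {
  pmax(rnorm(n, mean, sd), lower)
}

#' Generate one labelled signal with ground-truth beat annotations
#'
#' Beats are placed apex-to-apex at intervals drawn from the configured
#' distribution (clamped so consecutive beats never overlap), superposed on
#' the baseline level, and Gaussian noise is added. The emitted trace is
#' divided by 1000 so it lives on the raw Fura-2 ratio scale like a real
#' recording; [scale_amplitudes()] in the analysis pipeline restores the
#' scaled units the generator is parameterised in. The annotation (scaled
#' units, absolute seconds) records the realised onset/apex/end of every
#' beat and its abnormality flag.
#'
#' @param cfg A [class_gen_config()].
#' @param signal_id Identifier for the generated signal.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with `signal` (a [ct_signal()]) and `annotation` (tibble
#'   with one row per beat).
#' @export
generate_signal <- function(cfg, signal_id = "synthetic", seed = cfg$seed) {
  if (!inherits(cfg, "ct_gen_config")) {
    abort("`cfg` must come from class_gen_config().")
  }
  with_ct_seed(seed, generate_signal_impl(cfg, signal_id))
}

generate_signal_impl <- function(cfg, signal_id) {
  m <- cfg$shape_means
  s <- cfg$shape_sds
  dt <- 1 / cfg$sample_rate
  n <- round(cfg$duration / dt) + 1L
  t_grid <- (seq_len(n) - 1L) * dt
  if (cfg$duration < m$rise_duration + m$decay_duration) {
    abort("`duration` is too short for a single beat.")
  }

  # Amplitudes are positive and right-skewed in real recordings, so they are
  # drawn lognormally with moments matched to (mean, sd); durations and
  # intervals use truncated Gaussians.
  ln_sigma2 <- log(1 + (s$amplitude / m$amplitude)^2)
  ln_mu <- log(m$amplitude) - ln_sigma2 / 2

  # per-signal mean shape (between-signal variation)
  sig_mean <- list(
    log_amplitude = rnorm(1, ln_mu, cfg$signal_sd_frac * sqrt(ln_sigma2)),
    rise_duration = rtrunc_norm(1, m$rise_duration,
                                cfg$signal_sd_frac * s$rise_duration, 0.08),
    decay_duration = rtrunc_norm(1, m$decay_duration,
                                 cfg$signal_sd_frac * s$decay_duration, 0.12),
    interval = rtrunc_norm(1, m$interval, cfg$signal_sd_frac * s$interval, 0.3)
  )

  values <- rep(m$baseline_level, n)
  ann <- list()
  apex <- 0
  prev_decay <- 0
  repeat {
    amp <- exp(rnorm(1, sig_mean$log_amplitude,
                     cfg$beat_sd_frac * sqrt(ln_sigma2)))
    rise <- rtrunc_norm(1, sig_mean$rise_duration,
                        cfg$beat_sd_frac * s$rise_duration, 0.08)
    decay <- rtrunc_norm(1, sig_mean$decay_duration,
                         cfg$beat_sd_frac * s$decay_duration, 0.12)
    abnormal <- runif(1) < cfg$abnormal_fraction
    kind <- if (abnormal) {
      sample(ct_abnormality_kinds, 1, prob = cfg$abnormality_mix)
    } else "none"

    gap <- rtrunc_norm(1, sig_mean$interval, cfg$beat_sd_frac * s$interval, 0.3)
    if (kind == "irregular_interval") gap <- gap * runif(1, 0.3, 0.6)
    # beats must not overlap: next onset strictly after the previous end
    gap <- max(gap, prev_decay + rise + 3 * dt)
    apex <- apex + gap
    plateau <- if (kind == "plateau") 0.5 * decay else 0
    end_time <- apex + plateau / 2 + decay
    if (end_time > cfg$duration) break

    params <- peak_shape_params(amp, rise, decay, sig_mean$interval,
                                m$baseline_level)
    beat <- sample_peak_shape(params,
                              abnormality = if (abnormal) kind else NULL,
                              sample_rate = cfg$sample_rate)
    onset <- apex - rise - plateau / 2
    i0 <- round(onset / dt) + 1L
    idx <- i0 + seq_along(beat$value) - 1L
    keep <- idx >= 1L & idx <= n
    values[idx[keep]] <- values[idx[keep]] +
      (beat$value[keep] - m$baseline_level)
    ann[[length(ann) + 1L]] <- tibble::tibble(
      onset_time = (i0 - 1L) * dt,
      apex_time = (i0 - 1L) * dt + beat$annotation$apex_time,
      end_time = (i0 - 1L) * dt + beat$annotation$end_time,
      amplitude = beat$annotation$amplitude,
      abnormal = abnormal, kind = kind
    )
    prev_decay <- plateau / 2 + decay
  }
  if (!length(ann)) {
    abort("`duration` is too short for a single beat at the drawn intervals.")
  }
  if (cfg$noise_sd > 0) values <- values + rnorm(n, 0, cfg$noise_sd)
  # emit on the raw ratio scale; the pipeline's x1000 amplitude scaling
  # restores the scaled units the generator is parameterised in
  values <- values / 1000

  resp <- if (cfg$condition == "dantrolene") cfg$label else "none"
  sig <- ct_signal(t_grid, values, signal_id = signal_id,
                   cell_line = cfg$cell_line, condition = cfg$condition,
                   response_class = resp)
  annotation <- dplyr::bind_rows(ann)
  annotation$signal_id <- signal_id
  annotation$beat <- seq_len(nrow(annotation))
  list(signal = sig, annotation = annotation)
}

#' Generate a labelled multi-class dataset
#'
#' Runs [generate_signal()] for every configuration, collecting signals,
#' manifest metadata and ground-truth annotations. When `dir` is given the
#' signals are written as two-column CSVs together with `manifest.csv` and
#' `annotations.csv`; otherwise everything stays in memory.
#'
#' @param configs List of [class_gen_config()] objects.
#' @param dir Optional output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param seed Integer master seed; per-signal seeds are derived from it so
#'   two distinct seeds give distinct datasets and the same seed reproduces
#'   the dataset exactly.
#' @return A list with `dataset` (tibble with a `signal` list-column, as
#'   [read_ct_dataset()] returns), `manifest`, and `annotations`.
#' @export
generate_dataset <- function(configs, dir = NULL, overwrite = FALSE,
                             seed = 1L) {
  if (!length(configs)) abort("`configs` must be non-empty.")
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
      abort(sprintf("output directory '%s' is not empty (use overwrite = TRUE).", dir))
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  rows <- list(); anns <- list(); sigs <- list()
  counter <- 0L
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (k in seq_len(cfg$n_signals)) {
      counter <- counter + 1L
      id <- sprintf("%s_%03d", cfg$label, k)
      # distinct, reproducible stream per signal, bounded below 2^31
      sseed <- (as.integer(seed) * 10007L + counter * 97L) %% 2147483629L
      g <- generate_signal(cfg, signal_id = id, seed = sseed)
      sigs[[counter]] <- g$signal
      anns[[counter]] <- g$annotation
      rows[[counter]] <- tibble::tibble(
        signal_id = id,
        file = paste0(id, ".csv"),
        cell_line = cfg$cell_line,
        condition = cfg$condition,
        response_class = attr(g$signal, "response_class")
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  annotations <- dplyr::bind_rows(anns)
  dataset <- manifest[setdiff(names(manifest), "file")]
  dataset$signal <- sigs
  if (!is.null(dir)) {
    purrr::walk2(sigs, manifest$file,
                 ~ write_ct_signal(.x, file.path(dir, .y)))
    readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
    readr::write_csv(annotations, file.path(dir, "annotations.csv"),
                     progress = FALSE)
  }
  list(dataset = dataset, manifest = manifest, annotations = annotations)
}

#' Generator presets
#'
#' Ready-made configuration sets:
#'
#' * `"study"` emulates a 128-signal-per-condition drug study: 128 baseline,
#'   128 adrenaline and 128 dantrolene signals, the latter split 59
#'   responders / 28 semi-responders / 41 non-responders, with per-condition
#'   beat morphology centred on published summary statistics (e.g. baseline
#'   amplitude 277 scaled units, rise 0.212 s, decay 0.438 s, interval
#'   1.038 s; adrenaline interval 0.672 s).
#' * `"tiny"` is the same class structure at 6/6/(3, 2, 3) signals for quick
#'   checks.
#' * `"demo3"` is a deliberately well-separated three-class dantrolene set
#'   (20 signals per class, 12 s each) used to demonstrate the end-to-end
#'   classification pipeline.
#'
#' @param preset One of `"study"`, `"tiny"`, `"demo3"`.
#' @param seed Base seed stored in the configs.
#' @return A named list of [class_gen_config()] objects.
#' @export
ct_presets <- function(preset = c("study", "tiny", "demo3"), seed = 1L) {
  preset <- match.arg(preset)
  shapes <- list(
    baseline = list(
      means = peak_shape_params(277, 0.212, 0.438, 1.038, 100),
      sds = list(amplitude = 181, rise_duration = 0.109,
                 decay_duration = 0.303, interval = 0.603),
      abn = 0.30, cond = "baseline"
    ),
    adrenaline = list(
      means = peak_shape_params(252, 0.213, 0.397, 0.672, 100),
      sds = list(amplitude = 171, rise_duration = 0.107,
                 decay_duration = 0.247, interval = 0.440),
      abn = 0.50, cond = "adrenaline"
    ),
    responder = list(
      means = peak_shape_params(236, 0.247, 0.424, 1.082, 100),
      sds = list(amplitude = 168, rise_duration = 0.097,
                 decay_duration = 0.229, interval = 0.443),
      abn = 0, cond = "dantrolene"
    ),
    semi_responder = list(
      means = peak_shape_params(257, 0.243, 0.413, 1.017, 100),
      sds = list(amplitude = 174, rise_duration = 0.099,
                 decay_duration = 0.136, interval = 0.267),
      abn = 0.20, cond = "dantrolene"
    ),
    non_responder = list(
      means = peak_shape_params(163, 0.228, 0.347, 0.674, 100),
      sds = list(amplitude = 133, rise_duration = 0.106,
                 decay_duration = 0.219, interval = 0.421),
      abn = 0.55, cond = "dantrolene"
    )
  )
  n_study <- c(baseline = 128, adrenaline = 128, responder = 59,
               semi_responder = 28, non_responder = 41)
  n_tiny <- c(baseline = 6, adrenaline = 6, responder = 3,
              semi_responder = 2, non_responder = 3)

  if (preset %in% c("study", "tiny")) {
    ns <- if (preset == "study") n_study else n_tiny
    dur <- if (preset == "study") 20 else 12
    cfgs <- purrr::imap(shapes, function(sh, lab) {
      class_gen_config(
        label = lab, n_signals = ns[[lab]], shape_means = sh$means,
        shape_sds = sh$sds, abnormal_fraction = sh$abn,
        noise_sd = 0.02 * sh$means$amplitude, duration = dur,
        condition = sh$cond, seed = seed
      )
    })
    return(cfgs)
  }

  # demo3: exaggerated class separation, low dispersion, low noise
  demo <- list(
    responder = list(means = peak_shape_params(300, 0.25, 0.45, 1.15, 100),
                     abn = 0),
    semi_responder = list(means = peak_shape_params(200, 0.20, 0.35, 0.90, 100),
                          abn = 0.25),
    non_responder = list(means = peak_shape_params(120, 0.15, 0.28, 0.60, 100),
                         abn = 0.60)
  )
  purrr::imap(demo, function(sh, lab) {
    class_gen_config(
      label = lab, n_signals = 20, shape_means = sh$means,
      shape_sds = list(amplitude = 20, rise_duration = 0.02,
                       decay_duration = 0.03, interval = 0.08),
      abnormal_fraction = sh$abn,
      noise_sd = 0.01 * sh$means$amplitude, duration = 12,
      condition = "dantrolene", seed = seed
    )
  })
}
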