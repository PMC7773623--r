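#' Construct a calcium transient signal
#'
#' Bundles one cardiomyocyte's Fura-2 340/380 ratio trace with its metadata.
#' The result is a tibble with columns `time` (seconds) and `value`
#' (fluorescence ratio; "scaled units" after [scale_amplitudes()]), carrying
#' the signal id, cell line, recording condition, dantrolene response class
#' and the uniform sample interval as attributes.
#'
#' Time stamps must be strictly increasing. Mild jitter in the sampling grid
#' (time steps within 1% of the median step) is resampled onto the uniform
#' median-step grid by linear interpolation, because the derivative operators
#' downstream assume uniform sampling; larger irregularity is an error.
#'
#' @param time Numeric vector of strictly increasing times in seconds.
#' @param value Numeric vector of ratio samples, same length as `time`.
#' @param signal_id Identifier for the signal.
#' @param cell_line Cell line / mutation label.
#' @param condition One of `"baseline"`, `"adrenaline"`, `"dantrolene"`.
#' @param response_class One of `"responder"`, `"semi_responder"`,
#'   `"non_responder"`, `"none"`. Must be `"none"` unless the condition is
#'   `"dantrolene"`.
#' @return A `ct_signal` tibble.
#' @export
ct_signal <- function(time, value, signal_id = "signal",
                      cell_line = "unknown",
                      condition = c("baseline", "adrenaline", "dantrolene"),
                      response_class = c("none", "responder",
                                         "semi_responder", "non_responder")) {
  condition <- match.arg(condition)
  response_class <- match.arg(response_class)
  if (length(time) != length(value)) {
    abort("`time` and `value` must have the same length.")
  }
  if (length(time) < 2L) {
    abort("a signal needs at least 2 samples.")
  }
  if (anyNA(time) || anyNA(value)) {
    abort("`time` and `value` must not contain missing values.")
  }
  steps <- diff(time)
  if (any(steps <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  if (condition != "dantrolene" && response_class != "none") {
    abort("`response_class` must be \"none\" unless condition is \"dantrolene\".")
  }
  dt <- median(steps)
  jitter <- max(abs(steps - dt)) / dt
  if (jitter > 1e-9) {
    if (jitter > 0.01) {
      abort(sprintf(
        "signal '%s': time steps deviate by %.1f%% from the median step; only 1%% jitter is tolerated.",
        signal_id, 100 * jitter
      ))
    }
    grid <- seq(time[1], time[length(time)], by = dt)
    value <- stats::approx(time, value, xout = grid)$y
    time <- grid
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  structure(out,
    class = c("ct_signal", class(out)),
    signal_id = signal_id, cell_line = cell_line,
    condition = condition, response_class = response_class,
    sample_interval = dt
  )
}

signal_meta <- function(signal) {
  tibble::tibble(
    signal_id = attr(signal, "signal_id"),
    cell_line = attr(signal, "cell_line"),
    condition = attr(signal, "condition"),
    response_class = attr(signal, "response_class"),
    sample_interval = attr(signal, "sample_interval")
  )
}

#' @export
print.ct_signal <- function(x, ...) {
  m <- signal_meta(x)
  cat(sprintf(
    "<ct_signal> %s  [%s, %s%s]  %d samples @ %.4g s\n",
    m$signal_id, m$cell_line, m$condition,
    if (m$response_class != "none") paste0("/", m$response_class) else "",
    nrow(x), m$sample_interval
  ))
  NextMethod()
}

#' Read one calcium transient signal from CSV
#'
#' Expects a two-column CSV with header `time_s, ratio`. Metadata usually
#' comes from a manifest row (see [read_ct_manifest()]); the sample interval
#' is inferred from the median time step.
#'
#' @param path Path to the CSV file.
#' @inheritParams ct_signal
#' @return A [ct_signal()] tibble.
#' @export
read_ct_signal <- function(path, signal_id = NULL, cell_line = "unknown",
                           condition = "baseline", response_class = "none") {
  if (!file.exists(path)) {
    abort(sprintf("signal file '%s' does not exist.", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "ratio") %in% names(df))) {
    abort(sprintf(
      "signal file '%s' must have columns 'time_s' and 'ratio' (found: %s).",
      path, paste(names(df), collapse = ", ")
    ))
  }
  if (nrow(df) < 2L) {
    abort(sprintf("signal file '%s' has fewer than 2 samples.", path))
  }
  if (any(diff(df$time_s) <= 0)) {
    abort(sprintf("signal file '%s': time_s is not strictly increasing.", path))
  }
  ct_signal(df$time_s, df$ratio,
    signal_id = signal_id %||% sub("\\.[^.]*$", "", basename(path)),
    cell_line = cell_line, condition = condition,
    response_class = response_class
  )
}

#' Write a signal back to its CSV representation
#'
#' @param signal A [ct_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_signal <- function(signal, path) {
  readr::write_csv(
    tibble::tibble(time_s = signal$time, ratio = signal$value),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with columns `signal_id, file, cell_line, condition,
#' response_class`, one row per signal. Relative file paths are resolved
#' against the manifest's directory. Signal ids must be unique, condition and
#' response-class tokens must be known, and non-dantrolene rows must have
#' response class `none`.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that every referenced signal file exists.
#' @return A `ct_manifest` tibble with resolved `file` paths.
#' @export
read_ct_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("manifest '%s' does not exist.", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("signal_id", "file", "cell_line", "condition", "response_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("manifest '%s' lacks columns: %s.", path,
                  paste(missing, collapse = ", ")))
  }
  dup <- df$signal_id[duplicated(df$signal_id)]
  if (length(dup)) {
    abort(sprintf("manifest '%s': duplicate signal_id(s): %s.", path,
                  paste(unique(dup), collapse = ", ")))
  }
  bad_cond <- which(!df$condition %in% ct_conditions)
  bad_resp <- which(!df$response_class %in% ct_response_classes |
                      (df$condition != "dantrolene" & df$response_class != "none"))
  if (length(bad_cond) || length(bad_resp)) {
    abort(sprintf(
      "manifest '%s': invalid condition/response_class in row(s): %s.",
      path, paste(sort(unique(c(bad_cond, bad_resp))), collapse = ", ")
    ))
  }
  dir <- dirname(path)
  df$file <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$file), df$file, file.path(dir, df$file)
  )
  if (check_files) {
    absent <- df$file[!file.exists(df$file)]
    if (length(absent)) {
      abort(sprintf("manifest '%s': missing signal file(s): %s.", path,
                    paste(absent, collapse = ", ")))
    }
  }
  structure(df, class = c("ct_manifest", class(df)))
}

#' Load every signal listed in a manifest
#'
#' @param manifest A `ct_manifest` from [read_ct_manifest()].
#' @return A tibble with one row per signal: the manifest metadata plus a
#'   `signal` list-column of [ct_signal()] objects.
#' @export
read_ct_dataset <- function(manifest) {
  sigs <- purrr::pmap(
    list(manifest$file, manifest$signal_id, manifest$cell_line,
         manifest$condition, manifest$response_class),
    function(file, id, line, cond, resp) {
      read_ct_signal(file, signal_id = id, cell_line = line,
                     condition = cond, response_class = resp)
    }
  )
  out <- tibble::as_tibble(manifest[setdiff(names(manifest), "file")])
  out$signal <- sigs
  out
}

#' Rescale signal amplitudes
#'
#' Ratio traces live on a unit scale; before peak recognition all amplitude
#' values are multiplied by 1000 so the per-peak variables come out in
#' convenient "scaled units". Times and metadata are untouched.
#'
#' @param signal A [ct_signal()].
#' @param factor Positive multiplier (default 1000).
#' @return The rescaled `ct_signal`.
#' @export
scale_amplitudes <- function(signal, factor = 1000) {
  assert_scalar_number(factor, "factor", positive = TRUE)
  signal$value <- signal$value * factor
  signal
}
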