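# Preprocessing: raw trials -> fixed-size network input/target blocks.

#' Stance window constructor
#'
#' Half-open sample-index window `[start, end)` on the GRF time base
#' (1-based: samples `start` through `end - 1` are inside the window).
#'
#' @param start first sample index inside the window (1-based).
#' @param end first sample index after the window.
#' @return object of class `stance_window`.
#' @export
stance_window <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end <= start) {
    stop_kneeload("invalid stance window [", start, ", ", end, ")",
      class = "kneeload_stance_error"
    )
  }
  structure(list(start = start, end = end), class = "stance_window")
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass filtering,
#' the standard smoothing step for biomechanical signals. The effective
#' magnitude response is the squared single-pass response and the phase
#' response is identically zero, so peaks are not shifted in time. Edge
#' transients are controlled by odd-symmetric signal extension plus
#' steady-state initial conditions, so a constant signal passes through
#' unchanged to machine precision.
#'
#' @param x numeric vector, or matrix whose columns are filtered
#'   independently.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 15, the conventional cutoff
#'   for gait kinetics).
#' @param order single-pass filter order (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' noisy <- sin(2 * pi * 2 * t) + 0.1 * sin(2 * pi * 200 * t)
#' smooth <- lowpass_zero_phase(noisy, rate = 1000)
lowpass_zero_phase <- function(x, rate, cutoff = 15, order = 4) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- lowpass_zero_phase(x[, j], rate, cutoff, order)
    return(out)
  }
  assert_scalar_number(rate, "rate", positive = TRUE)
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  n <- length(x)
  if (n <= 3 * order) {
    stop_kneeload("signal too short to filter (need > ", 3 * order, " samples)",
      class = "kneeload_filter_error"
    )
  }
  if (cutoff >= rate / 2) {
    stop_kneeload("cutoff must be below the Nyquist frequency ", rate / 2, " Hz",
      class = "kneeload_filter_error"
    )
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  nfilt <- max(length(bf$b), length(bf$a))
  # odd extension long enough for start-up transients to die out inside it
  pad <- min(n - 1L, max(3L * (nfilt - 1L), ceiling(6 * rate / cutoff)))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(pre, x, post)
  pass <- function(s) {
    # steady-state initial conditions for a DC-gain-1 low-pass: past inputs
    # and outputs equal to the first sample
    signal::filter(bf, s,
      init.x = rep(s[1], nfilt - 1L),
      init.y = rep(s[1], nfilt - 1L)
    )
  }
  yp <- rev(pass(xp))
  yp <- rev(pass(yp))
  unclass(yp)[pad + seq_len(n)]
}

#' Detect the stance phase from the vertical ground reaction force
#'
#' The stance phase is the longest contiguous run of samples at or above the
#' force threshold - 20 N by convention for foot-contact detection. No
#' debouncing is applied; the longest-run rule is robust to sub-threshold
#' swing-phase noise.
#'
#' @param vgrf vertical GRF samples in Newtons.
#' @param threshold contact threshold in Newtons (default 20).
#' @return a [stance_window()] (half-open, 1-based).
#' @export
detect_stance <- function(vgrf, threshold = 20) {
  if (length(vgrf) == 0) {
    stop_kneeload("empty vertical GRF signal", class = "kneeload_stance_error")
  }
  runs <- rle(vgrf >= threshold)
  if (!any(runs$values)) {
    stop_kneeload("no stance detected: no sample reaches ", threshold, " N",
      class = "kneeload_stance_error"
    )
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- which(runs$values)
  best <- on[which.max(runs$lengths[on])]
  stance_window(starts[best], ends[best] + 1L)
}

#' Crop a trial's streams to a stance window
#'
#' GRF-rate streams (vertical GRF, reference moments) are sliced to
#' `[start, end)`. The IMU stream is sliced to the same time interval by
#' rate-ratio index mapping with round-half-up at the boundaries, so the two
#' cropped streams cover the same duration to within one IMU sample.
#'
#' @param trial a `raw_trial`.
#' @param window a [stance_window()] on the GRF time base.
#' @return list with `imu` (matrix), `vgrf`, `ref_moments`, cropped.
#' @export
crop_to_stance <- function(trial, window) {
  T_grf <- length(trial$vgrf)
  if (window$end > T_grf + 1L) {
    stop_kneeload("stance window [", window$start, ", ", window$end,
      ") outside trial of length ", T_grf,
      class = "kneeload_stance_error"
    )
  }
  ratio <- trial$imu_rate / trial$grf_rate
  # 0-based boundary mapping with round-half-up, then back to 1-based slices
  imu_start0 <- floor((window$start - 1L) * ratio + 0.5)
  imu_end0 <- floor((window$end - 1L) * ratio + 0.5)
  imu_end0 <- min(imu_end0, nrow(trial$imu))
  list(
    imu = trial$imu[(imu_start0 + 1L):imu_end0, , drop = FALSE],
    vgrf = trial$vgrf[window$start:(window$end - 1L)],
    ref_moments = trial$ref_moments[window$start:(window$end - 1L), , drop = FALSE]
  )
}

#' Time-normalize a series to a fixed number of stance-percent steps
#'
#' Linear interpolation of a `K x C` series onto `n` equally spaced query
#' points spanning the first through last sample inclusive, i.e. 0-100% of
#' the stance phase. The first and last output rows equal the first and last
#' input rows, and a series already on the target grid passes through
#' unchanged.
#'
#' @param series numeric vector or `K x C` matrix, `K >= 2`.
#' @param n number of output steps (default 100).
#' @return `n x C` matrix (or length-`n` vector for vector input).
#' @export
time_normalize <- function(series, n = 100) {
  vec_in <- !is.matrix(series)
  m <- if (vec_in) matrix(series, ncol = 1) else series
  K <- nrow(m)
  if (K < 2) {
    stop_kneeload("need at least 2 samples to time-normalize", class = "kneeload_preprocess_error")
  }
  xin <- seq(0, 1, length.out = K)
  xout <- seq(0, 1, length.out = n)
  out <- apply(m, 2, function(col) stats::approx(xin, col, xout = xout)$y)
  out <- matrix(out, nrow = n, dimnames = list(NULL, colnames(m)))
  if (vec_in) drop(out) else out
}

#' Normalize joint moments by body mass
#'
#' Elementwise division of moment amplitudes (Nm) by body mass (kg), giving
#' the conventional body-mass-normalized moments (Nm/kg) that make
#' participants comparable.
#'
#' @param moments numeric vector or matrix in Nm.
#' @param body_mass_kg body mass in kg (> 0).
#' @return moments in Nm/kg.
#' @export
normalize_moments <- function(moments, body_mass_kg) {
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1L ||
    !is.finite(body_mass_kg) || body_mass_kg <= 0) {
    stop_kneeload("body mass must be a single positive number", class = "kneeload_preprocess_error")
  }
  moments / body_mass_kg
}

#' Preprocess one raw trial into a normalized input/target block
#'
#' The full per-trial pipeline: (1) zero-phase low-pass filter the raw IMU
#' stream (full stream, before cropping, to keep filter edge effects out of
#' the stance phase); (2) detect the stance window from the raw vertical
#' GRF at the 20 N threshold; (3) crop IMU and GRF-rate streams to the
#' window; (4) time-normalize both to `n_steps` stance-percent steps;
#' (5) normalize the reference moments by body mass. The result is the
#' 100 x 12 input block and 100 x 2 target block (Nm/kg, external moment
#' convention: flexion and adduction positive) for one stance phase.
#'
#' @param trial a `raw_trial`.
#' @param n_steps stance-percent steps (default 100).
#' @param cutoff IMU low-pass cutoff in Hz (default 15).
#' @param threshold stance-detection threshold in Newtons (default 20).
#' @return object of class `normalized_trial`: `inputs` (`n_steps x 12`),
#'   `targets` (`n_steps x 2`), plus trial metadata.
#' @export
preprocess_trial <- function(trial, n_steps = 100, cutoff = 15, threshold = 20) {
  imu_f <- lowpass_zero_phase(trial$imu, rate = trial$imu_rate, cutoff = cutoff)
  window <- detect_stance(trial$vgrf, threshold = threshold)
  cropped <- crop_to_stance(
    list(
      imu = imu_f, vgrf = trial$vgrf, ref_moments = trial$ref_moments,
      imu_rate = trial$imu_rate, grf_rate = trial$grf_rate
    ),
    window
  )
  inputs <- time_normalize(cropped$imu, n = n_steps)
  targets <- time_normalize(cropped$ref_moments, n = n_steps)
  targets <- normalize_moments(targets, trial$body_mass_kg)
  structure(
    list(
      inputs = inputs, targets = targets,
      participant_id = trial$participant_id, task = trial$task,
      trial_index = trial$trial_index, stance_window = window
    ),
    class = "normalized_trial"
  )
}

#' Preprocess every trial of a cohort
#'
#' @param trials list of `raw_trial` objects, or a cohort as returned by
#'   [generate_cohort()] (elements with `$trial`).
#' @inheritParams preprocess_trial
#' @return list of `normalized_trial` objects.
#' @export
preprocess_cohort <- function(trials, n_steps = 100, cutoff = 15, threshold = 20) {
  lapply(trials, function(x) {
    tr <- if (!is.null(x[["trial"]])) x[["trial"]] else x
    preprocess_trial(tr, n_steps = n_steps, cutoff = cutoff, threshold = threshold)
  })
}

#' Assemble network input/target matrices from normalized trials
#'
#' Vertically concatenates the per-trial blocks into the design matrices the
#' network consumes: `X` with one column per IMU channel (12) and `Y` with
#' two columns (KFM, KAM) for the combined model or one column for an
#' independent single-output model. Rows of a trial stay contiguous, and
#' `row_index` records (participant, task, trial, step) per row.
#'
#' @param trials list of `normalized_trial` objects.
#' @param outputs `"both"` (KFM + KAM), `"kfm"`, or `"kam"`.
#' @return list of class `dataset_matrices`: `X`, `Y`, `row_index`
#'   (data frame), `outputs`.
#' @export
assemble_matrices <- function(trials, outputs = c("both", "kfm", "kam")) {
  outputs <- match.arg(outputs)
  if (length(trials) == 0) {
    stop_kneeload("empty trial list", class = "kneeload_preprocess_error")
  }
  n_steps <- nrow(trials[[1]]$inputs)
  bad <- vapply(trials, function(t) nrow(t$inputs) != n_steps || nrow(t$targets) != n_steps, logical(1))
  if (any(bad)) {
    stop_kneeload("inconsistent block sizes across trials", class = "kneeload_preprocess_error")
  }
  X <- do.call(rbind, lapply(trials, `[[`, "inputs"))
  Y_full <- do.call(rbind, lapply(trials, `[[`, "targets"))
  Y <- switch(outputs,
    both = Y_full,
    kfm = Y_full[, "kfm", drop = FALSE],
    kam = Y_full[, "kam", drop = FALSE]
  )
  row_index <- data.frame(
    participant = rep(vapply(trials, `[[`, "", "participant_id"), each = n_steps),
    task = rep(vapply(trials, `[[`, "", "task"), each = n_steps),
    trial = rep(vapply(trials, function(t) as.integer(t$trial_index), 1L), each = n_steps),
    step = rep(seq_len(n_steps), times = length(trials)),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, Y = Y, row_index = row_index, outputs = outputs),
    class = "dataset_matrices"
  )
}
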