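# Synthetic gait cohort generator.
#
# Emulates the statistical structure of a two-IMU knee-sleeve gait study:
# n participants x six locomotion tasks x k trials, each trial carrying two
# 6-channel IMU streams (thigh, shank), a vertical ground reaction force
# channel, and reference knee flexion / adduction moment (KFM / KAM) series.
# The IMU channels are, by construction, a fixed linear mixture of the latent
# normalized moment curves, their stance-phase derivatives and two gait
# harmonics, so the IMU -> moment relationship the estimator must learn
# exists exactly (up to configured noise) and is invertible - which is what
# makes parameter-recovery testing of the full pipeline possible.

#' The six locomotion task labels
#'
#' Ordered task labels of the simulated protocol: linear gait at three
#' intensities plus three change-of-direction movements.
#'
#' @return character vector of length 6.
#' @export
kneeload_tasks <- function() {
  c(
    "walking straight", "90° walking turn", "moderate running",
    "fast running", "90° running turn", "45° cutting maneuver"
  )
}

#' Cohort simulation configuration
#'
#' @param n_participants number of participants (>= 2); default 13 matches
#'   the cohort size of the validation study the simulator emulates.
#' @param trials_per_task successful trials per participant and task
#'   (default 3).
#' @param tasks ordered subset of [kneeload_tasks()] (default: all six).
#' @param imu_rate IMU sampling rate in Hz (default 1500).
#' @param grf_rate force-plate sampling rate in Hz (default 1000).
#' @param participant_gain_sd standard deviation of the per-participant
#'   variability: a scalar amplitude gain on the moment curves and a
#'   multiplicative perturbation of the participant's IMU mixing matrix
#'   (sensor-mounting variation). 0 gives a cohort with an exactly shared
#'   IMU -> moment mapping. Default 0.1.
#' @param noise_sd relative sensor noise level: Gaussian noise with standard
#'   deviation `noise_sd` times each channel's amplitude scale is added to
#'   the IMU channels and (scaled down) to the reference moments. Default
#'   0.02.
#' @param seed integer master seed; identical configurations produce
#'   bit-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 13, trials_per_task = 3,
                          tasks = kneeload_tasks(),
                          imu_rate = 1500, grf_rate = 1000,
                          participant_gain_sd = 0.1, noise_sd = 0.02,
                          seed = 1) {
  assert_scalar_number(n_participants, "n_participants", positive = TRUE)
  assert_scalar_number(trials_per_task, "trials_per_task", positive = TRUE)
  assert_scalar_number(imu_rate, "imu_rate", positive = TRUE)
  assert_scalar_number(grf_rate, "grf_rate", positive = TRUE)
  assert_scalar_number(participant_gain_sd, "participant_gain_sd")
  assert_scalar_number(noise_sd, "noise_sd")
  assert_scalar_number(seed, "seed")
  if (n_participants < 2) {
    stop_kneeload("n_participants must be >= 2", class = "kneeload_config_error")
  }
  if (participant_gain_sd < 0 || noise_sd < 0) {
    stop_kneeload("noise levels must be >= 0", class = "kneeload_config_error")
  }
  unknown <- setdiff(tasks, kneeload_tasks())
  if (length(unknown) > 0 || length(tasks) == 0 || anyDuplicated(tasks)) {
    stop_kneeload(
      "tasks must be a non-empty duplicate-free subset of kneeload_tasks(); unknown: ",
      paste(unknown, collapse = ", "),
      class = "kneeload_task_error"
    )
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_task = as.integer(trials_per_task),
      tasks = tasks,
      imu_rate = imu_rate, grf_rate = grf_rate,
      participant_gain_sd = participant_gain_sd, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Gaussian bump basis for stance-phase moment shapes: p in [0, 1].
eval_bumps <- function(p, bumps) {
  out <- numeric(length(p))
  for (i in seq_len(nrow(bumps))) {
    out <- out + bumps$amp[i] * exp(-((p - bumps$center[i]) / bumps$width[i])^2 / 2)
  }
  out
}

# Normalize a bump set so its peak absolute value over stance is exactly 1.
normalize_bumps <- function(bumps) {
  p <- seq(0, 1, length.out = 2001)
  bumps$amp <- bumps$amp / max(abs(eval_bumps(p, bumps)))
  bumps
}

bump_df <- function(amp, center, width) data.frame(amp = amp, center = center, width = width)

# Template registry. Peak scales (Nm/kg) follow published per-task reference
# peaks of the movement protocol the simulator emulates; stance durations are
# literature-typical values for self-selected speed (no protocol speeds are
# published, so these are deliberately generic).
task_template_table <- function() {
  list(
    "walking straight" = list(
      kfm_bumps = bump_df(c(1.0, 0.85), c(0.30, 0.72), c(0.10, 0.10)),
      kam_bumps = bump_df(c(1.0, 0.80), c(0.28, 0.70), c(0.10, 0.11)),
      stance_duration_s = 0.62, grf_profile = "double_hump",
      peak_scale = c(kfm = 0.67, kam = 0.54)
    ),
    "90° walking turn" = list(
      kfm_bumps = bump_df(c(1.0, 0.75), c(0.32, 0.74), c(0.11, 0.10)),
      kam_bumps = bump_df(c(1.0, 0.70), c(0.30, 0.72), c(0.11, 0.11)),
      stance_duration_s = 0.68, grf_profile = "double_hump",
      peak_scale = c(kfm = 1.02, kam = 0.57)
    ),
    "moderate running" = list(
      kfm_bumps = bump_df(1.0, 0.45, 0.13),
      kam_bumps = bump_df(1.0, 0.40, 0.12),
      stance_duration_s = 0.25, grf_profile = "single_hump",
      peak_scale = c(kfm = 2.03, kam = 0.52)
    ),
    "fast running" = list(
      kfm_bumps = bump_df(1.0, 0.43, 0.12),
      kam_bumps = bump_df(1.0, 0.38, 0.11),
      stance_duration_s = 0.20, grf_profile = "single_hump",
      peak_scale = c(kfm = 2.49, kam = 0.77)
    ),
    "90° running turn" = list(
      kfm_bumps = bump_df(1.0, 0.46, 0.13),
      kam_bumps = bump_df(c(1.0, -0.20), c(0.40, 0.85), c(0.12, 0.06)),
      stance_duration_s = 0.27, grf_profile = "single_hump",
      peak_scale = c(kfm = 2.20, kam = 0.60)
    ),
    "45° cutting maneuver" = list(
      kfm_bumps = bump_df(1.0, 0.44, 0.13),
      kam_bumps = bump_df(c(1.0, -0.25), c(0.40, 0.85), c(0.12, 0.06)),
      stance_duration_s = 0.30, grf_profile = "single_hump",
      peak_scale = c(kfm = 2.52, kam = 0.61)
    )
  )
}

#' Stance-phase template for a locomotion task
#'
#' Each task is described by parametric stance-phase curves: the KFM shape is
#' a sum of Gaussian bumps (two bumps for walking tasks, one for running and
#' cutting), the KAM shape one bump with an optional sign-flipping late-stance
#' tail for the change-of-direction tasks, plus a typical stance duration, a
#' vertical-GRF profile family ("double_hump" for walking, "single_hump" for
#' running/cutting) and per-output peak scales in Nm/kg. Shapes are
#' normalized to unit peak, so `peak_scale` sets the task's reference peak
#' moment.
#'
#' @param task one of [kneeload_tasks()].
#' @return an object of class `task_template` with elements `kfm_bumps`,
#'   `kam_bumps` (data frames `amp`/`center`/`width` on the 0-1 stance axis),
#'   `stance_duration_s`, `grf_profile`, `peak_scale` (named: kfm, kam), and
#'   shape evaluators `kfm_shape(p)`, `kam_shape(p)`.
#' @export
#' @examples
#' tpl <- template_for("walking straight")
#' tpl$peak_scale["kfm"]
#' tpl$kfm_shape(c(0, 0.3, 1))
template_for <- function(task) {
  tab <- task_template_table()
  if (!is.character(task) || length(task) != 1L || !task %in% names(tab)) {
    stop_kneeload("unknown task label: ", task, class = "kneeload_task_error")
  }
  tpl <- tab[[task]]
  tpl$task <- task
  tpl$kfm_bumps <- normalize_bumps(tpl$kfm_bumps)
  tpl$kam_bumps <- normalize_bumps(tpl$kam_bumps)
  kfm_b <- tpl$kfm_bumps
  kam_b <- tpl$kam_bumps
  tpl$kfm_shape <- function(p) eval_bumps(p, kfm_b)
  tpl$kam_shape <- function(p) eval_bumps(p, kam_b)
  structure(tpl, class = "task_template")
}

# Analytic derivative of the bump basis w.r.t. stance fraction p.
eval_bumps_deriv <- function(p, bumps) {
  out <- numeric(length(p))
  for (i in seq_len(nrow(bumps))) {
    z <- (p - bumps$center[i]) / bumps$width[i]
    out <- out - bumps$amp[i] * z / bumps$width[i] * exp(-z^2 / 2)
  }
  out
}

# Vertical GRF stance profile in units of body weight, p in [0, 1].
grf_shape <- function(p, profile) {
  envelope <- sin(pi * pmin(pmax(p, 0), 1))^0.2
  core <- if (profile == "double_hump") {
    1.10 * exp(-((p - 0.22) / 0.10)^2 / 2) +
      1.05 * exp(-((p - 0.78) / 0.10)^2 / 2) +
      0.65 * exp(-((p - 0.50) / 0.22)^2 / 2)
  } else {
    2.30 * exp(-((p - 0.45) / 0.16)^2 / 2) +
      0.30 * exp(-((p - 0.12) / 0.05)^2 / 2)
  }
  envelope * core
}

# Fixed 12x6 mixing matrix from moment-space features to IMU channels:
# columns (kfm, kam, dkfm/dp, dkam/dp, harmonic1, harmonic2), rows the 12
# channels (thigh ax..gz, shank ax..gz). Constant across tasks and cohorts;
# generated once from a hard-wired seed and scaled so moment terms dominate.
imu_mixing_matrix <- function() {
  A <- with_seed(902001L, matrix(rnorm(12 * 6), nrow = 12, ncol = 6))
  # column scales: moments strong, derivatives damped (they are ~5-10x larger
  # in raw magnitude), harmonics moderate
  A <- sweep(A, 2, c(1.5, 1.5, 0.22, 0.22, 0.8, 0.8), "*")
  rownames(A) <- imu_channel_names()
  colnames(A) <- c("kfm", "kam", "dkfm", "dkam", "h1", "h2")
  A
}

imu_channel_names <- function() {
  paste0(
    rep(c("thigh_", "shank_"), each = 6),
    rep(c("ax", "ay", "az", "gx", "gy", "gz"), times = 2)
  )
}

# duration of low-amplitude swing padding before and after stance, seconds
PAD_SECONDS <- 0.3
GRAVITY <- 9.80665

# Generate one trial plus its ground-truth bookkeeping.
generate_trial <- function(config, template, participant, trial_index, trial_seed) {
  with_seed(trial_seed, {
    jitter_sd <- config$participant_gain_sd / 3
    amp_jitter <- 1 + jitter_sd * rnorm(1)
    dur_jitter <- 1 + jitter_sd * rnorm(1)
    dur_jitter <- min(max(dur_jitter, 0.7), 1.3)

    stance_s <- template$stance_duration_s * dur_jitter
    L <- max(round(stance_s * config$grf_rate), 50L)
    pad <- round(PAD_SECONDS * config$grf_rate)
    T_grf <- L + 2L * pad
    T_imu <- round(T_grf / config$grf_rate * config$imu_rate)

    gain <- participant$gain * amp_jitter
    peak <- template$peak_scale

    # latent normalized moment curves on the canonical 100-step grid (Nm/kg)
    p100 <- seq(0, 1, length.out = 100)
    clean_moments <- cbind(
      kfm = peak[["kfm"]] * gain * template$kfm_shape(p100),
      kam = peak[["kam"]] * gain * template$kam_shape(p100)
    )

    # reference moments on the GRF time base (Nm, un-normalized)
    pL <- seq(0, 1, length.out = L)
    kfm_L <- peak[["kfm"]] * gain * template$kfm_shape(pL)
    kam_L <- peak[["kam"]] * gain * template$kam_shape(pL)
    ref <- matrix(0, nrow = T_grf, ncol = 2, dimnames = list(NULL, c("kfm", "kam")))
    idx <- pad + seq_len(L)
    ref[idx, "kfm"] <- kfm_L * participant$mass
    ref[idx, "kam"] <- kam_L * participant$mass
    if (config$noise_sd > 0) {
      # small measurement noise on the reference series, well below signal scale
      ref_sd <- 0.25 * config$noise_sd * participant$mass *
        c(peak[["kfm"]], peak[["kam"]])
      ref[, "kfm"] <- ref[, "kfm"] + rnorm(T_grf, sd = ref_sd[1])
      ref[, "kam"] <- ref[, "kam"] + rnorm(T_grf, sd = ref_sd[2])
    }

    # vertical GRF: stance profile scaled by body weight, padded with
    # sub-threshold noise; samples inside the stance window are floored at
    # 22 N so the 20 N detector recovers the recorded window exactly
    vgrf <- numeric(T_grf)
    p_grf <- (seq_len(L) - 0.5) / L
    vgrf[idx] <- pmax(participant$mass * GRAVITY * grf_shape(p_grf, template$grf_profile), 22)
    if (config$noise_sd > 0) {
      vgrf[-idx] <- abs(rnorm(T_grf - L, sd = 2)) # swing noise, < 20 N
      vgrf[idx] <- pmax(vgrf[idx] + rnorm(L, sd = config$noise_sd * participant$mass * GRAVITY), 22)
    }

    # IMU channels: fixed mixture of moment features at the IMU time base
    t_imu <- (seq_len(T_imu) - 1) / config$imu_rate
    p_imu <- (t_imu - pad / config$grf_rate) / (L / config$grf_rate)
    inside <- p_imu >= 0 & p_imu <= 1
    feat <- matrix(0, nrow = T_imu, ncol = 6)
    feat[inside, 1] <- peak[["kfm"]] * gain * template$kfm_shape(p_imu[inside])
    feat[inside, 2] <- peak[["kam"]] * gain * template$kam_shape(p_imu[inside])
    feat[inside, 3] <- peak[["kfm"]] * gain * eval_bumps_deriv(p_imu[inside], template$kfm_bumps)
    feat[inside, 4] <- peak[["kam"]] * gain * eval_bumps_deriv(p_imu[inside], template$kam_bumps)
    feat[inside, 5] <- sin(2 * pi * p_imu[inside])
    feat[inside, 6] <- sin(4 * pi * p_imu[inside])
    imu <- feat %*% t(participant$mixing)
    colnames(imu) <- imu_channel_names()
    if (config$noise_sd > 0) {
      scale_j <- apply(abs(imu), 2, max)
      noise <- matrix(rnorm(T_imu * 12), nrow = T_imu)
      imu <- imu + sweep(noise, 2, config$noise_sd * scale_j, "*")
    }

    trial <- structure(
      list(
        participant_id = participant$id,
        task = template$task,
        trial_index = as.integer(trial_index),
        body_mass_kg = participant$mass,
        imu_rate = config$imu_rate,
        grf_rate = config$grf_rate,
        imu = imu,
        vgrf = vgrf,
        ref_moments = ref
      ),
      class = "raw_trial"
    )
    truth <- structure(
      list(
        stance_window = stance_window(pad + 1L, pad + L + 1L),
        participant_gain = gain,
        clean_moments = clean_moments
      ),
      class = "ground_truth"
    )
    list(trial = trial, truth = truth)
  })
}

#' Generate a seeded synthetic gait cohort
#'
#' Simulates `n_participants x length(tasks) x trials_per_task` trials. Each
#' participant draws a body mass (uniform 70-90 kg), a scalar moment
#' amplitude gain and a perturbed copy of the fixed IMU mixing matrix (both
#' controlled by `participant_gain_sd`). Each trial embeds a stance phase
#' (vertical GRF > 20 N inside the recorded window, < 20 N in the 0.3 s
#' swing padding on either side), reference KFM/KAM moment series on the GRF
#' time base, and 12 IMU channels that are a fixed linear mixture of the
#' latent normalized moment curves, their stance-phase derivatives and two
#' gait harmonics, plus Gaussian sensor noise.
#'
#' The same configuration (including seed) reproduces the cohort
#' bit-identically; sub-seeds are derived per participant and trial with
#' [derive_seed()], so reproducibility does not depend on generation order.
#'
#' @param config a [cohort_config()].
#' @return a list of `n x tasks x trials` elements, each a list with `trial`
#'   (class `raw_trial`) and `truth` (class `ground_truth`: recorded stance
#'   window, participant gain, noiseless 100 x 2 normalized moment block).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_participants = 2,
#'   tasks = "walking straight", seed = 7
#' ))
#' length(cohort) # 2 participants x 1 task x 3 trials
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  A <- imu_mixing_matrix()
  out <- vector("list", config$n_participants * length(config$tasks) * config$trials_per_task)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    participant <- with_seed(derive_seed(config$seed, p, 0L, 0L), {
      gain <- 1 + config$participant_gain_sd * rnorm(1)
      gain <- max(gain, 0.3)
      perturb <- 1 + config$participant_gain_sd * matrix(rnorm(12 * 6), nrow = 12)
      list(
        id = sprintf("P%02d", p),
        mass = runif(1, 70, 90),
        gain = gain,
        mixing = A * perturb
      )
    })
    for (ti in seq_along(config$tasks)) {
      template <- template_for(config$tasks[ti])
      for (tr in seq_len(config$trials_per_task)) {
        k <- k + 1L
        out[[k]] <- generate_trial(
          config, template, participant, tr,
          derive_seed(config$seed, p, ti, tr)
        )
      }
    }
  }
  out
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(
    sprintf(
      "<raw_trial> %s / %s / trial %d: %d IMU samples @ %g Hz, %d GRF samples @ %g Hz, mass %.1f kg\n",
      x$participant_id, x$task, x$trial_index, nrow(x$imu), x$imu_rate,
      length(x$vgrf), x$grf_rate, x$body_mass_kg
    )
  )
  invisible(x)
}
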