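# Shared fixtures, built in code at test time.

# small noise-free cohort configuration for exactness checks
clean_config <- function(n = 3, tasks = kneeload_tasks(), trials = 1, seed = 5) {
  cohort_config(
    n_participants = n, trials_per_task = trials, tasks = tasks,
    participant_gain_sd = 0, noise_sd = 0, seed = seed
  )
}

# a synthetic normalized trial without running the preprocessing pipeline
fake_normalized_trial <- function(participant, task = "walking straight",
                                  trial_index = 1, n_steps = 100, seed = 1) {
  set.seed(seed)
  inputs <- matrix(rnorm(n_steps * 12), ncol = 12, dimnames = list(NULL, NULL))
  targets <- matrix(rnorm(n_steps * 2), ncol = 2, dimnames = list(NULL, c("kfm", "kam")))
  structure(
    list(
      inputs = inputs, targets = targets, participant_id = participant,
      task = task, trial_index = trial_index
    ),
    class = "normalized_trial"
  )
}

# fold results in which the estimate is an exact or perturbed copy of the
# reference, for metric-aggregation tests
fake_fold_results <- function(participants = c("P01", "P02"),
                              tasks = c("walking straight", "fast running"),
                              trials = 2, distort = function(ref) ref,
                              seed = 42) {
  set.seed(seed)
  lapply(participants, function(p) {
    fold_trials <- list()
    for (tk in tasks) {
      for (tr in seq_len(trials)) {
        p100 <- seq(0, 1, length.out = 100)
        ref <- cbind(
          kfm = sin(pi * p100) + 0.1 * rnorm(1),
          kam = 0.5 * sin(pi * p100)^2 + 0.1 * rnorm(1) + 0.05
        )
        fold_trials[[length(fold_trials) + 1L]] <-
          list(task = tk, trial_index = tr, ref = ref, est = distort(ref))
      }
    }
    list(participant = p, trials = fold_trials)
  })
}

# amplitude of a sinusoid at frequency f (Hz) in signal y sampled at `rate`,
# by projection onto quadrature carriers over an integer number of periods
sine_amplitude <- function(y, f, rate) {
  n <- length(y)
  t <- (seq_len(n) - 1) / rate
  periods <- floor(f * n / rate)
  keep <- t < periods / f
  t <- t[keep]
  y <- y[keep]
  2 * sqrt(mean(y * sin(2 * pi * f * t))^2 + mean(y * cos(2 * pi * f * t))^2)
}

# analytic squared magnitude of the zero-phase (forward-backward) digital
# Butterworth low-pass: bilinear-transform prewarped frequency axis
butter2_gain <- function(f, rate, cutoff = 15, order = 4) {
  ratio <- tan(pi * f / rate) / tan(pi * cutoff / rate)
  1 / (1 + ratio^(2 * order))
}

# central finite-difference Jacobian of the scaled forward pass
fd_jacobian <- function(params, Xs, h = 1e-6) {
  theta <- kneeload:::pack_params(params)
  n_out <- params$layer_sizes[length(params$layer_sizes)]
  J <- matrix(0, nrow(Xs) * n_out, length(theta))
  for (k in seq_along(theta)) {
    tp <- theta
    tp[k] <- tp[k] + h
    tm <- theta
    tm[k] <- tm[k] - h
    yp <- kneeload:::forward_scaled(kneeload:::unpack_params(tp, params$layer_sizes), Xs)
    ym <- kneeload:::forward_scaled(kneeload:::unpack_params(tm, params$layer_sizes), Xs)
    J[, k] <- as.vector((yp - ym) / (2 * h))
  }
  J
}
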