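test_that("zero-phase filter preserves DC and commutes with scaling", {
  x <- rep(3.5, 500)
  expect_lt(max(abs(lowpass_zero_phase(x, rate = 1000) - 3.5)), 1e-9)
  set.seed(1)
  y <- cumsum(rnorm(800))
  expect_lt(
    max(abs(
      lowpass_zero_phase(5 * y, rate = 1000) - 5 * lowpass_zero_phase(y, rate = 1000)
    )),
    1e-9
  )
})

test_that("zero-phase filter matches the analytic squared Butterworth response", {
  rate <- 1000
  t <- (0:3999) / rate
  for (f in c(2, 10, 30, 100)) {
    y <- lowpass_zero_phase(sin(2 * pi * f * t), rate = rate)
    mid <- 500:3500
    amp <- sine_amplitude(y[mid], f, rate)
    expect_equal(amp, butter2_gain(f, rate), tolerance = 1e-3)
  }
  # passband sinusoid comes through with zero phase: peak cross-correlation at lag 0
  s <- sin(2 * pi * 2 * t)
  y <- lowpass_zero_phase(s, rate = rate)
  cc <- stats::ccf(y, s, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stopband content is annihilated
  y100 <- lowpass_zero_phase(sin(2 * pi * 100 * t), rate = rate)
  expect_lt(max(abs(y100[500:3500])), 0.001)
})

test_that("filter rejects unusable inputs", {
  expect_error(lowpass_zero_phase(rnorm(10), rate = 1000), class = "kneeload_filter_error")
  expect_error(lowpass_zero_phase(rnorm(100), rate = 20, cutoff = 15),
    class = "kneeload_filter_error"
  )
})

test_that("stance detection finds the longest supra-threshold run", {
  vgrf <- numeric(500)
  vgrf[101:300] <- 25 # 1-based [101, 301)
  w <- detect_stance(vgrf)
  expect_equal(c(w$start, w$end), c(101, 301))
  # a shorter, stronger burst elsewhere does not win
  vgrf[450:470] <- 800
  w2 <- detect_stance(vgrf)
  expect_equal(c(w2$start, w2$end), c(101, 301))
  expect_error(detect_stance(numeric(0)), class = "kneeload_stance_error")
  expect_error(detect_stance(rep(0, 100)), class = "kneeload_stance_error")
})

test_that("cropping maps the stance window across sampling rates", {
  trial <- list(
    imu = matrix(seq_len(600 * 12), ncol = 12), vgrf = rnorm(400),
    ref_moments = matrix(rnorm(800), ncol = 2), imu_rate = 1500, grf_rate = 1000
  )
  # GRF window [100, 300) 0-based = [101, 301) 1-based; ratio 1.5 -> IMU [150, 450) 0-based
  out <- crop_to_stance(trial, stance_window(101, 301))
  expect_equal(nrow(out$imu), 300)
  expect_equal(out$imu[1, 1], trial$imu[151, 1])
  expect_equal(out$imu[300, 1], trial$imu[450, 1])
  expect_length(out$vgrf, 200)
  # identity window returns full streams
  full <- crop_to_stance(trial, stance_window(1, 401))
  expect_equal(dim(full$imu), dim(trial$imu))
  expect_error(crop_to_stance(trial, stance_window(390, 460)),
    class = "kneeload_stance_error"
  )
})

test_that("cropped IMU and GRF durations agree within one IMU sample", {
  cohort <- generate_cohort(cohort_config(n_participants = 2, seed = 9))
  for (x in cohort[seq(1, length(cohort), by = 7)]) {
    t <- x$trial
    w <- detect_stance(t$vgrf)
    out <- crop_to_stance(t, w)
    expect_lt(
      abs(nrow(out$imu) / t$imu_rate - length(out$vgrf) / t$grf_rate),
      1 / t$imu_rate + 1e-12
    )
  }
})

test_that("time normalization interpolates linearly onto the stance-percent grid", {
  expect_equal(time_normalize(rep(2.5, 37)), rep(2.5, 100))
  ramp <- time_normalize(seq(0, 1, length.out = 500))
  expect_equal(ramp, seq(0, 1, length.out = 100), tolerance = 1e-12)
  # one sine period over 1000 samples: < 1e-4 from the analytic values
  s <- sin(2 * pi * seq(0, 1, length.out = 1000))
  out <- time_normalize(s)
  expect_lt(max(abs(out - sin(2 * pi * seq(0, 1, length.out = 100)))), 1e-4)
  # endpoints are preserved exactly
  m <- cbind(a = rnorm(57), b = rnorm(57))
  tn <- time_normalize(m)
  expect_equal(tn[c(1, 100), ], m[c(1, 57), ])
  # idempotence on an already-100-step series
  expect_equal(time_normalize(tn), tn, tolerance = 1e-12)
  expect_error(time_normalize(matrix(1, 1, 2)), class = "kneeload_preprocess_error")
})

test_that("moment normalization divides by body mass", {
  expect_equal(normalize_moments(160, 80), 2.0)
  expect_equal(normalize_moments(matrix(0, 5, 2), 70), matrix(0, 5, 2))
  expect_error(normalize_moments(1, 0), class = "kneeload_preprocess_error")
  expect_error(normalize_moments(1, -70), class = "kneeload_preprocess_error")
})

test_that("matrix assembly stacks trial blocks with a complete row index", {
  trials <- c(
    lapply(1:2, function(i) fake_normalized_trial("P01", trial_index = i, seed = i)),
    lapply(3:4, function(i) fake_normalized_trial("P02", trial_index = i, seed = i))
  )
  m <- assemble_matrices(trials, outputs = "both")
  expect_equal(dim(m$X), c(400, 12))
  expect_equal(dim(m$Y), c(400, 2))
  expect_equal(nrow(m$row_index), 400)
  expect_equal(m$row_index$step[101], 1)
  expect_equal(m$row_index$participant[201], "P02")

  kam <- assemble_matrices(trials[1], outputs = "kam")
  expect_equal(dim(kam$Y), c(100, 1))
  expect_equal(unname(kam$Y[, 1]), unname(trials[[1]]$targets[, "kam"]))

  # shuffling trials permutes blocks but keeps row content consistent
  perm <- assemble_matrices(trials[c(3, 1, 4, 2)], outputs = "both")
  key <- function(mm) {
    o <- order(mm$row_index$participant, mm$row_index$trial, mm$row_index$step)
    cbind(mm$X[o, ], mm$Y[o, ])
  }
  expect_equal(key(perm), key(m))

  expect_error(assemble_matrices(list()), class = "kneeload_preprocess_error")
  short <- fake_normalized_trial("P03", n_steps = 50)
  expect_error(
    assemble_matrices(list(trials[[1]], short)),
    class = "kneeload_preprocess_error"
  )
})

test_that("full-size assembly matches the reference dataset dimensions", {
  # 234 trials x 100 steps: the matrix layout of the full protocol
  trials <- lapply(seq_len(234), function(i) {
    fake_normalized_trial(sprintf("P%02d", (i - 1) %/% 18 + 1), trial_index = i, seed = i)
  })
  m <- assemble_matrices(trials, outputs = "both")
  expect_equal(dim(m$X), c(23400, 12))
  expect_equal(dim(m$Y), c(23400, 2))
})
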