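test_that("LOSO folds partition the participants", {
  folds <- loso_folds(sprintf("P%02d", 1:13))
  expect_length(folds, 13)
  for (f in folds) {
    expect_length(f$train, 12)
    expect_false(f$test %in% f$train)
  }
  expect_setequal(vapply(folds, `[[`, "", "test"), sprintf("P%02d", 1:13))
  expect_length(loso_folds(c("a", "b")), 2)
  expect_error(loso_folds("a"), class = "kneeload_config_error")
})

test_that("pearson_r matches the product-moment formula", {
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 5)
  # independent oracle: direct evaluation of the sum formula
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), r_direct, tolerance = 1e-14)
  expect_equal(pearson_r(a, a), 1.0)
  expect_equal(pearson_r(a, -a), -1.0)
  expect_warning(expect_true(is.na(pearson_r(a, rep(1, 4)))), "constant")
  expect_error(pearson_r(1:3, 1:4), class = "kneeload_metric_error")
})

test_that("fisher_mean pools correlations on the z scale", {
  expect_equal(fisher_mean(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-14)
  expect_equal(fisher_mean(c(0, 0)), 0)
  expect_equal(fisher_mean(c(0.3, 0.7)),
    tanh((atanh(0.3) + atanh(0.7)) / 2),
    tolerance = 1e-14
  )
  # bounded between min and max of the inputs
  set.seed(8)
  for (i in 1:25) {
    r <- runif(5, -0.95, 0.95)
    fm <- fisher_mean(r)
    expect_gte(fm, min(r))
    expect_lte(fm, max(r))
  }
  expect_warning(fm1 <- fisher_mean(c(1, 0.5)), "clamped")
  expect_true(fm1 < 1 && fm1 > 0.5)
  expect_error(fisher_mean(1.2), class = "kneeload_metric_error")
})

test_that("rmse and rrmse follow their definitions and invariances", {
  a <- c(0, 1)
  b <- c(0, 2)
  expect_equal(rmse(a, b), sqrt(0.5), tolerance = 1e-14)
  expect_equal(rrmse(a, b), 100 * sqrt(0.5) / 1.5, tolerance = 1e-14)
  expect_equal(rmse(a, a), 0)
  expect_equal(rrmse(a, a), 0)
  # common positive rescaling: rmse scales, rrmse invariant
  set.seed(9)
  x <- rnorm(100)
  y <- x + rnorm(100, sd = 0.3)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)
  expect_equal(rrmse(3 * x, 3 * y), rrmse(x, y), tolerance = 1e-12)
  expect_equal(rrmse(x + 5, y + 5), rrmse(x, y), tolerance = 1e-12)
  expect_warning(expect_true(is.na(rrmse(rep(1, 5), rep(1, 5)))), "zero range")
})

test_that("peak and impulse compute the discrete load metrics", {
  expect_equal(series_peak(rep(1, 100)), 1.0)
  expect_equal(series_impulse(rep(1, 100)), 99.0)
  expect_equal(series_impulse(rep(0, 100)), 0)
  expect_equal(series_peak(rep(0, 100)), 0)
  # symmetric triangle peaking at 2.0: piecewise-linear area 49 + 2 + 49
  tri <- c(seq(0, 2, length.out = 50), seq(2, 0, length.out = 50))
  expect_equal(series_peak(tri), 2.0)
  expect_equal(series_impulse(tri), 100, tolerance = 1e-12)
})

test_that("percent differences are signed and guard the zero reference", {
  expect_equal(percent_diff(1.1, 1.0), 10.0, tolerance = 1e-12)
  expect_equal(percent_diff(0.9, 1.0), -10.0, tolerance = 1e-12)
  expect_equal(percent_diff(2.5, 2.5), 0)
  expect_warning(expect_true(is.na(percent_diff(1, 0))), "zero reference")
})

test_that("correlation bands use the closed/open boundaries", {
  expect_equal(categorize_r(0.35), "weak")
  expect_equal(categorize_r(0.36), "moderate")
  expect_equal(categorize_r(0.67), "moderate")
  expect_equal(categorize_r(0.68), "strong")
  expect_equal(categorize_r(0.90), "strong")
  expect_equal(categorize_r(0.91), "excellent")
  expect_equal(categorize_r(-0.5), "weak")
  expect_equal(categorize_r(c(0.2, NA, 0.95)), c("weak", NA, "excellent"))
})

test_that("perfect estimates give perfect aggregate metrics", {
  folds <- fake_fold_results(distort = function(ref) ref)
  ev <- suppressWarnings(evaluate_folds(folds)) # exact estimates: r = 1 clamps in Fisher pooling
  tm <- ev$task_metrics
  expect_true(all(tm$r_mean > 1 - 1e-9))
  expect_true(all(tm$rmse_mean < 1e-12))
  expect_true(all(tm$rrmse_mean < 1e-9))
  expect_true(all(tm$r_band == "excellent"))
  dm <- ev$discrete_metrics
  expect_true(all(abs(dm$pdiff_mean) < 1e-9))
  expect_equal(dm$est_mean, dm$ref_mean, tolerance = 1e-12)
})

test_that("aggregation pools per fold with sample sds and arithmetic Mean rows", {
  # two folds whose scalar rmse differ: means and sample sds across folds
  folds <- fake_fold_results(
    participants = c("P01", "P02"), tasks = "walking straight",
    trials = 1, distort = function(ref) ref
  )
  folds[[1]]$trials[[1]]$est <- folds[[1]]$trials[[1]]$ref + 1 # rmse 1, both outputs
  folds[[2]]$trials[[1]]$est <- folds[[2]]$trials[[1]]$ref + 3 # rmse 3
  ev <- suppressWarnings(evaluate_folds(folds)) # offset-only estimates: r undefined-safe
  tm <- ev$task_metrics
  row <- tm[tm$task == "walking straight" & tm$output == "kfm", ]
  expect_equal(row$rmse_mean, 2)
  expect_equal(row$rmse_sd, sqrt(2), tolerance = 1e-12) # sample sd of (1, 3)
})

test_that("cross-task Mean rows reproduce published arithmetic means", {
  # per-task r values of the reference KFM results
  tbl <- data.frame(
    task = kneeload_tasks(), output = "kfm",
    r_mean = c(0.72, 0.69, 0.85, 0.65, 0.79, 0.73)
  )
  out <- cross_task_mean(tbl)
  expect_equal(out$r_mean[out$task == "Mean"], mean(tbl$r_mean))
  expect_equal(round(out$r_mean[out$task == "Mean"], 2), 0.74)
})

test_that("aggregation is invariant to fold and trial order", {
  set.seed(10)
  folds <- fake_fold_results(
    participants = c("P01", "P02", "P03"),
    distort = function(ref) ref + matrix(rnorm(length(ref), sd = 0.1), nrow(ref))
  )
  ev1 <- evaluate_folds(folds)
  shuffled <- rev(folds)
  shuffled[[1]]$trials <- rev(shuffled[[1]]$trials)
  ev2 <- evaluate_folds(shuffled)
  expect_equal(ev1$task_metrics, ev2$task_metrics, tolerance = 1e-12)
  expect_equal(ev1$discrete_metrics, ev2$discrete_metrics, tolerance = 1e-12)
})

test_that("pooling modes and absolute percent differences are available", {
  set.seed(11)
  folds <- fake_fold_results(
    distort = function(ref) ref * 0.8
  )
  # est = 0.8 * ref correlates perfectly, so Fisher pooling clamps r = 1
  ev_trial <- suppressWarnings(evaluate_folds(folds, pooling = "trial"))
  ev_fold <- suppressWarnings(evaluate_folds(folds, pooling = "fold"))
  expect_equal(names(ev_trial$task_metrics), names(ev_fold$task_metrics))
  ev_abs <- suppressWarnings(evaluate_folds(folds, signed_pdiff = FALSE))
  expect_true(all(ev_abs$discrete_metrics$pdiff_mean >= 0))
  # 20% shrink of a positive-peak series: signed peak %Diff is -20
  peak_rows <- ev_trial$discrete_metrics$metric == "peak" &
    ev_trial$discrete_metrics$task != "Mean"
  expect_equal(ev_trial$discrete_metrics$pdiff_mean[peak_rows],
    rep(-20, sum(peak_rows)),
    tolerance = 1e-9
  )
})

test_that("model comparison differences and self-comparison identity", {
  set.seed(12)
  folds <- fake_fold_results(
    distort = function(ref) ref + matrix(rnorm(length(ref), sd = 0.05), nrow(ref))
  )
  tm <- evaluate_folds(folds)$task_metrics
  self <- compare_models(tm, tm)
  expect_true(all(abs(self$delta_r) == 0))
  expect_true(all(abs(self$delta_rmse) == 0))
  expect_true(all(abs(self$delta_rrmse) == 0))
  # Mean row = arithmetic mean of task deltas (published KFM RMSE deltas)
  cmp <- data.frame(
    task = kneeload_tasks(), output = "kfm",
    r_mean = 0.5, rmse_mean = 0.5, rrmse_mean = 10
  )
  ind <- cmp
  ind$rmse_mean <- cmp$rmse_mean + c(0.00, 0.03, 0.18, 0.15, 0.11, 0.44)
  out <- compare_models(cmp, ind)
  expect_equal(out$delta_rmse[out$task == "Mean"],
    mean(c(0.00, 0.03, 0.18, 0.15, 0.11, 0.44)),
    tolerance = 1e-12
  )
  expect_equal(round(out$delta_rmse[out$task == "Mean"], 2), 0.15)
  # single-task tables: Mean equals the task delta
  one <- compare_models(cmp[1, ], ind[1, ])
  expect_equal(one$delta_rmse[one$task == "Mean"], one$delta_rmse[1])
  expect_error(compare_models(cmp, ind[-1, ]), class = "kneeload_metric_error")
})
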