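# Agreement metrics and the leave-one-subject-out evaluation harness.

#' Leave-one-subject-out fold structure
#'
#' One fold per participant: the fold's test set is that participant, the
#' training set all others. Union of test ids equals the input ids.
#'
#' @param participant_ids character or integer vector of unique ids (>= 2).
#' @return list of folds, each `list(train = ids, test = id)`.
#' @export
loso_folds <- function(participant_ids) {
  ids <- unique(participant_ids)
  if (length(ids) < 2) {
    stop_kneeload("leave-one-subject-out needs at least 2 participants",
      class = "kneeload_config_error"
    )
  }
  lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
}

#' Pearson product-moment correlation
#'
#' @param a,b equal-length numeric series (length >= 2) with non-zero
#'   variance.
#' @return correlation in `[-1, 1]`; `NA` with a warning if either series is
#'   constant.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_kneeload("series must have equal length >= 2", class = "kneeload_metric_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined for a constant series", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Fisher-z pooled mean of correlation coefficients
#'
#' Correlations are averaged on the z scale (`atanh`) and the mean is mapped
#' back with `tanh`, the standard way to pool correlations without the bias
#' of a direct arithmetic mean. Values at exactly +/-1 (infinite z) are
#' clamped to `1 - 1e-12` in magnitude with a warning. `NA` inputs are
#' dropped.
#'
#' @param r_values numeric vector of correlations.
#' @return pooled correlation in `(-1, 1)`.
#' @export
fisher_mean <- function(r_values) {
  r_values <- r_values[!is.na(r_values)]
  if (length(r_values) == 0) {
    return(NA_real_)
  }
  if (any(abs(r_values) > 1)) {
    stop_kneeload("correlations must lie in [-1, 1]", class = "kneeload_metric_error")
  }
  if (any(abs(r_values) >= 1)) {
    warning("correlation(s) at +/-1 clamped before Fisher transform", call. = FALSE)
    r_values <- sign(r_values) * pmin(abs(r_values), 1 - 1e-12)
  }
  tanh(mean(atanh(r_values)))
}

#' Root-mean-squared error and relative RMSE
#'
#' `rmse` is the usual root of the mean squared difference. `rrmse`
#' normalizes it by the mean of the two series' peak-to-peak ranges and
#' reports a percentage, which makes tasks with different moment amplitudes
#' comparable; it is invariant to a common positive rescaling or a common
#' offset of both series.
#'
#' @param a,b equal-length numeric series (length >= 2); conventionally `a`
#'   is the reference and `b` the estimate.
#' @return `rmse`: error in the series' units (Nm/kg for moments);
#'   `rrmse`: percentage, `NA` with a warning when both ranges are zero.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_kneeload("series must have equal length >= 2", class = "kneeload_metric_error")
  }
  sqrt(mean((a - b)^2))
}

#' @rdname rmse
#' @export
rrmse <- function(a, b) {
  denom <- ((max(a) - min(a)) + (max(b) - min(b))) / 2
  if (denom == 0) {
    warning("relative RMSE undefined: both series have zero range", call. = FALSE)
    return(NA_real_)
  }
  100 * rmse(a, b) / denom
}

#' Discrete knee-load metrics: peak and impulse
#'
#' `series_peak` is the maximum of the stance-phase moment series.
#' `series_impulse` is the trapezoidal integral over the stance-percent
#' axis with unit step 1% of stance (so a constant series of 1.0 over 100
#' steps has impulse 99): the area under the moment-stance curve, the
#' standard cumulative-load metric. Units: Nm/kg for the peak,
#' Nm.%stance/kg for the impulse.
#'
#' @param series numeric stance-phase series (typically 100 steps, Nm/kg).
#' @return scalar metric.
#' @export
series_peak <- function(series) max(series)

#' @rdname series_peak
#' @export
series_impulse <- function(series) {
  n <- length(series)
  if (n < 2) {
    stop_kneeload("impulse needs at least 2 samples", class = "kneeload_metric_error")
  }
  sum((series[-1] + series[-n]) / 2)
}

#' Signed percent difference between an estimated and a reference metric
#'
#' @param estimated,reference scalar metrics; `reference` must be non-zero.
#' @return `100 * (estimated - reference) / reference`; `NA` with a warning
#'   for a zero reference.
#' @export
percent_diff <- function(estimated, reference) {
  out <- 100 * (estimated - reference) / reference
  zero <- reference == 0
  if (any(zero)) {
    warning("percent difference undefined for zero reference; returning NA", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Categorize a correlation coefficient into agreement bands
#'
#' Conventional interpretation bands for agreement studies:
#' weak (`r <= 0.35`), moderate (`0.35 < r <= 0.67`), strong
#' (`0.67 < r <= 0.90`), excellent (`r > 0.90`).
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return character vector of band labels (`NA` stays `NA`).
#' @export
categorize_r <- function(r) {
  out <- rep(NA_character_, length(r))
  ok <- !is.na(r)
  out[ok & r <= 0.35] <- "weak"
  out[ok & r > 0.35 & r <= 0.67] <- "moderate"
  out[ok & r > 0.67 & r <= 0.90] <- "strong"
  out[ok & r > 0.90] <- "excellent"
  out
}

#' Append the cross-task Mean row to a per-task metrics table
#'
#' The Mean row is the arithmetic columnwise mean of the per-task rows
#' (computed separately per output and metric where those columns exist).
#'
#' @param table data frame with a `task` column and numeric metric columns;
#'   may contain an `output` (and `metric`) grouping column.
#' @return the table with one `"Mean"` row appended per group.
#' @export
cross_task_mean <- function(table) {
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  group_cols <- intersect(c("output", "metric"), names(table))
  groups <- if (length(group_cols)) {
    split(table, table[group_cols], drop = TRUE)
  } else {
    list(table)
  }
  mean_rows <- lapply(groups, function(g) {
    row <- g[1, , drop = FALSE]
    row$task <- "Mean"
    for (cc in num_cols) row[[cc]] <- mean(g[[cc]], na.rm = TRUE)
    row
  })
  out <- rbind(table, do.call(rbind, mean_rows))
  rownames(out) <- NULL
  out
}

# per-trial metric records from a list of fold results
fold_trial_records <- function(fold_results) {
  rows <- list()
  for (fr in fold_results) {
    for (tr in fr$trials) {
      for (out in colnames(tr$ref)) {
        ref <- tr$ref[, out]
        est <- tr$est[, out]
        rows[[length(rows) + 1L]] <- data.frame(
          participant = fr$participant, task = tr$task, trial = tr$trial_index,
          output = out,
          r = suppressWarnings(pearson_r(ref, est)),
          rmse = rmse(ref, est),
          rrmse = suppressWarnings(rrmse(ref, est)),
          ref_peak = series_peak(ref), est_peak = series_peak(est),
          ref_impulse = series_impulse(ref), est_impulse = series_impulse(est),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate fold results into the per-task metrics tables
#'
#' Computes, per held-out trial and output, the continuous agreement metrics
#' (Pearson r over the 100-step series, RMSE, relative RMSE) and the
#' discrete load metrics (peak, impulse, signed percent difference). Within
#' each fold and task, r values are pooled across trials with the Fisher-z
#' mean and the other metrics with the arithmetic mean; across folds, r is
#' again Fisher-pooled (the reported spread is the sample sd of the
#' fold-level r values) and everything else is mean +/- sample sd over the
#' folds. With `pooling = "fold"`, r/RMSE/rRMSE are instead computed on the
#' concatenated trials of each fold and task. Each task's pooled r is
#' labelled with its [categorize_r()] band, and cross-task `"Mean"` rows
#' (arithmetic columnwise means) are appended.
#'
#' @param fold_results list of fold results as produced by [run_loso()]:
#'   each `list(participant, trials = list(list(task, trial_index, est,
#'   ref)))` with `est`/`ref` 100 x C matrices.
#' @param signed_pdiff if `FALSE`, percent differences are aggregated as
#'   absolute values.
#' @param pooling `"trial"` (per-trial metrics, then pooled; default) or
#'   `"fold"` (metrics on concatenated series per fold and task).
#' @return list with `task_metrics` (per task/output: r, RMSE, rRMSE,
#'   mean +/- sd, band), `discrete_metrics` (per task/output/metric:
#'   reference and estimated values and percent difference, mean +/- sd),
#'   and `trial_records` (the raw per-trial table).
#' @export
evaluate_folds <- function(fold_results, signed_pdiff = TRUE,
                           pooling = c("trial", "fold")) {
  pooling <- match.arg(pooling)
  if (length(fold_results) == 0) {
    stop_kneeload("no fold results to evaluate", class = "kneeload_metric_error")
  }
  rec <- fold_trial_records(fold_results)

  all_tasks <- unique(rec$task)
  n_folds <- length(unique(rec$participant))

  # --- continuous metrics: fold x task x output level ---
  if (pooling == "trial") {
    fold_level <- do.call(rbind, lapply(
      split(rec, list(rec$participant, rec$task, rec$output), drop = TRUE),
      function(g) {
        data.frame(
          participant = g$participant[1], task = g$task[1], output = g$output[1],
          r = fisher_mean(g$r), rmse = mean(g$rmse), rrmse = mean(g$rrmse, na.rm = TRUE),
          stringsAsFactors = FALSE
        )
      }
    ))
  } else {
    fold_level <- list()
    for (fr in fold_results) {
      tasks <- vapply(fr$trials, `[[`, "", "task")
      for (tk in unique(tasks)) {
        sel <- fr$trials[tasks == tk]
        for (out in colnames(sel[[1]]$ref)) {
          ref <- unlist(lapply(sel, function(t) t$ref[, out]))
          est <- unlist(lapply(sel, function(t) t$est[, out]))
          fold_level[[length(fold_level) + 1L]] <- data.frame(
            participant = fr$participant, task = tk, output = out,
            r = suppressWarnings(pearson_r(ref, est)),
            rmse = rmse(ref, est), rrmse = suppressWarnings(rrmse(ref, est)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    fold_level <- do.call(rbind, fold_level)
  }

  task_metrics <- do.call(rbind, lapply(
    split(fold_level, list(fold_level$task, fold_level$output), drop = TRUE),
    function(g) {
      if (nrow(g) < n_folds) {
        warning(
          "task '", g$task[1], "' (", g$output[1], ") present in only ",
          nrow(g), " of ", n_folds, " folds",
          call. = FALSE
        )
      }
      data.frame(
        task = g$task[1], output = g$output[1], n_folds = nrow(g),
        r_mean = fisher_mean(g$r), r_sd = sample_sd(g$r),
        rmse_mean = mean(g$rmse), rmse_sd = sample_sd(g$rmse),
        rrmse_mean = mean(g$rrmse, na.rm = TRUE), rrmse_sd = sample_sd(g$rrmse),
        stringsAsFactors = FALSE
      )
    }
  ))
  task_metrics <- task_metrics[order(
    match(task_metrics$output, c("kfm", "kam")),
    match(task_metrics$task, kneeload_tasks())
  ), ]
  task_metrics$r_band <- categorize_r(task_metrics$r_mean)
  task_metrics <- cross_task_mean(task_metrics)
  task_metrics$r_band[task_metrics$task == "Mean"] <-
    categorize_r(task_metrics$r_mean[task_metrics$task == "Mean"])

  # --- discrete load metrics ---
  long <- rbind(
    data.frame(rec[c("participant", "task", "trial", "output")],
      metric = "peak", ref = rec$ref_peak, est = rec$est_peak
    ),
    data.frame(rec[c("participant", "task", "trial", "output")],
      metric = "impulse", ref = rec$ref_impulse, est = rec$est_impulse
    )
  )
  long$pdiff <- suppressWarnings(percent_diff(long$est, long$ref))
  if (!signed_pdiff) long$pdiff <- abs(long$pdiff)
  disc_fold <- do.call(rbind, lapply(
    split(long, list(long$participant, long$task, long$output, long$metric), drop = TRUE),
    function(g) {
      data.frame(
        participant = g$participant[1], task = g$task[1], output = g$output[1],
        metric = g$metric[1], ref = mean(g$ref), est = mean(g$est),
        pdiff = mean(g$pdiff, na.rm = TRUE), stringsAsFactors = FALSE
      )
    }
  ))
  discrete_metrics <- do.call(rbind, lapply(
    split(disc_fold, list(disc_fold$task, disc_fold$output, disc_fold$metric), drop = TRUE),
    function(g) {
      data.frame(
        task = g$task[1], output = g$output[1], metric = g$metric[1],
        ref_mean = mean(g$ref), ref_sd = sample_sd(g$ref),
        est_mean = mean(g$est), est_sd = sample_sd(g$est),
        pdiff_mean = mean(g$pdiff, na.rm = TRUE), pdiff_sd = sample_sd(g$pdiff),
        stringsAsFactors = FALSE
      )
    }
  ))
  discrete_metrics <- discrete_metrics[order(
    match(discrete_metrics$output, c("kfm", "kam")),
    match(discrete_metrics$metric, c("peak", "impulse")),
    match(discrete_metrics$task, kneeload_tasks())
  ), ]
  discrete_metrics <- cross_task_mean(discrete_metrics)

  list(
    task_metrics = task_metrics, discrete_metrics = discrete_metrics,
    trial_records = rec
  )
}

#' Compare independent single-output models against the combined model
#'
#' Per task and output, the change in estimation accuracy due to independent
#' model building: `delta = independent - combined` for r, RMSE and rRMSE,
#' with a cross-task `"Mean"` row of arithmetic means. A positive RMSE/rRMSE
#' delta therefore means the independent model is less accurate.
#'
#' @param combined,independent `task_metrics` tables from [evaluate_folds()]
#'   covering identical tasks and outputs (the `"Mean"` rows are ignored and
#'   recomputed).
#' @return data frame with `task`, `output`, `delta_r`, `delta_rmse`,
#'   `delta_rrmse` plus `"Mean"` rows.
#' @export
compare_models <- function(combined, independent) {
  strip <- function(t) t[t$task != "Mean", c("task", "output", "r_mean", "rmse_mean", "rrmse_mean")]
  a <- strip(combined)
  b <- strip(independent)
  key_a <- paste(a$task, a$output)
  key_b <- paste(b$task, b$output)
  if (!setequal(key_a, key_b) || length(key_a) != length(key_b)) {
    stop_kneeload("tables do not cover identical task/output combinations",
      class = "kneeload_metric_error"
    )
  }
  b <- b[match(key_a, key_b), ]
  out <- data.frame(
    task = a$task, output = a$output,
    delta_r = b$r_mean - a$r_mean,
    delta_rmse = b$rmse_mean - a$rmse_mean,
    delta_rrmse = b$rrmse_mean - a$rrmse_mean,
    stringsAsFactors = FALSE
  )
  cross_task_mean(out)
}

#' Run the full leave-one-subject-out cross-validation
#'
#' For each fold, assembles the training matrices from the other
#' participants' normalized trials, fits the scalers on that training fold
#' only, trains a network (initialization seed derived from `seed` and the
#' fold index), and predicts every trial of the held-out participant.
#'
#' @param norm_trials list of `normalized_trial` objects (see
#'   [preprocess_cohort()]).
#' @param outputs `"both"`, `"kfm"`, or `"kam"`.
#' @param hidden hidden-layer sizes (default `c(100, 20)`).
#' @param config a [train_config()]; its `seed` is mixed with the fold index
#'   so every fold gets its own initialization stream.
#' @param seed master seed for fold-level derivation (default
#'   `config$seed`).
#' @param verbose print per-fold progress.
#' @return list of fold results (see [evaluate_folds()]), with the trained
#'   model attached as `$model` per fold.
#' @export
run_loso <- function(norm_trials, outputs = "both", hidden = c(100, 20),
                     config = train_config(), seed = config$seed,
                     verbose = FALSE) {
  ids <- vapply(norm_trials, `[[`, "", "participant_id")
  folds <- loso_folds(ids)
  lapply(seq_along(folds), function(fi) {
    fold <- folds[[fi]]
    train_set <- norm_trials[ids %in% fold$train]
    test_set <- norm_trials[ids == fold$test]
    mats <- assemble_matrices(train_set, outputs = outputs)
    cfg <- config
    cfg$seed <- derive_seed(seed, 7919L, fi)
    model <- train_network(mats$X, mats$Y, hidden = hidden, config = cfg)
    if (verbose) {
      message(sprintf(
        "fold %d/%d (test %s): %d epochs, MSE %.4g",
        fi, length(folds), fold$test, nrow(model$log), tail(model$log$mse, 1)
      ))
    }
    trials <- lapply(test_set, function(t) {
      ref <- switch(outputs,
        both = t$targets,
        kfm = t$targets[, "kfm", drop = FALSE],
        kam = t$targets[, "kam", drop = FALSE]
      )
      est <- predict(model, t$inputs)
      colnames(est) <- colnames(ref)
      list(task = t$task, trial_index = t$trial_index, est = est, ref = ref)
    })
    list(participant = fold$test, trials = trials, model = model)
  })
}
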