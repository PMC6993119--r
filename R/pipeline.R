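# End-to-end experiment orchestration: simulate -> preprocess -> LOSO
# train/evaluate -> report -> compare.

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment. One master `seed`
#' governs cohort generation and all per-fold network initializations via
#' derived sub-seeds, so a single number reproduces the whole experiment.
#'
#' @param cohort a [cohort_config()].
#' @param train a [train_config()].
#' @param outputs `"both"` (combined two-output model), `"kfm"` / `"kam"`
#'   (one independent model), or `"all"` (combined plus both independent
#'   models and the model-comparison table).
#' @param hidden hidden-layer sizes (default `c(100, 20)`).
#' @param n_steps stance-percent steps (default 100).
#' @param signed_pdiff,pooling forwarded to [evaluate_folds()].
#' @param write_trials also write every simulated trial plus a manifest
#'   under the output directory (default `FALSE`; the cohort is fully
#'   reproducible from the config, so files are opt-in).
#' @param save_models write each fold's trained model as JSON.
#' @param seed master seed; overrides `cohort$seed`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(), train = train_config(),
                              outputs = c("both", "kfm", "kam", "all"),
                              hidden = c(100, 20), n_steps = 100,
                              signed_pdiff = TRUE, pooling = "trial",
                              write_trials = FALSE, save_models = FALSE,
                              seed = cohort$seed) {
  outputs <- match.arg(outputs)
  stopifnot(inherits(cohort, "cohort_config"), inherits(train, "train_config"))
  cohort$seed <- as.integer(seed)
  structure(
    list(
      cohort = cohort, train = train, outputs = outputs, hidden = hidden,
      n_steps = n_steps, signed_pdiff = signed_pdiff, pooling = pooling,
      write_trials = write_trials, save_models = save_models,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

run_variant <- function(norm_trials, variant, config, out_dir, verbose) {
  folds <- run_loso(
    norm_trials,
    outputs = variant, hidden = config$hidden,
    config = config$train,
    seed = derive_seed(config$seed, match(variant, c("both", "kfm", "kam"))),
    verbose = verbose
  )
  if (config$save_models) {
    mdir <- file.path(out_dir, paste0("models_", variant))
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(folds)) {
      write_model(folds[[i]]$model, file.path(
        mdir,
        sprintf("fold_%s.json", folds[[i]]$participant)
      ))
    }
  }
  folds
}

#' Run the full experiment from a single configuration
#'
#' Generates the synthetic cohort, preprocesses every trial, runs
#' leave-one-subject-out cross-validation for the requested model
#' variant(s), and writes the result tables to `out_dir`:
#' `continuous_accuracy.csv` (per-task r/RMSE/rRMSE), `discrete_load.csv`
#' (reference and estimated peak/impulse), `discrete_pdiff.csv` (percent
#' differences), and - with `outputs = "all"` - `model_comparison.csv`
#' (independent minus combined deltas), plus a machine-readable
#' `summary.json`. Identical config and seed give identical outputs.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print per-fold progress.
#' @return invisibly, a list with the evaluation tables per variant and the
#'   comparison table (if computed).
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (verbose) message("simulating cohort ...")
  cohort <- generate_cohort(config$cohort)
  if (config$write_trials) {
    if (verbose) message("writing trials + manifest ...")
    write_cohort(cohort, file.path(out_dir, "trials"))
  }
  if (verbose) message("preprocessing ...")
  norm_trials <- preprocess_cohort(cohort, n_steps = config$n_steps)

  variants <- if (config$outputs == "all") c("both", "kfm", "kam") else config$outputs
  results <- list()
  for (v in variants) {
    if (verbose) message("LOSO cross-validation, outputs = ", v, " ...")
    folds <- run_variant(norm_trials, v, config, out_dir, verbose)
    results[[v]] <- evaluate_folds(folds,
      signed_pdiff = config$signed_pdiff,
      pooling = config$pooling
    )
  }

  primary <- results[[variants[1]]]
  write_metrics_table(primary$task_metrics, file.path(out_dir, "continuous_accuracy.csv"))
  disc <- primary$discrete_metrics
  write_metrics_table(
    disc[c("task", "output", "metric", "ref_mean", "ref_sd", "est_mean", "est_sd")],
    file.path(out_dir, "discrete_load.csv")
  )
  write_metrics_table(
    disc[c("task", "output", "metric", "pdiff_mean", "pdiff_sd")],
    file.path(out_dir, "discrete_pdiff.csv")
  )

  comparison <- NULL
  if (config$outputs == "all") {
    independent <- rbind(
      results$kfm$task_metrics[results$kfm$task_metrics$output == "kfm", ],
      results$kam$task_metrics[results$kam$task_metrics$output == "kam", ]
    )
    independent <- independent[independent$task != "Mean", ]
    combined <- results$both$task_metrics
    combined <- combined[combined$task != "Mean", ]
    comparison <- compare_models(combined, independent)
    write_metrics_table(comparison, file.path(out_dir, "model_comparison.csv"))
  }

  summary <- list(
    seed = config$seed,
    outputs = config$outputs,
    n_participants = config$cohort$n_participants,
    tasks = config$cohort$tasks,
    trials_per_task = config$cohort$trials_per_task,
    hidden = config$hidden,
    mean_row = lapply(results, function(res) {
      m <- res$task_metrics[res$task_metrics$task == "Mean", ]
      split(
        m[c("output", "r_mean", "rmse_mean", "rrmse_mean")],
        seq_len(nrow(m))
      )
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    digits = 12, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(results = results, comparison = comparison))
}
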