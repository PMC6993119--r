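# Published per-task reference values shipped with the package.

ref_path <- function(file) {
  system.file("extdata", file, package = "kneeload", mustWork = TRUE)
}

#' Published per-task reference metrics of the two-IMU knee-load estimator
#'
#' Per-task accuracy values reported for the combined two-output estimator
#' in the validation study this package reimplements (13 healthy males, two
#' knee-sleeve IMUs, six locomotion tasks, leave-one-subject-out
#' cross-validation against inverse-dynamics reference moments). They are
#' shipped as plain CSVs and serve two purposes: worked-example inputs for
#' the cross-task aggregation functions (the published cross-task Mean rows
#' are arithmetic means of these per-task values, see [cross_task_mean()]),
#' and plausibility context for synthetic-cohort results.
#'
#' \describe{
#'   \item{`reference_continuous_accuracy()`}{per task and output (kfm,
#'     kam): Pearson r, RMSE (Nm/kg) and relative RMSE (%) as mean and sd
#'     over the 13 cross-validation folds.}
#'   \item{`reference_discrete_pdiff()`}{per task, output and metric (peak,
#'     impulse): signed percent difference between estimated and reference
#'     discrete load metrics, mean and sd.}
#'   \item{`reference_model_comparison()`}{per task and output: change in
#'     r, RMSE and rRMSE due to independent (single-output) model building,
#'     independent minus combined.}
#' }
#'
#' @return a data frame (see above).
#' @export
#' @examples
#' acc <- reference_continuous_accuracy()
#' # the published cross-task Mean row is the arithmetic mean per column:
#' subset(cross_task_mean(acc), task == "Mean")
reference_continuous_accuracy <- function() {
  utils::read.csv(ref_path("reference_continuous_accuracy.csv"),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_continuous_accuracy
#' @export
reference_discrete_pdiff <- function() {
  utils::read.csv(ref_path("reference_discrete_pdiff.csv"),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_continuous_accuracy
#' @export
reference_model_comparison <- function() {
  utils::read.csv(ref_path("reference_model_comparison.csv"),
    stringsAsFactors = FALSE
  )
}
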