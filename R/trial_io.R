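# Plain-text I/O: trials, cohort manifests, trained models, result tables.
#
# Trial file dialect: a commented header block of "# key: value" lines
# (participant_id, task, trial_index, body_mass_kg, imu_rate, grf_rate,
# accel_units), then two CSV sections introduced by "# section: imu" and
# "# section: grf". The IMU section has the 12 fixed channel columns at
# imu_rate; the GRF section has vgrf, kfm_nm, kam_nm at grf_rate. Everything
# is human-inspectable and diff-friendly; numbers round-trip at full double
# precision.

REQUIRED_HEADER_KEYS <- c(
  "participant_id", "task", "trial_index", "body_mass_kg",
  "imu_rate", "grf_rate"
)
GRF_COLUMNS <- c("vgrf", "kfm_nm", "kam_nm")

fmt_num <- function(x) trimws(formatC(x, digits = 17, format = "g"))

#' Write / read a trial in the plain-text trial format
#'
#' @param trial a `raw_trial` (see [generate_cohort()]).
#' @param path file path.
#' @param accel_units units the accelerometer columns are stored in:
#'   `"m/s^2"` (default) or `"g"`. On read, g-unit accelerations are
#'   converted to SI, so [read_trial()] always returns m/s^2.
#' @return `write_trial`: `path`, invisibly. `read_trial`: a `raw_trial`.
#' @export
write_trial <- function(trial, path, accel_units = c("m/s^2", "g")) {
  accel_units <- match.arg(accel_units)
  imu <- trial$imu
  if (accel_units == "g") {
    acc <- grepl("_a[xyz]$", colnames(imu))
    imu[, acc] <- imu[, acc] / GRAVITY
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# participant_id: %s", trial$participant_id),
    sprintf("# task: %s", trial$task),
    sprintf("# trial_index: %d", trial$trial_index),
    sprintf("# body_mass_kg: %s", fmt_num(trial$body_mass_kg)),
    sprintf("# imu_rate: %s", fmt_num(trial$imu_rate)),
    sprintf("# grf_rate: %s", fmt_num(trial$grf_rate)),
    sprintf("# accel_units: %s", accel_units),
    "# section: imu",
    paste(colnames(imu), collapse = ",")
  ), con)
  writeLines(apply(imu, 1, function(r) paste(fmt_num(r), collapse = ",")), con)
  writeLines(c("# section: grf", paste(GRF_COLUMNS, collapse = ",")), con)
  grf <- cbind(trial$vgrf, trial$ref_moments)
  writeLines(apply(grf, 1, function(r) paste(fmt_num(r), collapse = ",")), con)
  invisible(path)
}

parse_section <- function(lines, expected_cols, what, path) {
  if (length(lines) < 2) {
    stop_kneeload("trial file ", path, ": empty ", what, " section",
      class = "kneeload_format_error"
    )
  }
  cols <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing <- setdiff(expected_cols, cols)
  if (length(missing) > 0) {
    stop_kneeload("trial file ", path, ": ", what, " section missing column(s): ",
      paste(missing, collapse = ", "),
      class = "kneeload_format_error"
    )
  }
  dat <- utils::read.csv(textConnection(lines[-1]), header = FALSE, col.names = cols)
  as.matrix(dat[, expected_cols, drop = FALSE])
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) {
    stop_kneeload("trial file not found: ", path, class = "kneeload_format_error")
  }
  lines <- readLines(path)
  hdr_lines <- grep("^# (?!section:)", lines, perl = TRUE, value = TRUE)
  header <- list()
  for (h in hdr_lines) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    header[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  missing <- setdiff(REQUIRED_HEADER_KEYS, names(header))
  if (length(missing) > 0) {
    stop_kneeload("trial file ", path, ": missing header key(s): ",
      paste(missing, collapse = ", "),
      class = "kneeload_format_error"
    )
  }
  sec <- grep("^# section:", lines)
  sec_names <- trimws(sub("^# section:", "", lines[sec]))
  if (!all(c("imu", "grf") %in% sec_names)) {
    stop_kneeload("trial file ", path, ": need both 'imu' and 'grf' sections",
      class = "kneeload_format_error"
    )
  }
  bounds <- c(sec, length(lines) + 1L)
  section_lines <- function(name) {
    i <- which(sec_names == name)[1]
    lines[(sec[i] + 1L):(bounds[i + 1L] - 1L)]
  }
  imu <- parse_section(section_lines("imu"), imu_channel_names(), "imu", path)
  grf <- parse_section(section_lines("grf"), GRF_COLUMNS, "grf", path)

  mass <- as.numeric(header$body_mass_kg)
  imu_rate <- as.numeric(header$imu_rate)
  grf_rate <- as.numeric(header$grf_rate)
  if (is.na(mass) || mass <= 0) {
    stop_kneeload("trial file ", path, ": body mass must be positive",
      class = "kneeload_format_error"
    )
  }
  if (is.na(imu_rate) || is.na(grf_rate) || imu_rate <= 0 || grf_rate <= 0) {
    stop_kneeload("trial file ", path, ": rates must be positive",
      class = "kneeload_format_error"
    )
  }
  # streams must cover the same interval to within one sample period
  dur_diff <- abs(nrow(imu) / imu_rate - nrow(grf) / grf_rate)
  if (dur_diff > 1 / min(imu_rate, grf_rate) + 1e-9) {
    stop_kneeload(
      "trial file ", path, ": IMU and GRF stream durations differ by ",
      signif(dur_diff, 3), " s (rate mismatch)",
      class = "kneeload_format_error"
    )
  }
  units <- if (is.null(header$accel_units)) "m/s^2" else header$accel_units
  if (units == "g") {
    acc <- grepl("_a[xyz]$", colnames(imu))
    imu[, acc] <- imu[, acc] * GRAVITY
  } else if (units != "m/s^2") {
    stop_kneeload("trial file ", path, ": unknown accel_units '", units, "'",
      class = "kneeload_format_error"
    )
  }
  ref <- grf[, c("kfm_nm", "kam_nm")]
  colnames(ref) <- c("kfm", "kam")
  structure(
    list(
      participant_id = header$participant_id,
      task = header$task,
      trial_index = as.integer(header$trial_index),
      body_mass_kg = mass,
      imu_rate = imu_rate, grf_rate = grf_rate,
      imu = imu, vgrf = unname(grf[, "vgrf"]), ref_moments = ref
    ),
    class = "raw_trial"
  )
}

#' Write / read a cohort manifest
#'
#' A manifest is a CSV listing trial file paths (relative to the manifest's
#' directory) with per-trial metadata. Reading validates that every
#' referenced file exists and that (participant, task, trial) triples are
#' unique.
#'
#' @param trials list of `raw_trial` objects already written to `dir`.
#' @param paths character vector of trial file paths (same order).
#' @param path manifest file path.
#' @return `read_manifest`: a data frame of class `cohort_manifest` with
#'   columns `path`, `participant_id`, `task`, `trial_index`,
#'   `body_mass_kg`, `imu_rate`, `grf_rate` (paths resolved against the
#'   manifest directory).
#' @export
write_manifest <- function(trials, paths, path) {
  stopifnot(length(trials) == length(paths))
  df <- data.frame(
    path = paths,
    participant_id = vapply(trials, `[[`, "", "participant_id"),
    task = vapply(trials, `[[`, "", "task"),
    trial_index = vapply(trials, function(t) as.integer(t$trial_index), 1L),
    body_mass_kg = vapply(trials, `[[`, 1.0, "body_mass_kg"),
    imu_rate = vapply(trials, `[[`, 1.0, "imu_rate"),
    grf_rate = vapply(trials, `[[`, 1.0, "grf_rate"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_kneeload("manifest not found: ", path, class = "kneeload_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("manifest ", path, " lists no trials", call. = FALSE)
    class(df) <- c("cohort_manifest", class(df))
    return(df)
  }
  key <- paste(df$participant_id, df$task, df$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), ]
    stop_kneeload(
      "manifest ", path, ": duplicate participant/task/trial triple(s), e.g. ",
      dup$participant_id[1], " / ", dup$task[1], " / ", dup$trial_index[1],
      class = "kneeload_format_error"
    )
  }
  resolved <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$path), df$path,
    file.path(dirname(path), df$path)
  )
  gone <- !file.exists(resolved)
  if (any(gone)) {
    stop_kneeload("manifest ", path, ": missing trial file(s): ",
      paste(utils::head(df$path[gone], 3), collapse = ", "),
      class = "kneeload_format_error"
    )
  }
  df$path <- resolved
  class(df) <- c("cohort_manifest", class(df))
  df
}

#' Write a cohort of trials plus manifest to a directory
#'
#' @param cohort output of [generate_cohort()] (or a plain list of
#'   `raw_trial`s).
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- lapply(cohort, function(x) if (!is.null(x[["trial"]])) x[["trial"]] else x)
  paths <- vapply(trials, function(t) {
    sprintf(
      "%s_%s_t%02d.csv", t$participant_id,
      gsub("[^A-Za-z0-9]+", "-", t$task), t$trial_index
    )
  }, "")
  for (i in seq_along(trials)) write_trial(trials[[i]], file.path(dir, paths[i]))
  manifest <- file.path(dir, "manifest.csv")
  write_manifest(trials, paths, manifest)
  invisible(manifest)
}

#' Serialize / restore a trained model as JSON
#'
#' Documented language-agnostic layout: layer sizes, per-layer row-major
#' weight lists and bias lists, the min-max scaler parameters, output names
#' and the training log. Round-trips at full double precision.
#'
#' @param model a `kneeload_mlp` from [train_network()].
#' @param path JSON file path.
#' @return `read_model`: a `kneeload_mlp`.
#' @export
write_model <- function(model, path) {
  scaler_json <- function(s) {
    list(min = unname(s$min), max = unname(s$max), constant = unname(s$constant))
  }
  obj <- list(
    format = "kneeload_mlp",
    layer_sizes = model$params$layer_sizes,
    weights = lapply(model$params$W, function(W) {
      list(rows = nrow(W), cols = ncol(W), data = as.vector(t(W)))
    }),
    biases = lapply(model$params$b, unname),
    input_scaler = scaler_json(model$scalers$input),
    target_scaler = scaler_json(model$scalers$target),
    outputs = model$outputs,
    stop_reason = attr(model$log, "stop_reason"),
    log = as.data.frame(model$log)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "kneeload_mlp") {
    stop_kneeload("not a kneeload model file: ", path, class = "kneeload_format_error")
  }
  sizes <- as.integer(obj$layer_sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    w <- obj$weights[l, ]
    matrix(unlist(w$data), nrow = w$rows, ncol = w$cols, byrow = TRUE)
  })
  b <- obj$biases
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  scaler_from <- function(s) {
    structure(
      list(
        min = as.numeric(s$min), max = as.numeric(s$max),
        constant = as.logical(s$constant)
      ),
      class = "minmax_scaler"
    )
  }
  log <- obj$log
  attr(log, "stop_reason") <- obj$stop_reason
  class(log) <- c("train_log", class(log))
  structure(
    list(
      params = structure(list(layer_sizes = sizes, W = W, b = b), class = "mlp_params"),
      scalers = list(
        input = scaler_from(obj$input_scaler),
        target = scaler_from(obj$target_scaler)
      ),
      log = log,
      outputs = obj$outputs
    ),
    class = "kneeload_mlp"
  )
}

#' Write / read a tidy result table as CSV
#'
#' Result tables (per-task metrics, discrete load metrics, model
#' comparison) round-trip through plain CSV at full precision.
#'
#' @param table data frame.
#' @param path CSV path.
#' @return `read_metrics_table`: the data frame.
#' @export
write_metrics_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
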