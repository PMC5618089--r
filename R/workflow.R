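# End-to-end workflows behind the command-line entry points: simulate,
# fit, predict, validate, quantify. Each writes its outputs plus a
# reproducibility block (seed, config hash, package version) as a
# plain-text + JSON report pair.

report_block <- function(seed, config) {
  list(
    package = "secofate",
    version = as.character(utils::packageVersion("secofate")),
    seed = if (is.null(seed)) NA else as.integer(seed),
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_report <- function(report, out_dir, name) {
  json_path <- file.path(out_dir, paste0(name, ".json"))
  txt_path <- file.path(out_dir, paste0(name, ".txt"))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  lines <- utils::capture.output(utils::str(report, give.attr = FALSE))
  writeLines(c(sprintf("secofate %s report", name), lines), txt_path)
  invisible(list(json = json_path, txt = txt_path))
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    fate_abort(sprintf("Cannot create output directory %s.", out_dir),
               "config_error")
  }
  out_dir
}

as_dataset <- function(dataset) {
  if (is.character(dataset)) read_batch_csv(dataset) else
    validate_batch_table(dataset)
}

as_models <- function(models) {
  if (is.character(models)) read_models(models) else {
    stopifnot(inherits(models, "stage_models"))
    models
  }
}

#' Simulate a batch dataset to disk
#'
#' Wraps [generate_dataset()]: draws the dataset, writes it as
#' `dataset.csv` in the batch-table CSV schema, and writes a
#' `simulate_report` (JSON + text) echoing the configuration, the seed and a
#' config hash so the run can be reproduced byte for byte.
#'
#' @param config A [generator_config()], a YAML path for
#'   [read_generator_config()], or `NULL` for [default_generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @return Invisibly, a list with the dataset tibble and output paths.
#' @export
run_simulate <- function(config = NULL, out_dir = ".", seed = NULL) {
  if (is.null(config)) {
    config <- default_generator_config()
  } else if (is.character(config)) {
    config <- read_generator_config(config)
  }
  if (!inherits(config, "generator_config")) {
    fate_abort("`config` must be a generator_config or a YAML path.",
               "config_error")
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(check_number(seed, "seed"))
  }
  ensure_out_dir(out_dir)
  dataset <- generate_dataset(config)
  csv_path <- file.path(out_dir, "dataset.csv")
  write_batch_csv(dataset, csv_path)
  report <- list(
    run = report_block(config$seed, config),
    n_batches = length(unique(dataset$batch_id)),
    varieties = names(config$varieties),
    n_batches_per_variety = config$n_batches_per_variety,
    mi_range = config$mi_range, noise_cv = config$noise_cv,
    dataset_csv = csv_path
  )
  paths <- write_report(report, out_dir, "simulate_report")
  fate_log("run_simulate: wrote %d batches to %s",
           report$n_batches, csv_path)
  invisible(list(dataset = dataset, dataset_csv = csv_path, report = report,
                 report_paths = paths))
}

#' Calibrate all stage models from a dataset and write them to disk
#'
#' Wraps [fit_stage_models()]: fits every available model, serializes the
#' bundle to `models.yaml` and writes a `fit_report` listing each fit's
#' sample count, estimates and r-squared.
#'
#' @param dataset A batch table or a CSV path.
#' @param out_dir Output directory.
#' @param seed Optional seed recorded in the report (fitting itself is
#'   deterministic).
#' @return Invisibly, a list with the [stage_models()] bundle and paths.
#' @export
run_fit <- function(dataset, out_dir = ".", seed = NULL) {
  tbl <- as_dataset(dataset)
  ensure_out_dir(out_dir)
  models <- fit_stage_models(tbl)
  yaml_path <- file.path(out_dir, "models.yaml")
  write_models(models, yaml_path)
  report <- list(
    run = report_block(seed, tbl),
    crushing = purrr::map(unname(models$crushing), function(m)
      list(variety = m$variety, slope = m$slope, intercept = m$intercept,
           r2 = m$r2, n = m$n)),
    malaxation = purrr::map(unname(models$malaxation), function(m)
      list(variety = m$variety, family = m$family, slope = m$slope,
           r2 = m$r2, n = m$n)),
    partition = purrr::map(unname(models$partition), function(m)
      list(family = m$family, K = m$K, n = m$n)),
    models_yaml = yaml_path
  )
  paths <- write_report(report, out_dir, "fit_report")
  invisible(list(models = models, models_yaml = yaml_path, report = report,
                 report_paths = paths))
}

#' Predict stage profiles for new fruit batches
#'
#' Wraps [run_fate_pipeline()]: reads calibrated models and a dataset whose
#' batches carry fruit profiles (plus a recorded milling intensity or a
#' measured crushed profile to compute one), and writes the predicted
#' crushed/kneaded/oil rows as `predicted.csv`.
#'
#' @param models A [stage_models()] bundle or a YAML path.
#' @param fruit A batch table or CSV path with the fruit-stage rows.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the predicted rows tibble and paths.
#' @export
run_predict <- function(models, fruit, out_dir = ".") {
  models <- as_models(models)
  tbl <- as_dataset(fruit)
  ensure_out_dir(out_dir)
  out <- run_fate_pipeline(tbl, models)
  predicted <- out[out$source == "predicted", ]
  csv_path <- file.path(out_dir, "predicted.csv")
  readr::write_csv(predicted, csv_path, na = "")
  report <- list(
    run = report_block(NULL, list(models = models, fruit = tbl)),
    n_batches = length(unique(predicted$batch_id)),
    predicted_csv = csv_path
  )
  paths <- write_report(report, out_dir, "predict_report")
  invisible(list(predicted = predicted, predicted_csv = csv_path,
                 report = report, report_paths = paths))
}

#' Validate calibrated models against measured data
#'
#' Runs the full prediction chain on a measured dataset and, for every
#' combination of stage, secoiridoid family and variety (plus pooled), fits
#' measured against predicted concentrations through the origin: a slope
#' near 1 and a high r-squared mean the stage models transfer to those
#' batches. Writes a `validation_report` (JSON + text).
#'
#' @param models A [stage_models()] bundle or YAML path.
#' @param dataset A batch table or CSV path with measured stages.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the validation tibble (columns `stage`,
#'   `family`, `variety`, `n`, `slope`, `r2`) and report paths.
#' @export
run_validate <- function(models, dataset, out_dir = ".") {
  models <- as_models(models)
  tbl <- as_dataset(dataset)
  ensure_out_dir(out_dir)
  out <- run_fate_pipeline(tbl, models)
  fams <- c("htyr_sec", "tyr_sec")
  long <- out |>
    dplyr::select(dplyr::all_of(c("batch_id", "variety", "stage", "source",
                                  "conc_htyr_sec", "conc_tyr_sec"))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("conc_", fams)),
                        names_to = "family", values_to = "conc",
                        names_prefix = "conc_") |>
    tidyr::pivot_wider(names_from = "source", values_from = "conc")
  if (!"measured" %in% names(long)) long$measured <- NA_real_
  pairs <- long[!is.na(long$measured) & !is.na(long$predicted) &
                  long$stage != "fruit", ]
  groups <- dplyr::bind_rows(
    dplyr::mutate(pairs, group = .data$variety),
    dplyr::mutate(pairs, group = "pooled")
  )
  res <- groups |>
    dplyr::group_by(.data$stage, .data$family, .data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 1 || sum(d$predicted^2) == 0) return(tibble::tibble())
      fit <- validate_prediction(d$predicted, d$measured)
      tibble::tibble(n = fit$n, slope = fit$slope, r2 = fit$r2)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(variety = "group")
  report <- list(
    run = report_block(NULL, list(models = models, dataset = tbl)),
    validation = purrr::transpose(as.list(res))
  )
  paths <- write_report(report, out_dir, "validation_report")
  invisible(list(validation = res, report = report, report_paths = paths))
}

#' Quantify a peak-area CSV into concentrations
#'
#' Wraps [quantify()] over every sample of a peak-area CSV (optionally with
#' a response-factor table) and writes the resulting family concentrations
#' as `quantified.csv`.
#'
#' @param peak_csv Peak-area CSV path (see [read_peak_csv()]).
#' @param rf_csv Optional response-factor CSV path (see [read_rf_csv()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the concentrations tibble and paths.
#' @export
run_quantify <- function(peak_csv, rf_csv = NULL, out_dir = ".") {
  rf <- if (is.null(rf_csv)) NULL else read_rf_csv(rf_csv)
  tables <- read_peak_csv(peak_csv, rf = rf)
  ensure_out_dir(out_dir)
  rows <- purrr::map(tables, function(pt) {
    prof <- quantify(pt)
    tibble::tibble(
      sample_id = pt$sample_id, matrix = pt$matrix, stage = prof$stage,
      conc_ole_glu = prof$concentrations[["ole_glu"]],
      conc_htyr_sec = prof$concentrations[["htyr_sec"]],
      conc_tyr_sec = prof$concentrations[["tyr_sec"]],
      conc_total = total_phenolics(prof)
    )
  })
  res <- dplyr::bind_rows(rows)
  csv_path <- file.path(out_dir, "quantified.csv")
  readr::write_csv(res, csv_path, na = "")
  report <- list(
    run = report_block(NULL, list(peak_csv = peak_csv, rf = rf)),
    n_samples = nrow(res), quantified_csv = csv_path
  )
  paths <- write_report(report, out_dir, "quantify_report")
  invisible(list(quantified = res, quantified_csv = csv_path,
                 report = report, report_paths = paths))
}
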