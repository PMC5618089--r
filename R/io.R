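# CSV and model-file I/O.
#
# CSV dialect: UTF-8, comma-separated, mandatory header, "." decimal
# separator. Missing measurements are empty cells, never zeros.

BATCH_COL_TYPES <- readr::cols(
  batch_id = readr::col_character(),
  variety = readr::col_character(),
  stage = readr::col_character(),
  humidity = readr::col_double(),
  added_water = readr::col_double(),
  mill_type = readr::col_character(),
  rpm = readr::col_double(),
  grid_mm = readr::col_double(),
  milling_intensity = readr::col_double(),
  conc_ole_glu = readr::col_double(),
  conc_htyr_sec = readr::col_double(),
  conc_tyr_sec = readr::col_double()
)

#' Read and write batch tables as CSV
#'
#' The CSV schema is the batch table of [as_batch_table()]: one row per
#' batch x stage. Empty cells are unmeasured values (`NA`); they are written
#' back as empty cells so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return `read_batch_csv`: the validated batch tibble. `write_batch_csv`:
#'   `path`, invisibly.
#' @export
read_batch_csv <- function(path) {
  if (!file.exists(path)) {
    fate_abort(sprintf("File not found: %s", path), "input_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec <- BATCH_COL_TYPES
  spec$cols <- spec$cols[intersect(names(spec$cols), header)]
  tbl <- tryCatch(
    readr::read_csv(path, col_types = spec, na = c("", "NA"),
                    progress = FALSE),
    error = function(e) fate_abort(
      sprintf("Failed to parse %s: %s", path, conditionMessage(e)),
      "input_error")
  )
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    fate_abort(sprintf("Malformed CSV %s: first problem at row %d, column %d (%s).",
                       path, probs$row[1], probs$col[1], probs$expected[1]),
               "input_error")
  }
  keep <- intersect(c(BATCH_COLUMNS, "milling_intensity"), names(tbl))
  validate_batch_table(tbl[, keep])
}

#' @rdname read_batch_csv
#' @param tbl A batch table.
#' @export
write_batch_csv <- function(tbl, path) {
  tbl <- validate_batch_table(tbl)
  readr::write_csv(tbl, path, na = "")
  invisible(path)
}

# Model serialization ----------------------------------------------------

#' Serialize and restore calibrated stage models
#'
#' Stage models are written to a YAML file recording, per model, the
#' variety/family, the estimates (slope/intercept or K), r-squared and the
#' sample count — enough to audit a calibration and to re-run predictions
#' without the training data.
#'
#' @param models A [stage_models()] bundle.
#' @param path File path (YAML).
#' @return `write_models`: `path`, invisibly. `read_models`: a
#'   [stage_models()] bundle.
#' @export
write_models <- function(models, path) {
  stopifnot(inherits(models, "stage_models"))
  doc <- list(
    format = "secofate_models", version = 1L,
    crushing = purrr::map(unname(models$crushing), function(m)
      list(variety = m$variety, slope = m$slope, intercept = m$intercept,
           r2 = m$r2, n = m$n)),
    malaxation = purrr::map(unname(models$malaxation), function(m)
      list(variety = m$variety, family = m$family, slope = m$slope,
           r2 = m$r2, n = m$n)),
    partition = purrr::map(unname(models$partition), function(m)
      list(family = m$family, K = m$K, n = m$n,
           per_sample_K = as.list(m$per_sample_K)))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  if (!file.exists(path)) {
    fate_abort(sprintf("Model file not found: %s", path), "input_error")
  }
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "secofate_models")) {
    fate_abort(sprintf("%s is not a secofate model file.", path),
               "config_error")
  }
  stage_models(
    crushing = purrr::map(doc$crushing, function(m)
      new_crushing_model(m$variety, m$slope, m$intercept, m$r2,
                         as.integer(m$n))),
    malaxation = purrr::map(doc$malaxation, function(m)
      new_malaxation_model(m$variety, m$family, m$slope, m$r2,
                           as.integer(m$n))),
    partition = purrr::map(doc$partition, function(m)
      new_partition_model(m$family, m$K, as.integer(m$n),
                          unlist(m$per_sample_K)))
  )
}

# Generator config YAML --------------------------------------------------

#' Read a generator configuration from YAML
#'
#' The YAML mirrors [generator_config()]: top-level
#' `n_batches_per_variety`, `mi_range`, `noise_cv`, `seed`, `ole_depletion`
#' and a `varieties` list whose entries are [variety_params()] fields.
#' Omitted fields take the package defaults.
#'
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    fate_abort(sprintf("Config file not found: %s", path), "config_error")
  }
  doc <- yaml::read_yaml(path)
  args <- doc[intersect(names(doc),
                        c("n_batches_per_variety", "mi_range", "noise_cv",
                          "seed", "ole_depletion"))]
  if (!is.null(doc$varieties)) {
    args$varieties <- purrr::map(doc$varieties, function(v)
      do.call(variety_params, v))
  }
  if (is.null(args$varieties)) {
    do.call(default_generator_config, args)
  } else {
    do.call(generator_config, args)
  }
}

# Peak-area CSV ----------------------------------------------------------

#' Read peak-area and response-factor CSV files
#'
#' The peak-area CSV has columns `sample_id`, `matrix`, `sample_mass_g`,
#' `is_mass_mg`, `is_area`, then one column per compound area (see
#' [compound_families()]). The response-factor table is a two-column CSV
#' `compound, rf`.
#'
#' @param path Peak-area CSV path.
#' @param rf Optional named numeric vector of response factors (e.g. from
#'   [read_rf_csv()]) applied to every sample.
#' @return `read_peak_csv`: a list of [peak_table()]s. `read_rf_csv`: a
#'   named numeric vector.
#' @export
read_peak_csv <- function(path, rf = NULL) {
  if (!file.exists(path)) {
    fate_abort(sprintf("File not found: %s", path), "input_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("sample_id", "matrix", "sample_mass_g", "is_mass_mg", "is_area")
  missing_cols <- setdiff(meta, names(tbl))
  if (length(missing_cols)) {
    fate_abort(sprintf("Peak CSV is missing column(s): %s.",
                       paste(missing_cols, collapse = ", ")), "input_error")
  }
  compounds <- setdiff(names(tbl), meta)
  purrr::map(seq_len(nrow(tbl)), function(i) {
    areas <- unlist(tbl[i, compounds])
    areas <- areas[!is.na(areas)]
    peak_table(tbl$sample_id[i], tbl$matrix[i], tbl$sample_mass_g[i],
               tbl$is_mass_mg[i], tbl$is_area[i], analyte_areas = areas,
               response_factors = if (is.null(rf)) NULL else
                 rf[intersect(names(rf), names(areas))])
  })
}

#' @rdname read_peak_csv
#' @export
read_rf_csv <- function(path) {
  if (!file.exists(path)) {
    fate_abort(sprintf("File not found: %s", path), "input_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("compound", "rf") %in% names(tbl))) {
    fate_abort("Response-factor CSV needs columns `compound` and `rf`.",
               "input_error")
  }
  setNames(tbl$rf, tbl$compound)
}
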