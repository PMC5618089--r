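# The fitted-model bundle and the fruit -> oil prediction chain.

#' Bundle calibrated stage models
#'
#' @param crushing Named list of [fit_crushing()] models, keyed by variety.
#' @param malaxation List of [fit_malaxation()] models; looked up by
#'   variety + family with fallback to a pooled model of the same family.
#' @param partition Named list of [estimate_partition()] models, keyed by
#'   family.
#' @return An object of class `stage_models`.
#' @export
stage_models <- function(crushing = list(), malaxation = list(),
                         partition = list()) {
  stopifnot(all(vapply(crushing, inherits, logical(1), "crushing_model")),
            all(vapply(malaxation, inherits, logical(1), "malaxation_model")),
            all(vapply(partition, inherits, logical(1), "partition_model")))
  names(crushing) <- vapply(crushing, `[[`, character(1), "variety")
  names(malaxation) <- vapply(malaxation, function(m)
    paste(m$variety, m$family, sep = "/"), character(1))
  names(partition) <- vapply(partition, `[[`, character(1), "family")
  structure(list(crushing = crushing, malaxation = malaxation,
                 partition = partition),
            class = "stage_models")
}

#' @export
print.stage_models <- function(x, ...) {
  cat("<stage_models>\n")
  for (m in x$crushing) print(m)
  for (m in x$malaxation) print(m)
  for (m in x$partition) print(m)
  invisible(x)
}

get_crushing <- function(models, variety) {
  m <- models$crushing[[variety]]
  if (is.null(m)) {
    fate_abort(sprintf("No crushing model calibrated for variety `%s`.",
                       variety), "config_error")
  }
  m
}

get_malaxation <- function(models, variety, family) {
  m <- models$malaxation[[paste(variety, family, sep = "/")]]
  if (is.null(m)) m <- models$malaxation[[paste("pooled", family, sep = "/")]]
  if (is.null(m)) {
    fate_abort(sprintf("No malaxation model for variety `%s`, family `%s` (and no pooled fallback).",
                       variety, family), "config_error")
  }
  m
}

get_partition <- function(models, family) {
  m <- models$partition[[family]]
  if (is.null(m)) {
    fate_abort(sprintf("No partition model for family `%s`.", family),
               "config_error")
  }
  m
}

#' Calibrate all stage models from a batch dataset
#'
#' Convenience wrapper fitting, for each variety present, the crushing
#' regression and the per-variety HtyrSec malaxation transfer; the TyrSec
#' malaxation transfer pooled across varieties (its behaviour is
#' cultivar-independent); and the partition coefficients pooled per family
#' (HtyrSec, TyrSec, and the independently calibrated total). Stages missing
#' from the data simply leave the corresponding models out, with a warning.
#'
#' @param records A batch table.
#' @return A [stage_models()] bundle.
#' @export
fit_stage_models <- function(records) {
  tbl <- validate_batch_table(records)
  varieties <- unique(tbl$variety)
  crushing <- list()
  malaxation <- list()
  partition <- list()
  for (v in varieties) {
    crushing[[v]] <- tryCatch(
      fit_crushing(tbl, v),
      secofate_insufficient_data_error = function(e) {
        warn(sprintf("Crushing fit skipped for `%s`: %s", v,
                     conditionMessage(e)))
        NULL
      }
    )
    m <- tryCatch(
      fit_malaxation(tbl, v, "htyr_sec"),
      secofate_insufficient_data_error = function(e) {
        warn(sprintf("HtyrSec malaxation fit skipped for `%s`.", v))
        NULL
      }
    )
    if (!is.null(m)) malaxation <- c(malaxation, list(m))
  }
  m <- tryCatch(
    fit_malaxation(tbl, NULL, "tyr_sec"),
    secofate_insufficient_data_error = function(e) {
      warn("Pooled TyrSec malaxation fit skipped: no crushed-kneaded pairs.")
      NULL
    }
  )
  if (!is.null(m)) malaxation <- c(malaxation, list(m))
  for (fam in c("htyr_sec", "tyr_sec", "total")) {
    pm <- tryCatch(
      estimate_partition(tbl, fam),
      secofate_insufficient_data_error = function(e) {
        warn(sprintf("Partition fit skipped for `%s`: no kneaded-oil pairs.",
                     fam))
        NULL
      }
    )
    if (!is.null(pm)) partition[[fam]] <- pm
  }
  stage_models(crushing = crushing[!vapply(crushing, is.null, logical(1))],
               malaxation = malaxation, partition = partition)
}

#' Predict the full fate chain from fruit composition
#'
#' Runs the three calibrated stage models in sequence for every batch with a
#' fruit profile: crushing (HtyrSec from the cultivar regression, TyrSec from
#' the milling-intensity definition `MI/100 * OleGlu_fruit`), malaxation
#' (through-origin transfer per family), and oil transfer (partition model
#' with the batch's water fraction). The milling intensity per batch is taken
#' from the `milling_intensity` column when present, otherwise computed from
#' a measured crushed profile; a batch with neither is an error.
#'
#' A batch with no precursor pool (fruit ole_glu = 0) has nothing to
#' transform: all downstream predictions are 0.
#'
#' @param records A batch table; measured rows are passed through untouched
#'   (tagged `source = "measured"`).
#' @param models A [stage_models()] bundle covering every variety present.
#' @return A batch table with a `source` column: the original measured rows
#'   plus predicted rows (`source = "predicted"`) for the crushed, kneaded
#'   and oil stages. `ole_glu` is only modelled as far as the process defines
#'   it (absent from predictions except its required 0 in the oil).
#' @export
run_fate_pipeline <- function(records, models) {
  stopifnot(inherits(models, "stage_models"))
  tbl <- validate_batch_table(records)
  if (!"milling_intensity" %in% names(tbl)) tbl$milling_intensity <- NA_real_
  fruit <- tbl[tbl$stage == "fruit", ]
  if (nrow(fruit) == 0) {
    fate_abort("run_fate_pipeline needs at least one batch with a fruit profile.",
               "input_error")
  }
  preds <- purrr::map(seq_len(nrow(fruit)), function(i) {
    row <- fruit[i, ]
    ole <- row$conc_ole_glu
    if (is.na(ole)) {
      fate_abort(sprintf("Batch `%s` has no fruit ole_glu measurement.",
                         row$batch_id), "input_error")
    }
    w <- water_fraction(row$humidity, row$added_water)
    if (ole == 0) {
      crushed <- c(htyr_sec = 0, tyr_sec = 0)
      kneaded <- c(htyr_sec = 0, tyr_sec = 0)
      oil <- c(htyr_sec = 0, tyr_sec = 0)
    } else {
      mi <- row$milling_intensity
      if (is.na(mi)) {
        meas_crushed <- tbl[tbl$batch_id == row$batch_id &
                              tbl$stage == "crushed", ]
        if (nrow(meas_crushed) == 1 && !is.na(meas_crushed$conc_tyr_sec)) {
          mi <- milling_intensity(ole, meas_crushed$conc_tyr_sec)
        } else {
          fate_abort(sprintf(
            "Batch `%s` has neither a recorded milling intensity nor a measured crushed TyrSec to compute one.",
            row$batch_id), "config_error")
        }
      }
      crushed <- c(
        htyr_sec = unname(predict_crushed_htyrsec(
          get_crushing(models, row$variety), mi)),
        tyr_sec = mi / 100 * ole
      )
      kneaded <- c(
        htyr_sec = predict_kneaded(
          get_malaxation(models, row$variety, "htyr_sec"), crushed[["htyr_sec"]]),
        tyr_sec = predict_kneaded(
          get_malaxation(models, row$variety, "tyr_sec"), crushed[["tyr_sec"]])
      )
      oil <- c(
        htyr_sec = predict_oil(get_partition(models, "htyr_sec"),
                               kneaded[["htyr_sec"]], w),
        tyr_sec = predict_oil(get_partition(models, "tyr_sec"),
                              kneaded[["tyr_sec"]], w)
      )
    }
    out <- row[rep(1L, 3L), ]
    out$stage <- c("crushed", "kneaded", "oil")
    out$conc_ole_glu <- c(NA_real_, NA_real_, 0)
    out$conc_htyr_sec <- c(crushed[["htyr_sec"]], kneaded[["htyr_sec"]],
                           oil[["htyr_sec"]])
    out$conc_tyr_sec <- c(crushed[["tyr_sec"]], kneaded[["tyr_sec"]],
                          oil[["tyr_sec"]])
    out
  })
  measured <- tbl
  measured$source <- "measured"
  predicted <- dplyr::bind_rows(preds)
  predicted$source <- "predicted"
  dplyr::bind_rows(measured, predicted) |>
    dplyr::arrange(.data$batch_id, match(.data$stage, STAGES), .data$source)
}
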