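# Oil transfer: water-phase partition-coefficient model.
#
# All polar phenolics are assumed solubilised in the paste's water phase
# (fraction w of the paste mass), so the water-phase concentration is
# C_paste / w and the oil concentration is governed only by the partition
# coefficient K = C_oil / C_water, i.e. C_oil = K * C_paste / w.

new_partition_model <- function(family, K, n, per_sample_K) {
  structure(list(family = family, K = K, n = n, per_sample_K = per_sample_K),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("<partition_model %s: K = %.4g (mean of %d sample ratios)>\n",
              x$family, x$K, x$n))
  invisible(x)
}

#' Estimate the oil-water partition coefficient of a family
#'
#' For every batch with both kneaded-paste and oil measurements, the
#' per-sample coefficient is `K_i = C_oil_i * w_i / C_kneaded_i`, where `w_i`
#' is the batch's water fraction ([water_fraction()]). The family coefficient
#' is the arithmetic mean of the per-sample ratios (pooled over whatever
#' varieties are in `records`); the regression-style diagnostic of predicted
#' vs measured transfer is provided separately by [validate_prediction()].
#'
#' Pairs with zero kneaded concentration carry no partition information and
#' are skipped with a warning.
#'
#' @param records A batch table.
#' @param family `"htyr_sec"`, `"tyr_sec"`, or `"total"` (the total is
#'   calibrated as its own family: its coefficient is not the
#'   concentration-weighted mean of the component coefficients).
#' @return A `partition_model` with `family`, `K` (dimensionless), `n` and
#'   `per_sample_K`.
#' @export
estimate_partition <- function(records, family = "htyr_sec") {
  tbl <- validate_batch_table(records)
  pairs <- stage_pairs(tbl, "kneaded", "oil", family)
  if (nrow(pairs) == 0) {
    fate_abort(sprintf(
      "estimate_partition needs >= 1 batch with kneaded and oil `%s` measurements.",
      family), "insufficient_data_error")
  }
  zero <- pairs$x <= 0
  if (any(zero)) {
    warn(sprintf("Skipping %d pair(s) with zero kneaded concentration (no partition information).",
                 sum(zero)))
    pairs <- pairs[!zero, ]
  }
  if (nrow(pairs) == 0) {
    fate_abort("No usable kneaded-oil pairs with positive kneaded concentration.",
               "insufficient_data_error")
  }
  w <- water_fraction(pairs$humidity, pairs$added_water)
  per_sample <- pairs$y * w / pairs$x
  K <- mean(per_sample)
  fate_log("estimate_partition[%s]: n=%d K=%.4g (sd %.3g)",
           family, length(per_sample), K, stats::sd(per_sample))
  new_partition_model(family, K, length(per_sample),
                      setNames(per_sample, pairs$batch_id))
}

#' Predict the oil concentration from the kneaded paste
#'
#' `C_oil = K * C_kneaded / w`: the phenolics concentrate in the water phase
#' (`C_kneaded / w`) and transfer to the oil in proportion to the partition
#' coefficient. Strictly increasing in `C_kneaded` and strictly decreasing in
#' `w` for fixed `K`.
#'
#' @param model A `partition_model` from [estimate_partition()], or a bare
#'   numeric coefficient `K > 0`.
#' @param kneaded_conc Kneaded-paste concentration(s), mg/kg, `>= 0`.
#' @param w Water fraction(s) of the paste, in `(0, 1)`.
#' @return Predicted oil concentration(s), mg/kg.
#' @examples
#' predict_oil(0.047, kneaded_conc = 3500, w = 0.35)  # 470 mg/kg
#' @export
predict_oil <- function(model, kneaded_conc, w) {
  K <- if (inherits(model, "partition_model")) model$K else model
  if (!is.numeric(K) || any(is.na(K)) || any(K <= 0)) {
    fate_abort("Partition coefficient K must be positive.", "domain_error")
  }
  if (any(is.na(w)) || any(w <= 0) || any(w >= 1)) {
    fate_abort("Water fraction `w` must lie in (0, 1).", "domain_error")
  }
  if (any(is.na(kneaded_conc)) || any(kneaded_conc < 0)) {
    fate_abort("`kneaded_conc` must be non-negative.", "precondition_error")
  }
  K * kneaded_conc / w
}

#' Model-adequacy regression of measured on predicted values
#'
#' Through-origin fit of measured concentrations (y) on predicted
#' concentrations (x). A slope near 1 with high r-squared indicates an
#' adequate transfer model; it is the standard diagnostic for the partition
#' prediction.
#'
#' @param predicted,measured Equal-length, non-empty numeric vectors.
#' @return A `fate_fit` (see [fit_through_origin()]).
#' @export
validate_prediction <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) == 0) {
    fate_abort("`predicted` and `measured` must have equal nonzero length.",
               "input_error")
  }
  fit <- fit_through_origin(predicted, measured)
  fate_log("validate_prediction: n=%d slope=%.4g r2=%.3f",
           fit$n, fit$slope, fit$r2)
  fit
}
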