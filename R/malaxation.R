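# Malaxation stage: linear transfer of each family from crushed to kneaded
# paste, fitted through the origin (no phenolics in, none out).

new_malaxation_model <- function(variety, family, slope, r2, n) {
  structure(list(variety = variety, family = family, slope = slope,
                 r2 = r2, n = n),
            class = "malaxation_model")
}

#' @export
print.malaxation_model <- function(x, ...) {
  cat(sprintf("<malaxation_model %s/%s: kneaded = %.4g * crushed (r2 %.3f, n %d)>\n",
              x$variety, x$family, x$slope, x$r2, x$n))
  invisible(x)
}

#' Calibrate the malaxation transfer for one family
#'
#' Fits kneaded-paste concentration against crushed-paste concentration of a
#' phenolic family through the origin (see [fit_through_origin()]): a batch
#' with no phenolics after crushing cannot gain any during kneading. The
#' tyrosol family behaves homogeneously across cultivars (its slope is
#' usually fitted pooled), whereas the hydroxytyrosol family — more sensitive
#' to oxidative enzymes via its ortho-diphenolic structure — shows strongly
#' cultivar-dependent slopes and should be fitted per variety.
#'
#' @param records A batch table.
#' @param variety Cultivar to fit, or `NULL` to pool all varieties.
#' @param family One of `"htyr_sec"`, `"tyr_sec"`, `"ole_glu"`, `"total"`.
#' @return A `malaxation_model` with `variety` (or `"pooled"`), `family`,
#'   dimensionless `slope` (kneaded/crushed), `r2` and `n`.
#' @export
fit_malaxation <- function(records, variety = NULL, family = "htyr_sec") {
  tbl <- validate_batch_table(records)
  label <- if (is.null(variety)) "pooled" else variety
  if (!is.null(variety)) tbl <- tbl[tbl$variety == variety, ]
  pairs <- stage_pairs(tbl, "crushed", "kneaded", family)
  if (nrow(pairs) < 1) {
    fate_abort(sprintf(
      "fit_malaxation needs >= 1 batch (%s) with crushed and kneaded `%s` measurements.",
      label, family), "insufficient_data_error")
  }
  fit <- fit_through_origin(pairs$x, pairs$y)
  fate_log("fit_malaxation[%s/%s]: n=%d slope=%.4g r2=%.3f",
           label, family, fit$n, fit$slope, fit$r2)
  new_malaxation_model(label, family, fit$slope, fit$r2, fit$n)
}

#' Predict kneaded-paste concentration from crushed-paste concentration
#'
#' @param model A `malaxation_model` from [fit_malaxation()].
#' @param crushed_conc Crushed-paste concentration(s), mg/kg, `>= 0`.
#' @return Predicted kneaded-paste concentration(s), mg/kg.
#' @export
predict_kneaded <- function(model, crushed_conc) {
  stopifnot(inherits(model, "malaxation_model"))
  if (any(is.na(crushed_conc)) || any(crushed_conc < 0)) {
    fate_abort("`crushed_conc` must be non-negative.", "precondition_error")
  }
  model$slope * crushed_conc
}
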