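# Crushing stage: the milling-intensity scale and the per-cultivar
# HtyrSec-formation regression.

family_col <- function(family) {
  if (!family %in% c(FAMILIES, "total")) {
    fate_abort(sprintf("Unknown phenolic family `%s`.", family),
               "config_error")
  }
  paste0("conc_", family)
}

# One row per batch with the concentrations of `family` at two stages.
stage_pairs <- function(tbl, stage_x, stage_y, family) {
  tbl <- validate_batch_table(tbl)
  if (family == "total") tbl <- with_total(tbl)
  col <- family_col(family)
  wide <- tbl |>
    dplyr::filter(.data$stage %in% c(stage_x, stage_y)) |>
    dplyr::select(dplyr::all_of(c("batch_id", "variety", "stage", "humidity",
                                  "added_water", col))) |>
    tidyr::pivot_wider(names_from = "stage", values_from = dplyr::all_of(col))
  for (s in c(stage_x, stage_y)) if (!s %in% names(wide)) wide[[s]] <- NA_real_
  wide$x <- wide[[stage_x]]
  wide$y <- wide[[stage_y]]
  wide[!is.na(wide$x) & !is.na(wide$y), ]
}

#' Milling intensity of a crushing operation
#'
#' The intensity of milling is scored as the percentage yield of the
#' transformation of the glucosidic precursors (oleuropein +
#' demethyl-oleuropein, measured in the fruit) into the tyrosol secoiridoids
#' (measured in the crushed paste). TyrSec anchors the scale because it is
#' the more stable of the two secoiridoid families.
#'
#' On the default mass basis the yield is `100 * TyrSec_crushed /
#' OleGlu_fruit` (both mg/kg). On the molar basis both terms are first
#' converted to moles using user-supplied molar masses for the (pooled)
#' families, keyed `"ole_glu"` and `"tyr_sec"` in `mw_table`.
#'
#' @param fruit A [phenolic_profile()] at stage `"fruit"`, or the fruit
#'   ole_glu concentration (mg/kg).
#' @param crushed A [phenolic_profile()] at stage `"crushed"`, or the crushed
#'   tyr_sec concentration (mg/kg).
#' @param basis `"mass"` (default) or `"molar"`.
#' @param mw_table Named numeric vector of molar masses (g/mol) with entries
#'   `ole_glu` and `tyr_sec`; required when `basis = "molar"`.
#' @return The milling intensity in percent (may exceed 100, with a warning).
#' @examples
#' milling_intensity(7740, 908)  # ~11.73 %
#' @export
milling_intensity <- function(fruit, crushed, basis = c("mass", "molar"),
                              mw_table = NULL) {
  basis <- match.arg(basis)
  ole <- if (inherits(fruit, "phenolic_profile")) {
    profile_conc(fruit, "ole_glu")
  } else {
    fruit
  }
  tyr <- if (inherits(crushed, "phenolic_profile")) {
    profile_conc(crushed, "tyr_sec")
  } else {
    crushed
  }
  if (is.na(ole) || ole <= 0) {
    fate_abort("Fruit ole_glu concentration must be positive to define milling intensity.",
               "precondition_error")
  }
  if (is.na(tyr) || tyr < 0) {
    fate_abort("Crushed tyr_sec concentration must be non-negative.",
               "precondition_error")
  }
  if (basis == "molar") {
    needed <- c("ole_glu", "tyr_sec")
    if (is.null(mw_table) || !all(needed %in% names(mw_table)) ||
        any(mw_table[needed] <= 0)) {
      fate_abort("Molar basis needs positive molar masses for `ole_glu` and `tyr_sec` in `mw_table`.",
                 "config_error")
    }
    ole <- ole / mw_table[["ole_glu"]]
    tyr <- tyr / mw_table[["tyr_sec"]]
  }
  mi <- 100 * tyr / ole
  if (mi > 100) {
    warn(sprintf("Milling intensity %.1f%% exceeds 100%%: apparent transformation yield above complete conversion.",
                 mi))
  }
  mi
}

new_crushing_model <- function(variety, slope, intercept, r2, n) {
  structure(list(variety = variety, slope = slope, intercept = intercept,
                 r2 = r2, n = n),
            class = "crushing_model")
}

#' @export
print.crushing_model <- function(x, ...) {
  cat(sprintf("<crushing_model %s: HtyrSec = %.4g * MI%% + %.4g (r2 %.3f, n %d)>\n",
              x$variety, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Calibrate the crushing model for one cultivar
#'
#' Regresses crushed-paste HtyrSec concentration (mg/kg) on milling intensity
#' (%) by ordinary least squares, over the batches of one variety that carry
#' both fruit and crushed profiles. The slope is cultivar-specific: the
#' transformation rate depends on the variety's enzyme levels, not simply on
#' its precursor pool.
#'
#' Milling intensity per batch is taken from the recorded `milling_intensity`
#' column when present (the design variable of the crushing experiment), and
#' otherwise computed from the measured profiles via [milling_intensity()].
#'
#' @param records A batch table (see [as_batch_table()]).
#' @param variety Cultivar to fit.
#' @param mi_source `"auto"` (recorded when available, else computed),
#'   `"recorded"`, or `"computed"`.
#' @return A `crushing_model` with `variety`, `slope` (mg/kg per % MI),
#'   `intercept` (mg/kg), `r2` and `n`.
#' @export
fit_crushing <- function(records, variety,
                         mi_source = c("auto", "recorded", "computed")) {
  mi_source <- match.arg(mi_source)
  tbl <- validate_batch_table(records)
  tbl <- tbl[tbl$variety == variety, ]
  pairs <- stage_pairs(tbl, "fruit", "crushed", "ole_glu")
  # fruit ole_glu (x) and crushed htyr_sec / tyr_sec per batch
  crushed <- tbl[tbl$stage == "crushed",
                 c("batch_id", "conc_htyr_sec", "conc_tyr_sec")]
  dat <- dplyr::inner_join(
    pairs[, c("batch_id", "x")], crushed, by = "batch_id"
  )
  has_recorded <- "milling_intensity" %in% names(tbl)
  if (has_recorded) {
    rec <- unique(tbl[, c("batch_id", "milling_intensity")])
    dat <- dplyr::left_join(dat, rec, by = "batch_id")
  } else {
    dat$milling_intensity <- NA_real_
  }
  dat$mi_computed <- ifelse(
    dat$x > 0 & !is.na(dat$conc_tyr_sec),
    100 * dat$conc_tyr_sec / dat$x, NA_real_
  )
  dat$mi <- switch(
    mi_source,
    recorded = dat$milling_intensity,
    computed = dat$mi_computed,
    auto = ifelse(is.na(dat$milling_intensity), dat$mi_computed,
                  dat$milling_intensity)
  )
  dat <- dat[!is.na(dat$mi) & !is.na(dat$conc_htyr_sec), ]
  if (nrow(dat) < 2) {
    fate_abort(sprintf(
      "fit_crushing needs >= 2 batches of variety `%s` with fruit and crushed profiles (got %d).",
      variety, nrow(dat)), "insufficient_data_error")
  }
  fit <- fit_linear(dat$mi, dat$conc_htyr_sec)
  fate_log("fit_crushing[%s]: n=%d slope=%.4g intercept=%.4g r2=%.3f",
           variety, fit$n, fit$slope, fit$intercept, fit$r2)
  new_crushing_model(variety, fit$slope, fit$intercept, fit$r2, fit$n)
}

#' Predict crushed-paste HtyrSec from milling intensity
#'
#' Applies a calibrated [fit_crushing()] model: `slope * mi + intercept`.
#' Negative predictions (possible with a negative fitted intercept at very
#' low intensity) are floored at 0 with a warning.
#'
#' @param model A `crushing_model`.
#' @param mi Milling intensity in percent (vectorised, all `>= 0`).
#' @return Predicted HtyrSec concentration(s) in mg/kg.
#' @export
predict_crushed_htyrsec <- function(model, mi) {
  stopifnot(inherits(model, "crushing_model"))
  if (any(is.na(mi)) || any(mi < 0)) {
    fate_abort("`mi` must be non-negative.", "precondition_error")
  }
  pred <- model$slope * mi + model$intercept
  if (any(pred < 0)) {
    warn("Negative predicted concentration floored at 0 mg/kg.")
    pred <- pmax(pred, 0)
  }
  pred
}
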