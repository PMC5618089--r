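# Batch records and the tidy batch table (one row per batch x stage).

BATCH_COLUMNS <- c(
  "batch_id", "variety", "stage", "humidity", "added_water",
  "mill_type", "rpm", "grid_mm",
  "conc_ole_glu", "conc_htyr_sec", "conc_tyr_sec"
)

#' Construct a batch record
#'
#' A batch record bundles one olive batch's processing metadata (variety,
#' fruit humidity, water added during malaxation, crushing conditions) with
#' its phenolic profiles at the stages measured so far. Stages must form a
#' prefix of the process order `fruit -> crushed -> kneaded -> oil` (no gaps:
#' a batch cannot have an oil profile without a kneaded one).
#'
#' @param batch_id Batch identifier.
#' @param variety Cultivar identifier (e.g. `"cornicabra"`, `"arbequina"`).
#' @param humidity Water mass fraction of the fruit/paste, in `[0, 1)`.
#' @param added_water Water mass fraction added during malaxation, in
#'   `[0, 1)`. `humidity + added_water` must be `< 1`.
#' @param mill_type,rpm,grid_mm Crushing condition metadata (`"hammer"` or
#'   `"blade"`; rotor speed in rpm; grid hole diameter in mm). `NA` allowed.
#' @param milling_intensity Optional recorded milling intensity (%), the
#'   design variable of the crushing scale (see [milling_intensity()]).
#' @param profiles Named list of [phenolic_profile()]s keyed by stage.
#' @return An object of class `batch_record`.
#' @examples
#' batch_record("b1", "cornicabra", humidity = 0.35,
#'              profiles = list(fruit = phenolic_profile("fruit", ole_glu = 7740)))
#' @export
batch_record <- function(batch_id, variety, humidity, added_water = 0,
                         mill_type = NA_character_, rpm = NA_real_,
                         grid_mm = NA_real_, milling_intensity = NA_real_,
                         profiles = list()) {
  humidity <- check_number(humidity, "humidity", min = 0, max = 1)
  added_water <- check_number(added_water, "added_water", min = 0, max = 1)
  if (humidity + added_water >= 1) {
    fate_abort("humidity + added_water must be < 1.", "domain_error")
  }
  if (!is.na(mill_type) && !mill_type %in% c("hammer", "blade")) {
    fate_abort("`mill_type` must be \"hammer\", \"blade\" or NA.", "input_error")
  }
  if (length(profiles)) {
    if (is.null(names(profiles)) ||
        !all(vapply(profiles, inherits, logical(1), "phenolic_profile"))) {
      fate_abort("`profiles` must be a named list of phenolic_profile objects.",
                 "input_error")
    }
    bad <- names(profiles)[vapply(
      names(profiles), function(s) !identical(profiles[[s]]$stage, s), logical(1)
    )]
    if (length(bad)) {
      fate_abort(sprintf("Profile stage mismatch for: %s.",
                         paste(bad, collapse = ", ")), "input_error")
    }
    present <- STAGES %in% names(profiles)
    k <- sum(present)
    if (!identical(which(present), seq_len(k))) {
      fate_abort(
        "Stages present must form a prefix of fruit -> crushed -> kneaded -> oil (no gaps).",
        "input_error"
      )
    }
    profiles <- profiles[STAGES[seq_len(k)]]
  }
  structure(
    list(
      batch_id = as.character(batch_id), variety = as.character(variety),
      humidity = humidity, added_water = added_water,
      mill_type = mill_type, rpm = rpm, grid_mm = grid_mm,
      milling_intensity = check_number(milling_intensity, "milling_intensity",
                                       min = 0, allow_na = TRUE),
      profiles = profiles
    ),
    class = "batch_record"
  )
}

#' @export
print.batch_record <- function(x, ...) {
  cat(sprintf("<batch_record %s: %s, humidity %.2f, stages: %s>\n",
              x$batch_id, x$variety, x$humidity,
              paste(names(x$profiles), collapse = " -> ")))
  invisible(x)
}

#' Convert between batch records and the tidy batch table
#'
#' The tidy batch table is the package's canonical tabular form (and its CSV
#' schema): one row per batch x stage, with columns `batch_id`, `variety`,
#' `stage`, `humidity`, `added_water`, `mill_type`, `rpm`, `grid_mm`,
#' `conc_ole_glu`, `conc_htyr_sec`, `conc_tyr_sec` (mg/kg, `NA` = not
#' measured) and, optionally, `milling_intensity` (%).
#'
#' @param records A list of [batch_record()]s (`as_batch_table`) or a batch
#'   table (`as_batch_records`).
#' @return A tibble, or a list of `batch_record`s.
#' @export
as_batch_table <- function(records) {
  if (inherits(records, "batch_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "batch_record")))
  rows <- purrr::map(records, function(r) {
    stages <- names(r$profiles)
    if (!length(stages)) return(NULL)
    tibble::tibble(
      batch_id = r$batch_id, variety = r$variety, stage = stages,
      humidity = r$humidity, added_water = r$added_water,
      mill_type = r$mill_type, rpm = r$rpm, grid_mm = r$grid_mm,
      milling_intensity = r$milling_intensity,
      conc_ole_glu = vapply(r$profiles, function(p)
        p$concentrations[["ole_glu"]], numeric(1), USE.NAMES = FALSE),
      conc_htyr_sec = vapply(r$profiles, function(p)
        p$concentrations[["htyr_sec"]], numeric(1), USE.NAMES = FALSE),
      conc_tyr_sec = vapply(r$profiles, function(p)
        p$concentrations[["tyr_sec"]], numeric(1), USE.NAMES = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname as_batch_table
#' @param tbl A batch table.
#' @export
as_batch_records <- function(tbl) {
  tbl <- validate_batch_table(tbl)
  split_rows <- split(tbl, tbl$batch_id)
  purrr::map(split_rows, function(rows) {
    rows <- rows[match(STAGES, rows$stage, nomatch = 0L), ]
    profiles <- purrr::pmap(
      list(rows$stage, rows$conc_ole_glu, rows$conc_htyr_sec, rows$conc_tyr_sec),
      function(s, o, h, t) phenolic_profile(s, o, h, t)
    )
    names(profiles) <- rows$stage
    batch_record(
      rows$batch_id[[1]], rows$variety[[1]], rows$humidity[[1]],
      rows$added_water[[1]], rows$mill_type[[1]], rows$rpm[[1]],
      rows$grid_mm[[1]],
      milling_intensity = if ("milling_intensity" %in% names(rows))
        rows$milling_intensity[[1]] else NA_real_,
      profiles = profiles
    )
  })
}

#' Validate a batch table
#'
#' Checks the canonical schema: required columns present, stages recognised,
#' concentrations non-negative, humidity and added water fractions valid, and
#' no duplicated batch x stage row. Returns the table (as a tibble, with
#' `added_water` defaulting to 0 when absent) or fails with row/column
#' diagnostics.
#'
#' @param tbl A data frame in the batch-table schema.
#' @return The validated tibble, invisibly usable in pipelines.
#' @export
validate_batch_table <- function(tbl) {
  if (!is.data.frame(tbl)) {
    fate_abort("Batch data must be a data frame.", "input_error")
  }
  tbl <- tibble::as_tibble(tbl)
  if (!"added_water" %in% names(tbl)) tbl$added_water <- 0
  tbl$added_water[is.na(tbl$added_water)] <- 0
  for (col in c("mill_type")) if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  for (col in c("rpm", "grid_mm")) if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  missing_cols <- setdiff(BATCH_COLUMNS, names(tbl))
  if (length(missing_cols)) {
    fate_abort(sprintf("Batch table is missing column(s): %s.",
                       paste(missing_cols, collapse = ", ")),
               "input_error")
  }
  bad_stage <- which(!tbl$stage %in% STAGES)
  if (length(bad_stage)) {
    fate_abort(sprintf("Unknown stage %s in row(s) %s (column `stage`).",
                       paste(unique(tbl$stage[bad_stage]), collapse = ", "),
                       paste(head(bad_stage, 5), collapse = ", ")),
               "input_error")
  }
  for (col in c("conc_ole_glu", "conc_htyr_sec", "conc_tyr_sec")) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] < 0)
    if (length(bad)) {
      fate_abort(sprintf("Negative concentration in column `%s`, row(s) %s.",
                         col, paste(head(bad, 5), collapse = ", ")),
                 "input_error")
    }
  }
  bad_w <- which(is.na(tbl$humidity) | tbl$humidity < 0 |
                   tbl$humidity + tbl$added_water >= 1)
  if (length(bad_w)) {
    fate_abort(sprintf(
      "Invalid humidity/added_water (need 0 <= humidity and humidity + added_water < 1) in row(s) %s.",
      paste(head(bad_w, 5), collapse = ", ")), "input_error")
  }
  dup <- duplicated(tbl[c("batch_id", "stage")])
  if (any(dup)) {
    fate_abort(sprintf("Duplicated batch x stage row(s): %s.",
                       paste(head(which(dup), 5), collapse = ", ")),
               "input_error")
  }
  tbl
}

#' Add a recomputed total-phenolics column
#'
#' Appends `conc_total`, the arithmetic sum of the family concentrations
#' present in each row (`NA` only when every family is unmeasured). The total
#' is always derived, never stored.
#'
#' @param tbl A batch table.
#' @return The table with a `conc_total` column.
#' @export
with_total <- function(tbl) {
  conc <- as.matrix(tbl[c("conc_ole_glu", "conc_htyr_sec", "conc_tyr_sec")])
  total <- rowSums(conc, na.rm = TRUE)
  total[rowSums(!is.na(conc)) == 0] <- NA_real_
  tbl$conc_total <- total
  tbl
}

#' Water fraction of an olive paste
#'
#' The water phase of the paste — assumed to hold all polar phenolics — is
#' the fruit humidity plus any water added to the malaxer, as mass fractions
#' of the paste. The partition model divides by this fraction
#' (see [predict_oil()]).
#'
#' @param x A [batch_record()], a data frame with `humidity` and
#'   `added_water` columns (vectorised over rows), or a numeric humidity.
#' @param added_water Water added during malaxation (mass fraction), used
#'   when `x` is numeric. Default 0.
#' @param ... Unused.
#' @return Numeric water fraction(s) in `(0, 1)`.
#' @examples
#' water_fraction(0.35)            # Cornicabra paste, no added water
#' water_fraction(0.50)            # Arbequina
#' water_fraction(0.4, 0.1)
#' @export
water_fraction <- function(x, ...) UseMethod("water_fraction")

#' @rdname water_fraction
#' @export
water_fraction.numeric <- function(x, added_water = 0, ...) {
  w <- x + added_water
  if (any(is.na(w)) || any(w <= 0) || any(w >= 1)) {
    fate_abort("Water fraction (humidity + added_water) must lie in (0, 1).",
               "domain_error")
  }
  w
}

#' @rdname water_fraction
#' @export
water_fraction.batch_record <- function(x, ...) {
  water_fraction(x$humidity, x$added_water)
}

#' @rdname water_fraction
#' @export
water_fraction.data.frame <- function(x, ...) {
  aw <- if ("added_water" %in% names(x)) x$added_water else 0
  water_fraction(x$humidity, aw)
}
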