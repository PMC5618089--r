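# Internal-standard HPLC quantification: peak areas -> concentrations.

#' Construct a peak table
#'
#' A peak table holds what is needed to quantify one sample by the
#' internal-standard (IS) method: the sample mass, the known mass of IS
#' spiked into it, the detector areas of the IS and of each analyte, and the
#' analytes' response factors (RF) relative to the IS. Concentration follows
#' from proportionality of area to amount:
#' `conc_c (mg/kg) = (area_c / is_area) * is_mass_mg * RF_c / (sample_mass_g / 1000)`.
#'
#' @param sample_id Sample identifier.
#' @param matrix `"paste_or_fruit"` (4-hydroxyphenylacetic acid protocol) or
#'   `"oil"` (syringic acid protocol).
#' @param sample_mass Sample mass in g, `> 0`.
#' @param is_mass Internal-standard mass added, in mg, `> 0`.
#' @param is_area Internal-standard peak area, `> 0`.
#' @param analyte_areas Named numeric vector of peak areas (`>= 0`), keyed by
#'   compound (see [compound_families()]).
#' @param response_factors Named numeric vector of RFs (`> 0`). Compounds
#'   with nonzero area and no RF are a configuration error at
#'   [quantify()] time; if omitted entirely, RF = 1 is assumed for all
#'   compounds with a warning (RFs are literature values the user should
#'   supply).
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(sample_id, matrix = c("paste_or_fruit", "oil"),
                       sample_mass, is_mass, is_area, analyte_areas,
                       response_factors = NULL) {
  matrix <- match.arg(matrix)
  sample_mass <- check_number(sample_mass, "sample_mass", min = 0)
  is_mass <- check_number(is_mass, "is_mass", min = 0)
  is_area <- check_number(is_area, "is_area", min = 0)
  if (sample_mass <= 0 || is_mass <= 0 || is_area <= 0) {
    fate_abort("sample_mass, is_mass and is_area must all be positive.",
               "input_error")
  }
  if (!is.numeric(analyte_areas) || is.null(names(analyte_areas)) ||
      any(names(analyte_areas) == "")) {
    fate_abort("`analyte_areas` must be a named numeric vector.", "input_error")
  }
  if (any(is.na(analyte_areas)) || any(analyte_areas < 0)) {
    fate_abort("Analyte areas must be non-negative.", "input_error")
  }
  unknown <- setdiff(names(analyte_areas), names(COMPOUND_FAMILIES))
  if (length(unknown)) {
    fate_abort(sprintf("Unknown compound(s): %s (see compound_families()).",
                       paste(unknown, collapse = ", ")), "config_error")
  }
  if (is.null(response_factors)) {
    warn("No response factors supplied; assuming RF = 1 for all compounds.")
    response_factors <- setNames(rep(1, length(analyte_areas)),
                                 names(analyte_areas))
  }
  if (any(is.na(response_factors)) || any(response_factors <= 0)) {
    fate_abort("Response factors must be positive.", "input_error")
  }
  structure(
    list(sample_id = as.character(sample_id), matrix = matrix,
         sample_mass = sample_mass, is_mass = is_mass, is_area = is_area,
         analyte_areas = analyte_areas, response_factors = response_factors),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table %s (%s): %.3g g sample, %.3g mg IS, %d analyte(s)>\n",
              x$sample_id, x$matrix, x$sample_mass, x$is_mass,
              length(x$analyte_areas)))
  invisible(x)
}

#' Quantify a peak table into a phenolic profile
#'
#' Converts each analyte area to mg/kg by the internal-standard formula (see
#' [peak_table()]) and sums compounds into their phenolic families.
#' Quantification is linear in each area and inversely proportional to
#' sample mass.
#'
#' @param table A [peak_table()].
#' @param stage Process stage of the resulting profile; defaults to
#'   `"crushed"` for the paste/fruit matrix and `"oil"` for the oil matrix.
#' @return A [phenolic_profile()].
#' @examples
#' pt <- peak_table("s1", "paste_or_fruit", sample_mass = 4.0, is_mass = 2.0,
#'                  is_area = 1e5, analyte_areas = c(dhpea_eda = 1e5),
#'                  response_factors = c(dhpea_eda = 1))
#' quantify(pt)  # 500 mg/kg HtyrSec
#' @export
quantify <- function(table, stage = NULL) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(stage)) {
    stage <- if (table$matrix == "oil") "oil" else "crushed"
  }
  areas <- table$analyte_areas
  need_rf <- names(areas)[areas > 0]
  missing_rf <- setdiff(need_rf, names(table$response_factors))
  if (length(missing_rf)) {
    fate_abort(sprintf("Missing response factor(s) for: %s.",
                       paste(missing_rf, collapse = ", ")), "config_error")
  }
  rf <- table$response_factors[names(areas)]
  rf[is.na(rf)] <- 1  # zero-area compounds contribute nothing regardless
  conc <- (areas / table$is_area) * table$is_mass * rf /
    (table$sample_mass / 1000)
  fam <- COMPOUND_FAMILIES[names(areas)]
  if (stage == "oil" && any(conc[fam == "ole_glu"] > 0)) {
    warn("Nonzero glucosidic precursor area in an oil sample; excluded (oleuropein is not soluble in the oily phase).")
    conc[fam == "ole_glu"] <- 0
  }
  by_family <- tapply(conc, fam, sum)
  get <- function(f) if (f %in% names(by_family)) unname(by_family[[f]]) else 0
  phenolic_profile(stage, ole_glu = get("ole_glu"),
                   htyr_sec = get("htyr_sec"), tyr_sec = get("tyr_sec"))
}

#' Peak-table template for a standard protocol
#'
#' Pre-fills the sample and internal-standard masses of the two extraction
#' protocols. Paste/fruit: 4.0 g of sample spiked with 2.0 mg of
#' 4-hydroxyphenylacetic acid. Oil: 2.5 g of oil spiked with 250 uL of a
#' 15 mg/kg syringic acid solution in methanol; the IS mass then depends on
#' how the solution strength is read. Under the default mass-per-mass
#' reading, `is_mass = volume * density * conc / 1000` (about 2.97 ug with
#' methanol density 0.792 g/mL); under a mass-per-volume (`"mg_per_L"`)
#' reading, `is_mass = volume * conc / 1000` (3.75 ug). Both readings are
#' supported because published protocols are often ambiguous on this point.
#'
#' @param matrix `"paste_or_fruit"` or `"oil"`.
#' @param is_units For the oil protocol: `"mg_per_kg"` (default) or
#'   `"mg_per_L"`.
#' @param is_volume_ml IS solution volume in mL (oil protocol, default 0.250).
#' @param is_conc IS solution strength (15, in the units of `is_units`).
#' @param methanol_density Solvent density in g/mL (default 0.792), used for
#'   the mass-per-mass reading.
#' @return A list with `matrix`, `sample_mass` (g) and `is_mass` (mg), to be
#'   completed with areas via [peak_table()].
#' @export
default_protocol <- function(matrix = c("paste_or_fruit", "oil"),
                             is_units = c("mg_per_kg", "mg_per_L"),
                             is_volume_ml = 0.250, is_conc = 15,
                             methanol_density = 0.792) {
  matrix <- match.arg(matrix)
  is_units <- match.arg(is_units)
  if (matrix == "paste_or_fruit") {
    return(list(matrix = matrix, sample_mass = 4.0, is_mass = 2.0))
  }
  is_mass <- if (is_units == "mg_per_kg") {
    is_volume_ml * methanol_density * is_conc / 1000
  } else {
    is_volume_ml * is_conc / 1000
  }
  list(matrix = matrix, sample_mass = 2.5, is_mass = is_mass)
}

#' Build a synthetic peak table from a known profile
#'
#' Inverts the internal-standard formula so that [quantify()] recovers the
#' given profile exactly — the round-trip used to verify the quantification
#' arithmetic. Each family's concentration is split evenly across that
#' family's compounds.
#'
#' @param profile A [phenolic_profile()] (`NA` families are omitted).
#' @param sample_id Sample identifier for the table.
#' @param matrix,sample_mass,is_mass Protocol fields; default from
#'   [default_protocol()] chosen by the profile's stage.
#' @param is_area IS peak area (default 1e5).
#' @param response_factors Named RFs; default 1 for every compound used.
#' @return A [peak_table()].
#' @export
synthetic_peak_table <- function(profile, sample_id = "synthetic",
                                 matrix = NULL, sample_mass = NULL,
                                 is_mass = NULL, is_area = 1e5,
                                 response_factors = NULL) {
  stopifnot(inherits(profile, "phenolic_profile"))
  if (is.null(matrix)) {
    matrix <- if (profile$stage == "oil") "oil" else "paste_or_fruit"
  }
  proto <- default_protocol(matrix)
  if (is.null(sample_mass)) sample_mass <- proto$sample_mass
  if (is.null(is_mass)) is_mass <- proto$is_mass
  conc <- profile$concentrations
  conc <- conc[!is.na(conc)]
  areas <- numeric(0)
  for (fam in names(conc)) {
    compounds <- names(COMPOUND_FAMILIES)[COMPOUND_FAMILIES == fam]
    if (matrix == "oil" && fam == "ole_glu") next
    share <- conc[[fam]] / length(compounds)
    areas[compounds] <- share
  }
  if (is.null(response_factors)) {
    response_factors <- setNames(rep(1, length(areas)), names(areas))
  }
  # invert conc = (area / is_area) * is_mass * rf / (mass/1000)
  areas <- areas * (sample_mass / 1000) * is_area /
    (is_mass * response_factors[names(areas)])
  peak_table(sample_id, matrix, sample_mass, is_mass, is_area,
             analyte_areas = areas, response_factors = response_factors)
}
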