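# Phenolic profiles: per-family concentrations at one process stage.

#' Construct a phenolic profile
#'
#' A phenolic profile holds the concentrations (mg per kg of the stage's
#' matrix, fresh weight) of the three phenolic families at one stage of the
#' oil-making process. Two chemical facts are enforced as invariants: the
#' secoiridoid families are absent in the intact fruit (they only form on
#' crushing), and the glucosidic precursors are absent in the oil (oleuropein
#' is not soluble in the oily phase).
#'
#' `NA` means "not measured" and is distinct from 0.
#'
#' @param stage One of `"fruit"`, `"crushed"`, `"kneaded"`, `"oil"`.
#' @param ole_glu,htyr_sec,tyr_sec Concentrations in mg/kg (`NA` = not
#'   measured). All must be non-negative.
#' @return An object of class `phenolic_profile`.
#' @examples
#' phenolic_profile("fruit", ole_glu = 7740)
#' phenolic_profile("crushed", ole_glu = 300, htyr_sec = 3500, tyr_sec = 908)
#' @export
phenolic_profile <- function(stage, ole_glu = NA_real_, htyr_sec = NA_real_,
                             tyr_sec = NA_real_) {
  if (!is.character(stage) || length(stage) != 1L || !stage %in% STAGES) {
    fate_abort(
      sprintf("`stage` must be one of %s.", paste(STAGES, collapse = ", ")),
      "input_error"
    )
  }
  conc <- c(
    ole_glu = check_number(ole_glu, "ole_glu", min = 0, allow_na = TRUE),
    htyr_sec = check_number(htyr_sec, "htyr_sec", min = 0, allow_na = TRUE),
    tyr_sec = check_number(tyr_sec, "tyr_sec", min = 0, allow_na = TRUE)
  )
  if (stage == "oil" && isTRUE(conc[["ole_glu"]] > 0)) {
    fate_abort(
      "ole_glu must be absent (0 or NA) in the oil: oleuropein is not soluble in the oily phase.",
      "domain_error"
    )
  }
  if (stage == "fruit" &&
      (isTRUE(conc[["htyr_sec"]] > 0) || isTRUE(conc[["tyr_sec"]] > 0))) {
    fate_abort(
      "Secoiridoid families must be absent (0 or NA) in the fruit: they are only formed upon crushing.",
      "domain_error"
    )
  }
  structure(list(stage = stage, concentrations = conc),
            class = "phenolic_profile")
}

#' @export
print.phenolic_profile <- function(x, ...) {
  cat(sprintf("<phenolic_profile: %s>\n", x$stage))
  conc <- c(x$concentrations, total = total_phenolics(x))
  for (fam in names(conc)) {
    cat(sprintf("  %-9s %s mg/kg\n", fam,
                ifelse(is.na(conc[[fam]]), "NA", format(conc[[fam]]))))
  }
  invisible(x)
}

#' Total polar phenolics of a profile
#'
#' The total is always recomputed as the arithmetic sum of the families
#' present (non-`NA`); it is never stored independently. All-`NA` profiles
#' give `NA`.
#'
#' @param profile A [phenolic_profile()].
#' @return A single number (mg/kg) or `NA`.
#' @export
total_phenolics <- function(profile) {
  stopifnot(inherits(profile, "phenolic_profile"))
  conc <- profile$concentrations
  if (all(is.na(conc))) return(NA_real_)
  sum(conc, na.rm = TRUE)
}

profile_conc <- function(profile, family) {
  stopifnot(inherits(profile, "phenolic_profile"))
  if (identical(family, "total")) return(total_phenolics(profile))
  profile$concentrations[[family]]
}
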