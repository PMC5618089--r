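# Shared vocabulary: phenolic families, process stages, error and log plumbing.

FAMILIES <- c("ole_glu", "htyr_sec", "tyr_sec")
STAGES <- c("fruit", "crushed", "kneaded", "oil")

# Compound -> family membership used by the quantification module.
# ole_glu pools oleuropein with its demethyl form; the secoiridoid families
# pool the dialdehydic (EDA) and aldehydic (EA) elenolic-acid forms.
COMPOUND_FAMILIES <- c(
  oleuropein           = "ole_glu",
  demethyl_oleuropein  = "ole_glu",
  dhpea_eda            = "htyr_sec",  # 3,4-DHPEA-EDA
  dhpea_ea             = "htyr_sec",  # 3,4-DHPEA-EA
  p_hpea_eda           = "tyr_sec",   # p-HPEA-EDA
  p_hpea_ea            = "tyr_sec"    # p-HPEA-EA
)

#' Phenolic families and process stages
#'
#' `phenolic_families()` returns the identifiers of the three quantified
#' phenolic families: `"ole_glu"` (oleuropein + demethyl-oleuropein, the
#' glucosidic precursors), `"htyr_sec"` (hydroxytyrosol secoiridoids:
#' 3,4-DHPEA-EDA + 3,4-DHPEA-EA) and `"tyr_sec"` (tyrosol secoiridoids:
#' p-HPEA-EDA + p-HPEA-EA). The `"total"` family is never stored: it is always
#' recomputed as the sum of the families present (see [with_total()]).
#'
#' `process_stages()` returns the ordered stages of the oil-making process:
#' `fruit -> crushed -> kneaded -> oil`.
#'
#' `compound_families()` returns the compound-to-family membership used when
#' summing quantified compounds into families.
#'
#' @return A character vector (`compound_families()`: a named character
#'   vector mapping compound identifier to family identifier).
#' @export
phenolic_families <- function() FAMILIES

#' @rdname phenolic_families
#' @export
process_stages <- function() STAGES

#' @rdname phenolic_families
#' @export
compound_families <- function() COMPOUND_FAMILIES

# Conditions -------------------------------------------------------------

fate_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("secofate_", class), "secofate_error"), ...)
}

LOG_LEVELS <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L, OFF = 99L)

#' Set the logging threshold
#'
#' Fits and pipeline steps emit messages at INFO level. Levels: `"DEBUG"`,
#' `"INFO"` (default), `"WARN"`, `"ERROR"`, `"OFF"`.
#'
#' @param level Threshold below which log messages are suppressed.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("INFO", "DEBUG", "WARN", "ERROR", "OFF")) {
  level <- match.arg(level)
  old <- getOption("secofate.log_level", "INFO")
  options(secofate.log_level = level)
  invisible(old)
}

fate_log <- function(fmt, ..., level = "INFO") {
  threshold <- getOption("secofate.log_level", "INFO")
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || (length(x) == 1L && is.na(x)))) {
    return(NA_real_)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    fate_abort(sprintf("`%s` must be a single finite number.", name),
               "input_error")
  }
  if (x < min || x > max) {
    fate_abort(
      sprintf("`%s` = %g is outside [%g, %g].", name, x, min, max),
      "domain_error"
    )
  }
  as.numeric(x)
}
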