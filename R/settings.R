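#' Structural model settings
#'
#' The source material leaves several structural choices open; each is
#' exposed here as an explicit switch with the calibrated default.  The
#' defaults were fixed once against the published base-case table and are
#' used by every engine (cohort and microsimulation) so that the two always
#' implement the same model.
#'
#' @param outpatient_scope which symptomatic states incur the monthly
#'   psychiatric outpatient cost: \code{"symptomatic"} (mild, moderate and
#'   severe; the default — stepped-up care applies to everyone who has not
#'   achieved remission) or \code{"moderate_severe"}.
#' @param highint_cbt how the one-off high-intensity CBT course
#'   (\code{sessions_high * minutes_high / 60 * therapist_hourly}) is
#'   charged: \code{"none"} (default — the claims-based outpatient
#'   patient-month cost already covers ambulatory psychiatric care including
#'   therapy, so a separate course charge would double count),
#'   \code{"initial"} (once, on the mass entering the Markov model in a
#'   symptomatic state) or \code{"entries"} (additionally on each relapse
#'   entry into the symptomatic pool).
#' @param dropout_truncates if \code{TRUE} (default), students who
#'   permanently drop out of university stop accruing costs and QALYs from
#'   that cycle on — the service-provider perspective; dropout never feeds
#'   back into the health-state transitions either way.
#' @param accrual when within a cycle state occupancy is rewarded:
#'   \code{"end"} (default; post-transition occupancy), \code{"start"}, or
#'   \code{"half"} (half-cycle correction, the mean of the two).
#' @param well_utility utility source for the well/remission state:
#'   \code{"remission"} (0.80, default) or \code{"age"} (the age-specific
#'   population utility, 0.92).
#' @param program_cost_payers who incurs the low-intensity program cost:
#'   \code{"accepters"} (default; resources are committed at enrollment) or
#'   \code{"compliers"}.
#' @return A \code{cea_settings} object (a validated list).
#' @examples
#' cea_settings()
#' cea_settings(dropout_truncates = FALSE, accrual = "start")
#' @export
cea_settings <- function(outpatient_scope = c("symptomatic", "moderate_severe"),
                         highint_cbt = c("none", "initial", "entries"),
                         dropout_truncates = TRUE,
                         accrual = c("end", "start", "half"),
                         well_utility = c("remission", "age"),
                         program_cost_payers = c("accepters", "compliers")) {
  s <- list(
    outpatient_scope = match.arg(outpatient_scope),
    highint_cbt = match.arg(highint_cbt),
    dropout_truncates = isTRUE(dropout_truncates),
    accrual = match.arg(accrual),
    well_utility = match.arg(well_utility),
    program_cost_payers = match.arg(program_cost_payers)
  )
  structure(s, class = "cea_settings")
}

#' @export
print.cea_settings <- function(x, ...) {
  cat("Model settings:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

as_settings <- function(settings) {
  if (inherits(settings, "cea_settings")) return(settings)
  if (is.null(settings)) return(cea_settings())
  do.call(cea_settings, as.list(settings))
}
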