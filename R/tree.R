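# Short-term decision tree: acceptance -> compliance -> response.
# Resolved at time zero; its output is the state distribution entering the
# Markov model plus the program cost incurred per strategy.

.strategies <- c("internet", "in_person")
.states <- c("well", "mild", "moderate", "severe", "dead")

match_strategy <- function(strategy) {
  match.arg(strategy, .strategies)
}

#' Low-intensity CBT program cost per participant
#'
#' In-person delivery costs the full therapist time
#' (\code{sessions_low * minutes_low/60 * therapist_hourly}); guided
#' internet-based delivery costs the platform overhead plus the stated
#' share of the in-person therapist time.
#'
#' @param strategy \code{"internet"} or \code{"in_person"}.
#' @param params a \code{cea_parameters} object.
#' @return Program cost in US dollars per treated participant.
#' @examples
#' p <- load_parameters()
#' program_cost("in_person", p)   # 7 * 0.5 * 54 = 189
#' program_cost("internet", p)    # 189 * 0.0923 + 24 = 41.4447
#' @export
program_cost <- function(strategy, params) {
  strategy <- match_strategy(strategy)
  full <- params$sessions_low * params$minutes_low / 60 * params$therapist_hourly
  if (full < 0) stop("negative program cost inputs", call. = FALSE)
  if (strategy == "in_person") full
  else full * params$therapist_time_share_internet + params$platform_overhead
}

#' Probability of actually receiving the program
#'
#' Acceptance times compliance for the strategy; students who decline or do
#' not adhere receive the no-intervention outcome probabilities.
#'
#' @inheritParams program_cost
#' @return A probability.
#' @examples
#' p <- load_parameters()
#' treatment_probability("internet", p)   # 0.753 * 0.808
#' @export
treatment_probability <- function(strategy, params) {
  strategy <- match_strategy(strategy)
  if (strategy == "internet") params$accept_internet * params$comply_internet
  else params$accept_inperson * params$comply_inperson
}

#' State distribution entering the Markov model
#'
#' Evaluates the decision tree: the treated fraction receives the
#' low-intensity CBT response probabilities (with the relative-effectiveness
#' multiplier applied to the recovery branch of the internet arm, capped at
#' probability one), the untreated fraction the no-intervention
#' probabilities.  Recovered mass starts well; deteriorated mass splits
#' moderate/severe by \code{prop_moderate_among_modsev}; the residual mass
#' stays mild.  The program cost is charged to accepters (or compliers,
#' per \code{settings$program_cost_payers}).
#'
#' @inheritParams program_cost
#' @param settings a [cea_settings()] object.
#' @return A \code{cea_initial} object: state probabilities
#'   (\code{p_well}, \code{p_mild}, \code{p_moderate}, \code{p_severe}) and
#'   the expected \code{program_cost} per cohort member.
#' @examples
#' p <- load_parameters()
#' initial_distribution("internet", p)
#' @export
initial_distribution <- function(strategy, params, settings = cea_settings()) {
  strategy <- match_strategy(strategy)
  settings <- as_settings(settings)
  treated <- treatment_probability(strategy, params)
  mult <- if (strategy == "internet") params$rel_effect_internet else 1
  rec_treated <- min(1, params$recovery_low_cbt * mult)
  det_treated <- min(params$deterioration_low_cbt, 1 - rec_treated)
  p_well <- treated * rec_treated + (1 - treated) * params$recovery_none
  p_det <- treated * det_treated + (1 - treated) * params$deterioration_none
  p_mild <- 1 - p_well - p_det
  if (p_mild < -1e-12) stop("decision tree probabilities exceed one", call. = FALSE)
  p_mild <- max(p_mild, 0)
  payer_frac <- if (settings$program_cost_payers == "accepters") {
    if (strategy == "internet") params$accept_internet else params$accept_inperson
  } else {
    treated
  }
  out <- list(
    p_well = p_well,
    p_mild = p_mild,
    p_moderate = p_det * params$prop_moderate_among_modsev,
    p_severe = p_det * (1 - params$prop_moderate_among_modsev),
    program_cost = payer_frac * program_cost(strategy, params)
  )
  total <- out$p_well + out$p_mild + out$p_moderate + out$p_severe
  if (abs(total - 1) > 1e-12)
    stop("initial state probabilities do not sum to one", call. = FALSE)
  structure(out, strategy = strategy, class = "cea_initial")
}

initial_occupancy <- function(init) {
  c(well = init$p_well, mild = init$p_mild, moderate = init$p_moderate,
    severe = init$p_severe, dead = 0)
}

#' @export
print.cea_initial <- function(x, ...) {
  cat("Initial distribution (", attr(x, "strategy"), ")\n", sep = "")
  cat(sprintf("  well %.6f | mild %.6f | moderate %.6f | severe %.6f\n",
              x$p_well, x$p_mild, x$p_moderate, x$p_severe))
  cat(sprintf("  program cost per cohort member: $%.4f\n", x$program_cost))
  invisible(x)
}
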