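# Monthly Markov cohort engine: five occupancy states
# (well/remission, mild, moderate, severe, dead), with school dropout
# tracked as a parallel counter rather than a health state.

#' Monthly transition probability matrix
#'
#' From well/remission: relapse with probability \code{relapse_monthly},
#' split across mild/moderate/severe by the relapse severity mix
#' (\code{prop_mild_relapse}, then \code{prop_moderate_among_modsev} within
#' the moderate-severe remainder); death with \code{mortality_monthly}.
#' From any symptomatic state: remission with \code{remission_monthly};
#' death with \code{mortality_monthly * rr_mortality_depressed}; the
#' staying mass is redistributed across the three severities by the same
#' mix each cycle, so severity within the symptomatic pool is a proportional
#' split of the pool (memoryless severity) rather than a persistent
#' attribute.  Death is absorbing.
#'
#' @param params a \code{cea_parameters} object.
#' @return A 5x5 row-stochastic matrix of class \code{cea_transitions},
#'   rows/columns ordered well, mild, moderate, severe, dead.
#' @examples
#' tm <- build_transition_model(load_parameters())
#' tm["well", "mild"]   # 0.0244 * 0.243
#' @export
build_transition_model <- function(params) {
  m_well <- params$mortality_monthly
  m_dep <- min(1, m_well * params$rr_mortality_depressed)
  rel <- params$relapse_monthly
  rem <- params$remission_monthly
  mix <- severity_mix(params)
  if (rel + m_well > 1)
    stop("well-state exits exceed one: relapse + mortality > 1", call. = FALSE)
  if (rem + m_dep > 1)
    stop("symptomatic-state exits exceed one: remission + mortality > 1",
         call. = FALSE)
  tm <- matrix(0, 5, 5, dimnames = list(.states, .states))
  tm["well", ] <- c(1 - rel - m_well, rel * mix, m_well)
  stay <- 1 - rem - m_dep
  for (s in c("mild", "moderate", "severe"))
    tm[s, ] <- c(rem, stay * mix, m_dep)
  tm["dead", "dead"] <- 1
  rs <- rowSums(tm)
  if (any(abs(rs - 1) > 1e-12) || any(tm < 0))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  structure(tm, class = c("cea_transitions", "matrix"))
}

# Severity mix of the symptomatic pool: (mild, moderate, severe).
severity_mix <- function(params) {
  c(params$prop_mild_relapse,
    (1 - params$prop_mild_relapse) * params$prop_moderate_among_modsev,
    (1 - params$prop_mild_relapse) * (1 - params$prop_moderate_among_modsev))
}

#' Discount factor for a monthly cycle index
#'
#' @param cycle cycle index (0 = model entry), possibly a vector.
#' @param annual_rate annual discounting rate (default 3\%).
#' @return \code{(1 + annual_rate)^(-cycle/12)}.
#' @examples
#' discount_factor(12, 0.03)   # 1/1.03
#' @export
discount_factor <- function(cycle, annual_rate = 0.03) {
  if (annual_rate <= -1) stop("annual_rate must exceed -1", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

# Per-state monthly utility weights (dead contributes zero).
state_utilities <- function(params, settings = cea_settings()) {
  settings <- as_settings(settings)
  u_well <- if (settings$well_utility == "remission") params$utility_remission
            else params$utility_age
  c(well = u_well, mild = params$utility_mild, moderate = params$utility_moderate,
    severe = params$utility_severe, dead = 0)
}

# Per-state monthly cost weights: outpatient psychiatric care on the
# configured symptomatic scope plus the expected hospitalization cost on
# severe occupancy.
state_costs <- function(params, settings = cea_settings()) {
  settings <- as_settings(settings)
  outp <- if (settings$outpatient_scope == "symptomatic") c(0, 1, 1, 1, 0)
          else c(0, 0, 1, 1, 0)
  costs <- params$outpatient_monthly * outp
  costs[4] <- costs[4] + params$hosp_monthly_severe * params$hosp_episode_cost
  names(costs) <- .states
  costs
}

# Monthly school-dropout hazards by state (dead students cannot drop out).
dropout_hazards <- function(params) {
  c(well = params$dropout_monthly_well,
    mild = params$dropout_monthly_dep, moderate = params$dropout_monthly_dep,
    severe = params$dropout_monthly_dep, dead = 0)
}

highint_course_cost <- function(params) {
  params$sessions_high * params$minutes_high / 60 * params$therapist_hourly
}

#' Cost and QALY accrued by an occupancy vector in one cycle
#'
#' @param occupancy named occupancy vector over the five states.
#' @param cycle cycle index used for discounting.
#' @param params a \code{cea_parameters} object.
#' @param settings a [cea_settings()] object.
#' @return \code{c(cost = , qaly = )}, discounted to model entry.
#' @examples
#' p <- load_parameters()
#' accrue_cycle(c(well = 1, mild = 0, moderate = 0, severe = 0, dead = 0), 0, p)
#' @export
accrue_cycle <- function(occupancy, cycle, params, settings = cea_settings()) {
  settings <- as_settings(settings)
  df <- discount_factor(cycle, params$discount_annual)
  cost <- sum(occupancy * state_costs(params, settings)) * df
  qaly <- sum(occupancy * state_utilities(params, settings)) / 12 * df
  if (cost < 0 || qaly < 0) stop("negative accrual", call. = FALSE)
  c(cost = unname(cost), qaly = unname(qaly))
}

#' Run the Markov cohort over the model horizon
#'
#' Propagates the initial distribution through the monthly transition model
#' for \code{horizon_months} cycles, accruing discounted costs and QALYs
#' per cycle (on start-of-cycle, post-transition, or half-cycle occupancy
#' per \code{settings$accrual}) and accumulating the school-dropout
#' probability from the state-specific monthly hazards.  When
#' \code{settings$dropout_truncates} is \code{TRUE} the accruals are taken
#' on the in-school occupancy, which is depleted by dropout as well as by
#' death; the full-cohort occupancy (which always sums to one) is tracked
#' alongside.
#'
#' @param init a \code{cea_initial} object from [initial_distribution()].
#' @param tm a transition matrix from [build_transition_model()].
#' @param params a \code{cea_parameters} object.
#' @param settings a [cea_settings()] object.
#' @return A \code{cea_trace}: \code{occupancy} and \code{school} matrices
#'   (one row per cycle 0..horizon), \code{cum_dropout} per cycle,
#'   per-cycle discounted \code{disc_cost} and \code{disc_qaly}, and
#'   \code{init_cost} (program cost plus any initial high-intensity CBT
#'   charge).
#' @export
run_cohort <- function(init, tm, params, settings = cea_settings()) {
  settings <- as_settings(settings)
  if (params$cycle_months != 1)
    stop("the engine is formulated on monthly cycles (cycle_months = 1)",
         call. = FALSE)
  horizon <- as.integer(params$horizon_months)
  occ <- initial_occupancy(init)
  sch <- occ
  cvec <- state_costs(params, settings)
  uvec <- state_utilities(params, settings)
  d <- dropout_hazards(params)
  hi <- highint_course_cost(params)
  rate <- params$discount_annual
  trunc <- settings$dropout_truncates

  occupancy <- matrix(NA_real_, horizon + 1, 5, dimnames = list(NULL, .states))
  school <- occupancy
  occupancy[1, ] <- occ
  school[1, ] <- sch
  cum_dropout <- numeric(horizon + 1)
  disc_cost <- numeric(horizon)
  disc_qaly <- numeric(horizon)

  init_cost <- init$program_cost
  if (settings$highint_cbt %in% c("initial", "entries"))
    init_cost <- init_cost + hi * sum((if (trunc) sch else occ)[2:4])

  t_seq <- seq_len(horizon) - 1L
  dfac <- discount_factor(t_seq, rate)
  dropped <- 0
  for (t in t_seq) {
    at_risk <- sch * (1 - d)
    sch2 <- as.vector(at_risk %*% tm)
    occ2 <- as.vector(occ %*% tm)
    a0 <- if (trunc) sch else occ
    a1 <- if (trunc) sch2 else occ2
    a <- switch(settings$accrual, end = a1, start = a0, half = (a0 + a1) / 2)
    df <- dfac[t + 1L]
    cost_t <- sum(a * cvec) * df
    if (settings$highint_cbt == "entries") {
      new_dep <- (if (trunc) at_risk[1] else occ[1]) * params$relapse_monthly
      cost_t <- cost_t + hi * new_dep * discount_factor(t + 1L, rate)
    }
    disc_cost[t + 1L] <- cost_t
    disc_qaly[t + 1L] <- sum(a * uvec) / 12 * df
    dropped <- dropped + sum(sch * d)
    occ <- occ2
    sch <- sch2
    occupancy[t + 2L, ] <- occ
    school[t + 2L, ] <- sch
    cum_dropout[t + 2L] <- dropped
    if (abs(sum(occ) - 1) > 1e-9)
      stop("occupancy drifted away from one at cycle ", t + 1L, call. = FALSE)
  }
  structure(list(occupancy = occupancy, school = school,
                 cum_dropout = cum_dropout, disc_cost = disc_cost,
                 disc_qaly = disc_qaly, init_cost = unname(init_cost),
                 settings = settings),
            strategy = attr(init, "strategy"), class = "cea_trace")
}

#' Evaluate one strategy end to end
#'
#' Resolves the decision tree at time zero, runs the 60-cycle cohort model
#' and totals the discounted accruals.
#'
#' @inheritParams program_cost
#' @param settings a [cea_settings()] object.
#' @param keep_trace retain the full cohort trace in the result.
#' @return A \code{cea_outcome}: \code{total_cost} (US $, discounted),
#'   \code{total_qaly} (discounted QALYs), \code{dropout_prob} (cumulative
#'   5-year school-dropout probability) and, optionally, \code{trace}.
#' @examples
#' out <- run_strategy("internet", load_parameters())
#' out$total_cost
#' @export
run_strategy <- function(strategy, params, settings = cea_settings(),
                         keep_trace = TRUE) {
  strategy <- match_strategy(strategy)
  settings <- as_settings(settings)
  init <- initial_distribution(strategy, params, settings)
  tm <- build_transition_model(params)
  trace <- run_cohort(init, tm, params, settings)
  out <- list(
    strategy = strategy,
    total_cost = trace$init_cost + sum(trace$disc_cost),
    total_qaly = sum(trace$disc_qaly),
    dropout_prob = trace$cum_dropout[length(trace$cum_dropout)],
    trace = if (keep_trace) trace else NULL
  )
  structure(out, class = "cea_outcome")
}

#' @export
print.cea_outcome <- function(x, ...) {
  cat(sprintf("%s strategy: cost $%.2f | %.4f QALYs | dropout %.4f%%\n",
              x$strategy, x$total_cost, x$total_qaly, 100 * x$dropout_prob))
  invisible(x)
}

#' Export a cohort trace as a data frame
#'
#' One row per cycle: state occupancies, in-school occupancies, cumulative
#' dropout probability and the discounted accruals of the cycle.
#'
#' @param x a \code{cea_trace}.
#' @param ... unused.
#' @return A data frame with \code{horizon + 1} rows (accrual columns are
#'   \code{NA} on the terminal row, which accrues nothing).
#' @export
as.data.frame.cea_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  data.frame(cycle = seq_len(n) - 1L,
             x$occupancy,
             school = x$school,
             cum_dropout = x$cum_dropout,
             disc_cost = c(x$disc_cost, NA),
             disc_qaly = c(x$disc_qaly, NA))
}
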