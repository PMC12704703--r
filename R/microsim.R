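# Individual-level Monte Carlo simulator of the identical decision tree,
# transition and accrual model.  Serves both as the synthetic-data
# generator (individual trajectories) and as a brute-force oracle for the
# cohort engine: at large n its means must agree with the cohort totals.

msim_run <- function(strategy, params, n, seed, settings = cea_settings(),
                     keep_paths = FALSE) {
  strategy <- match_strategy(strategy)
  settings <- as_settings(settings)
  set.seed(as.integer(seed))
  horizon <- as.integer(params$horizon_months)
  trunc <- settings$dropout_truncates

  acc_p <- if (strategy == "internet") params$accept_internet else params$accept_inperson
  com_p <- if (strategy == "internet") params$comply_internet else params$comply_inperson
  mult <- if (strategy == "internet") params$rel_effect_internet else 1
  rec_treated <- min(1, params$recovery_low_cbt * mult)
  det_treated <- min(params$deterioration_low_cbt, 1 - rec_treated)

  accept <- stats::runif(n) < acc_p
  comply <- accept & (stats::runif(n) < com_p)
  p_well <- ifelse(comply, rec_treated, params$recovery_none)
  p_det <- ifelse(comply, det_treated, params$deterioration_none)
  u0 <- stats::runif(n)
  u_sev0 <- stats::runif(n)
  # 1 well, 2 mild, 3 moderate, 4 severe, 5 dead
  state <- ifelse(u0 < p_well, 1L,
                  ifelse(u0 < p_well + (1 - p_well - p_det), 2L,
                         ifelse(u_sev0 < params$prop_moderate_among_modsev, 3L, 4L)))

  payer <- if (settings$program_cost_payers == "accepters") accept else comply
  cost <- as.numeric(payer) * program_cost(strategy, params)
  qaly <- numeric(n)
  hi <- highint_course_cost(params)
  if (settings$highint_cbt %in% c("initial", "entries"))
    cost <- cost + hi * (state >= 2L & state <= 4L)

  uvec <- unname(state_utilities(params, settings))
  outp_states <- if (settings$outpatient_scope == "symptomatic") 2:4 else 3:4
  d_haz <- dropout_hazards(params)
  mix <- severity_mix(params)
  cmix <- cumsum(mix)
  rel <- params$relapse_monthly
  rem <- params$remission_monthly
  m_well <- params$mortality_monthly
  m_dep <- min(1, m_well * params$rr_mortality_depressed)
  rate <- params$discount_annual

  in_school <- rep(TRUE, n)
  dropout_cycle <- rep(NA_integer_, n)
  paths <- if (keep_paths) matrix(NA_integer_, n, horizon + 1L) else NULL
  if (keep_paths) paths[, 1L] <- state

  accrue <- function(s, weight, df, u_h) {
    q <- uvec[s] / 12 * weight * df
    cc <- (s %in% outp_states) * params$outpatient_monthly
    cc <- cc + (s == 4L) * (u_h < params$hosp_monthly_severe) * params$hosp_episode_cost
    list(cost = cc * weight * df, qaly = q)
  }

  for (t in seq_len(horizon) - 1L) {
    df <- discount_factor(t, rate)
    s0 <- state
    school0 <- in_school
    # school dropout acts on the start-of-cycle state; the dead cannot drop out
    u_d <- stats::runif(n)
    drop_now <- in_school & (u_d < d_haz[s0])
    dropout_cycle[drop_now] <- t
    in_school <- in_school & !drop_now
    # health-state transition
    u_t <- stats::runif(n)
    u_m <- stats::runif(n)
    sev_draw <- ifelse(u_m < cmix[1], 2L, ifelse(u_m < cmix[2], 3L, 4L))
    s1 <- s0
    well <- s0 == 1L
    s1[well] <- ifelse(u_t[well] < rel, sev_draw[well],
                       ifelse(u_t[well] < rel + m_well, 5L, 1L))
    dep <- s0 >= 2L & s0 <= 4L
    s1[dep] <- ifelse(u_t[dep] < rem, 1L,
                      ifelse(u_t[dep] < rem + m_dep, 5L, sev_draw[dep]))
    state <- s1
    if (keep_paths) paths[, t + 2L] <- state
    if (settings$highint_cbt == "entries") {
      entered <- well & state >= 2L & state <= 4L
      if (trunc) entered <- entered & in_school
      cost <- cost + hi * entered * discount_factor(t + 1L, rate)
    }
    # accrual weights mirror the cohort engine's timing switch
    u_h <- stats::runif(n)
    if (settings$accrual == "end") {
      w <- if (trunc) as.numeric(in_school) else 1
      a <- accrue(s1, w, df, u_h)
    } else if (settings$accrual == "start") {
      w <- if (trunc) as.numeric(school0) else 1
      a <- accrue(s0, w, df, u_h)
    } else {
      u_h2 <- stats::runif(n)
      w0 <- if (trunc) as.numeric(school0) else 1
      w1 <- if (trunc) as.numeric(in_school) else 1
      a0 <- accrue(s0, w0 / 2, df, u_h)
      a1 <- accrue(s1, w1 / 2, df, u_h2)
      a <- list(cost = a0$cost + a1$cost, qaly = a0$qaly + a1$qaly)
    }
    cost <- cost + a$cost
    qaly <- qaly + a$qaly
  }
  list(cost = cost, qaly = qaly, dropout_cycle = dropout_cycle,
       dropped = !is.na(dropout_cycle), final_state = state, paths = paths,
       strategy = strategy)
}

#' Simulate one individual trajectory
#'
#' Samples the decision-tree branch (acceptance, compliance, response),
#' then the monthly health-state transitions, hospitalization events while
#' severe, and a school-dropout event from the state-specific hazards,
#' using exactly the same accrual rules as the cohort engine.
#'
#' @param strategy \code{"internet"} or \code{"in_person"}.
#' @param params a \code{cea_parameters} object.
#' @param seed integer seed; the trajectory is reproducible given the seed.
#' @param settings a [cea_settings()] object.
#' @return A \code{cea_trajectory}: \code{states} (state labels over cycles
#'   0..horizon), \code{dropout_cycle} (\code{NA} if the student never
#'   drops out), discounted \code{cost} and \code{qaly}.
#' @examples
#' simulate_individual("internet", load_parameters(), seed = 1)
#' @export
simulate_individual <- function(strategy, params, seed,
                                settings = cea_settings()) {
  r <- msim_run(strategy, params, 1L, seed, settings, keep_paths = TRUE)
  structure(list(states = .states[r$paths[1, ]],
                 dropout_cycle = r$dropout_cycle[1],
                 cost = r$cost[1], qaly = r$qaly[1],
                 strategy = r$strategy, seed = seed),
            class = "cea_trajectory")
}

#' @export
print.cea_trajectory <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("Trajectory (%s): cost $%.2f, %.4f QALYs, dropout %s\n",
              x$strategy, x$cost, x$qaly,
              if (is.na(x$dropout_cycle)) "never"
              else paste("at cycle", x$dropout_cycle)))
  runs <- rle(x$states)
  cat("  ", paste0(runs$values, " x", runs$lengths, collapse = " -> "), "\n")
  invisible(x)
}

#' Microsimulation estimate of one strategy's outcomes
#'
#' Simulates \code{n} independent students and estimates the mean cost,
#' mean QALYs and dropout fraction with Monte Carlo standard errors.  Used
#' as the brute-force oracle against which the cohort engine is validated:
#' by the law of large numbers the two must agree within Monte Carlo error
#' for any valid parameter set.
#'
#' @inheritParams simulate_individual
#' @param n number of simulated individuals.
#' @return A \code{cea_microsim}: means, standard errors (\code{NA} when
#'   \code{n} is 1), the dropout fraction, and the relative frequency of
#'   each state at the final cycle.
#' @examples
#' simulate_cohort("internet", load_parameters(), n = 2000, seed = 1)
#' @export
simulate_cohort <- function(strategy, params, n, seed,
                            settings = cea_settings()) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  r <- msim_run(strategy, params, as.integer(n), seed, settings)
  se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  freq <- tabulate(r$final_state, nbins = 5L) / n
  names(freq) <- .states
  structure(list(
    strategy = r$strategy, n = as.integer(n), seed = seed,
    mean_cost = mean(r$cost), se_cost = se(r$cost),
    mean_qaly = mean(r$qaly), se_qaly = se(r$qaly),
    dropout_frac = mean(r$dropped), se_dropout = se(as.numeric(r$dropped)),
    final_state_freq = freq
  ), class = "cea_microsim")
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation (%s, n = %d)\n", x$strategy, x$n))
  cat(sprintf("  mean cost:  $%.2f (SE %.3f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean QALYs: %.4f (SE %.5f)\n", x$mean_qaly, x$se_qaly))
  cat(sprintf("  dropout:    %.4f%% (SE %.4f%%)\n", 100 * x$dropout_frac,
              100 * x$se_dropout))
  invisible(x)
}

#' Simulate individual students from a fitted model
#'
#' @param object a [cea_model()] fit.
#' @param nsim number of individuals.
#' @param seed integer seed.
#' @param strategy which strategy arm to simulate.
#' @param ... unused.
#' @return A data frame with one row per simulated student: discounted
#'   \code{cost} and \code{qaly}, \code{dropout_cycle} (\code{NA} if never)
#'   and \code{final_state}.
#' @export
simulate.cea_model <- function(object, nsim = 1, seed = 1,
                               strategy = c("internet", "in_person"), ...) {
  strategy <- match.arg(strategy)
  r <- msim_run(strategy, object$params, as.integer(nsim), seed,
                object$settings)
  data.frame(cost = r$cost, qaly = r$qaly, dropout_cycle = r$dropout_cycle,
             final_state = .states[r$final_state])
}
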