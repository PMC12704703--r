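#' Fit the full decision-analytic model
#'
#' Central entry point: evaluates both delivery strategies (guided
#' internet-based and conventional in-person low-intensity CBT) on one
#' parameter set — decision tree at time zero, then the 60-cycle monthly
#' Markov cohort — and compares them.  All downstream analyses
#' ([one_way_sa()], [two_way_sa()], [threshold_search()], [run_psa()]) and
#' the microsimulation oracle ([simulate.cea_model()]) reuse the parameters
#' and settings stored in the fitted object.
#'
#' @param params model inputs from [load_parameters()] (defaults to the
#'   canonical set).
#' @param settings structural switches from [cea_settings()].
#' @param wtp willingness-to-pay threshold; defaults to the \code{wtp}
#'   parameter (US $48,119/QALY, the GDP-per-capita rule).
#' @return A \code{cea_model} object with components \code{outcomes} (one
#'   \code{cea_outcome} per strategy, traces included), \code{comparison}
#'   (internet vs in-person), \code{params}, \code{settings}, \code{wtp}.
#' @examples
#' m <- cea_model()
#' m
#' summary(m)
#' @export
cea_model <- function(params = load_parameters(), settings = cea_settings(),
                      wtp = params$wtp) {
  settings <- as_settings(settings)
  outcomes <- list(
    internet = run_strategy("internet", params, settings),
    in_person = run_strategy("in_person", params, settings)
  )
  structure(list(
    outcomes = outcomes,
    comparison = compare_strategies(outcomes$internet, outcomes$in_person),
    params = params,
    settings = settings,
    wtp = wtp
  ), class = "cea_model")
}

#' Base-case results in tabular form
#'
#' @param model a \code{cea_model}.
#' @return A two-row data frame mirroring the usual base-case reporting:
#'   per-strategy cost, incremental cost, school dropout (%), incremental
#'   dropout, QALYs and incremental QALYs.
#' @export
base_case_table <- function(model) {
  oi <- model$outcomes$internet
  op <- model$outcomes$in_person
  cmp <- model$comparison
  data.frame(
    strategy = c("internet", "in_person"),
    cost = c(oi$total_cost, op$total_cost),
    incr_cost = c(cmp$d_cost, NA),
    dropout_pct = 100 * c(oi$dropout_prob, op$dropout_prob),
    incr_dropout_pct = c(100 * cmp$d_dropout, NA),
    qalys = c(oi$total_qaly, op$total_qaly),
    incr_qalys = c(cmp$d_qaly, NA)
  )
}

#' @export
print.cea_model <- function(x, digits = 4, ...) {
  cat("Decision-analytic model: guided internet-based vs in-person",
      "low-intensity CBT\n")
  cat(sprintf("Horizon %d months, %.0f%% annual discounting, WTP $%s/QALY\n\n",
              as.integer(x$params$horizon_months), 100 * x$params$discount_annual,
              format(x$wtp, big.mark = ",")))
  tab <- base_case_table(x)
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  cmp <- x$comparison
  cat("\n")
  if (cmp$dominant) {
    cat(sprintf("Internet strategy is dominant (saves $%.0f, gains %.4f QALYs);",
                -cmp$d_cost, cmp$d_qaly))
    cat(sprintf(" ICER %.0f $/QALY.\n", cmp$icer))
  } else {
    cat(sprintf("ICER: %s $/QALY; cost-effective at WTP: %s\n",
                ifelse(is.na(cmp$icer), "undefined", sprintf("%.0f", cmp$icer)),
                is_cost_effective(cmp, x$wtp)))
  }
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  structure(list(
    table = base_case_table(object),
    comparison = object$comparison,
    cost_effective = is_cost_effective(object$comparison, object$wtp),
    nmb = net_monetary_benefit(object$comparison, object$wtp),
    wtp = object$wtp,
    settings = object$settings
  ), class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("\nNMB at WTP $%s/QALY: $%.2f -> internet %s cost-effective\n",
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$cost_effective) "is" else "is not"))
  invisible(x)
}

#' @export
coef.cea_model <- function(object, ...) {
  unlist(object$params)
}

#' Plot the cohort trace of a fitted model
#'
#' State occupancy over the model horizon for one or both strategies, with
#' the cumulative school-dropout probability overlaid.
#'
#' @param x a \code{cea_model}.
#' @param strategy which strategy's trace to draw.
#' @param ... passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.cea_model <- function(x, strategy = c("internet", "in_person"), ...) {
  strategy <- match.arg(strategy)
  trace <- x$outcomes[[strategy]]$trace
  occ <- trace$occupancy
  cycles <- seq_len(nrow(occ)) - 1L
  cols <- c("forestgreen", "goldenrod2", "darkorange3", "firebrick3", "grey40")
  graphics::matplot(cycles, occ, type = "l", lty = 1, lwd = 2, col = cols,
                    xlab = "cycle (months)", ylab = "occupancy",
                    main = paste0("Cohort trace (", strategy, ")"), ...)
  graphics::lines(cycles, trace$cum_dropout, lty = 2, col = "blue")
  graphics::legend("right", bty = "n", lwd = 2,
                   lty = c(rep(1, 5), 2),
                   col = c(cols, "blue"),
                   legend = c(colnames(occ), "cum. dropout"))
  invisible(x)
}
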