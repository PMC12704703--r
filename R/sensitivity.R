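# Deterministic sensitivity analyses: one-way (tornado), the two-way
# compliance grid, and threshold search for extended ranges.

eval_comparison <- function(params, settings) {
  compare_strategies(run_strategy("internet", params, settings, keep_trace = FALSE),
                     run_strategy("in_person", params, settings, keep_trace = FALSE))
}

ranged_parameters <- function(params) {
  reg <- attr(params, "registry")
  reg$name[reg$dist != "fixed" & reg$high > reg$low]
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full model with each selected parameter set to the endpoints
#' of its sensitivity range, all other parameters at base, and records the
#' resulting ICER, dominance status and net monetary benefit.  Rows are
#' ordered by ICER swing (tornado order); the NMB swing is reported
#' alongside since the ICER is ill-behaved near zero incremental QALYs.
#'
#' @param model a [cea_model()] fit.
#' @param parameters parameter names to vary; default all parameters with a
#'   non-degenerate range.
#' @return A \code{cea_oneway} data frame with one row per parameter:
#'   range endpoints, \code{icer_low}/\code{icer_high} (ICER with the
#'   parameter at its low/high value), dominance flags, NMB at both ends
#'   and the swings.  The base-case ICER and NMB are attached as
#'   attributes.
#' @examples
#' m <- cea_model()
#' head(one_way_sa(m, c("comply_internet", "comply_inperson")))
#' @export
one_way_sa <- function(model, parameters = NULL) {
  params <- model$params
  reg <- attr(params, "registry")
  if (is.null(parameters)) parameters <- ranged_parameters(params)
  unknown <- setdiff(parameters, reg$name)
  if (length(unknown))
    stop("unknown parameter: ", paste(unknown, collapse = ", "), call. = FALSE)
  degenerate <- parameters[!(parameters %in% ranged_parameters(params))]
  if (length(degenerate))
    stop("parameter has a degenerate range: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  base_cmp <- model$comparison
  wtp <- model$wtp
  rows <- lapply(parameters, function(nm) {
    spec <- param_spec(params, nm)
    ends <- lapply(c(spec$low, spec$high), function(v) {
      cmp <- eval_comparison(set_parameters(params, stats::setNames(list(v), nm)),
                             model$settings)
      list(icer = cmp$icer, dominant = cmp$dominant,
           nmb = net_monetary_benefit(cmp, wtp))
    })
    data.frame(parameter = nm, low = spec$low, high = spec$high,
               icer_low = ends[[1]]$icer, icer_high = ends[[2]]$icer,
               dominant_low = ends[[1]]$dominant, dominant_high = ends[[2]]$dominant,
               nmb_low = ends[[1]]$nmb, nmb_high = ends[[2]]$nmb)
  })
  out <- do.call(rbind, rows)
  out$icer_swing <- abs(out$icer_high - out$icer_low)
  out$nmb_swing <- abs(out$nmb_high - out$nmb_low)
  out <- out[order(-out$icer_swing), ]
  rownames(out) <- NULL
  structure(out, base_icer = base_cmp$icer,
            base_nmb = net_monetary_benefit(base_cmp, wtp), wtp = wtp,
            class = c("cea_oneway", "data.frame"))
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param x a \code{cea_oneway} result.
#' @param metric \code{"nmb"} (default; well-defined for every row) or
#'   \code{"icer"}.
#' @param n_top how many parameters to show.
#' @param ... unused.
#' @export
plot.cea_oneway <- function(x, metric = c("nmb", "icer"), n_top = 12, ...) {
  metric <- match.arg(metric)
  cols <- if (metric == "nmb") c("nmb_low", "nmb_high") else c("icer_low", "icer_high")
  base <- attr(x, if (metric == "nmb") "base_nmb" else "base_icer")
  x <- x[order(-x[[paste0(metric, "_swing")]]), ]
  x <- utils::head(x, n_top)
  x <- x[rev(seq_len(nrow(x))), ]
  lo <- x[[cols[1]]]
  hi <- x[[cols[2]]]
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)), ylim = c(0.5, nrow(x) + 0.5),
                 yaxt = "n", xlab = toupper(metric), ylab = "",
                 main = "One-way sensitivity")
  graphics::axis(2, at = seq_len(nrow(x)), labels = x$parameter, las = 1,
                 cex.axis = 0.8)
  graphics::segments(lo, seq_len(nrow(x)), hi, seq_len(nrow(x)),
                     lwd = 8, col = "steelblue", lend = 1)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

grid_verdict <- function(d_cost, d_qaly, wtp) {
  # vectorized mirror of is_cost_effective(); ties go to the comparator
  ifelse(d_cost < 0 & d_qaly > 0, TRUE,
         ifelse(d_cost >= 0 & d_qaly <= 0, FALSE,
                ifelse(d_cost > 0 & d_qaly > 0, d_cost / d_qaly < wtp,
                       d_qaly * wtp - d_cost > 0)))
}

#' Two-way sensitivity analysis on the compliance rates
#'
#' Evaluates the preferred strategy over a grid of compliance rates to
#' internet-based and in-person CBT (default 50--100\% on both axes, the
#' extended range).  Each cell's verdict applies the cost-effectiveness
#' rule at the model's willingness-to-pay threshold.  Because each arm's
#' outcome depends only on its own compliance rate, the grid needs one
#' model run per axis value rather than per cell.
#'
#' @param model a [cea_model()] fit.
#' @param step grid step on both axes (default 0.005, a 101x101 grid).
#' @param range compliance range explored on both axes.
#' @return A \code{cea_twoway}: axis vectors \code{comply_internet} and
#'   \code{comply_inperson} and the logical matrix
#'   \code{internet_preferred} (rows: internet compliance; columns:
#'   in-person compliance).
#' @export
two_way_sa <- function(model, step = 0.005, range = c(0.5, 1)) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (range[1] < 0 || range[2] > 1 || range[1] >= range[2])
    stop("range must be an increasing interval within [0, 1]", call. = FALSE)
  params <- model$params
  settings <- model$settings
  xs <- seq(range[1], range[2], by = step)
  run_axis <- function(strategy, name) {
    lapply(xs, function(v) {
      p <- set_parameters(params, stats::setNames(list(v), name), strict = FALSE)
      run_strategy(strategy, p, settings, keep_trace = FALSE)
    })
  }
  out_i <- run_axis("internet", "comply_internet")
  out_p <- run_axis("in_person", "comply_inperson")
  cost_i <- vapply(out_i, `[[`, numeric(1), "total_cost")
  qaly_i <- vapply(out_i, `[[`, numeric(1), "total_qaly")
  cost_p <- vapply(out_p, `[[`, numeric(1), "total_cost")
  qaly_p <- vapply(out_p, `[[`, numeric(1), "total_qaly")
  d_cost <- outer(cost_i, cost_p, "-")
  d_qaly <- outer(qaly_i, qaly_p, "-")
  verdict <- grid_verdict(d_cost, d_qaly, model$wtp)
  dimnames(verdict) <- list(comply_internet = format(xs, digits = 4),
                            comply_inperson = format(xs, digits = 4))
  structure(list(comply_internet = xs, comply_inperson = xs,
                 internet_preferred = verdict, wtp = model$wtp, step = step),
            class = "cea_twoway")
}

#' @export
print.cea_twoway <- function(x, ...) {
  frac <- mean(x$internet_preferred)
  cat(sprintf("Two-way compliance grid (%dx%d cells, WTP $%s/QALY)\n",
              length(x$comply_internet), length(x$comply_inperson),
              format(x$wtp, big.mark = ",")))
  cat(sprintf("Internet preferred in %.1f%% of cells\n", 100 * frac))
  invisible(x)
}

#' @export
plot.cea_twoway <- function(x, ...) {
  graphics::image(x$comply_internet, x$comply_inperson,
                  x$internet_preferred + 0,
                  col = c("white", "grey60"),
                  xlab = "compliance, internet-based CBT",
                  ylab = "compliance, in-person CBT",
                  main = "Preferred strategy (grey: internet)", ...)
  graphics::box()
  invisible(x)
}

#' Long-format export of a two-way grid
#'
#' @param x a \code{cea_twoway}.
#' @param ... unused.
#' @return A data frame with columns \code{comply_internet},
#'   \code{comply_inperson}, \code{internet_preferred}.
#' @export
as.data.frame.cea_twoway <- function(x, ...) {
  data.frame(comply_internet = rep(x$comply_internet,
                                   times = length(x$comply_inperson)),
             comply_inperson = rep(x$comply_inperson,
                                   each = length(x$comply_internet)),
             internet_preferred = as.vector(x$internet_preferred))
}

#' Threshold search on one parameter
#'
#' Bisects the cost-effectiveness verdict (at the model's willingness-to-pay
#' threshold) over a bracket of parameter values, all other inputs at base.
#' Used for the extended sensitivity analysis: platform overhead explored
#' up to US$2000 and the therapist time share up to 50\%.
#'
#' @param model a [cea_model()] fit.
#' @param parameter parameter name.
#' @param bracket numeric interval to search.
#' @param tol bisection tolerance: defaults to 1 (US $) for money-scale
#'   parameters and 0.001 (0.1 percentage point) otherwise.
#' @return A \code{cea_threshold}: \code{threshold} (\code{NA} when the
#'   verdict does not change over the bracket), the verdicts at the bracket
#'   ends, and — should the verdict flip more than once on a coarse scan —
#'   every detected crossing in \code{all_thresholds}.
#' @examples
#' m <- cea_model()
#' threshold_search(m, "platform_overhead", c(24, 2000))
#' @export
threshold_search <- function(model, parameter, bracket, tol = NULL) {
  params <- model$params
  spec <- param_spec(params, parameter)
  if (is.null(tol)) tol <- if (identical(spec$scale, "money")) 1 else 0.001
  if (length(bracket) != 2 || bracket[1] >= bracket[2])
    stop("bracket must be an increasing interval", call. = FALSE)
  verdict_at <- function(v) {
    p <- set_parameters(params, stats::setNames(list(v), parameter),
                        strict = FALSE)
    is_cost_effective(eval_comparison(p, model$settings), model$wtp)
  }
  scan <- seq(bracket[1], bracket[2], length.out = 41L)
  vs <- vapply(scan, verdict_at, logical(1))
  flips <- which(vs[-1] != vs[-length(vs)])
  bisect <- function(lo, hi, v_lo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (verdict_at(mid) == v_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  thresholds <- vapply(flips, function(i) bisect(scan[i], scan[i + 1], vs[i]),
                       numeric(1))
  structure(list(parameter = parameter, bracket = bracket,
                 threshold = if (length(thresholds)) thresholds[1] else NA_real_,
                 all_thresholds = thresholds,
                 verdict_low = vs[1], verdict_high = vs[length(vs)],
                 tol = tol, wtp = model$wtp),
            class = "cea_threshold")
}

#' @export
print.cea_threshold <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("No cost-effectiveness threshold for '%s' in [%g, %g]\n",
                x$parameter, x$bracket[1], x$bracket[2]))
  } else {
    cat(sprintf("Verdict flips at %s = %.4g (tolerance %g)\n",
                x$parameter, x$threshold, x$tol))
    if (length(x$all_thresholds) > 1)
      cat("  note: multiple crossings detected at ",
          paste(signif(x$all_thresholds, 6), collapse = ", "), "\n")
  }
  invisible(x)
}
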