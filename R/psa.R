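# Probabilistic sensitivity analysis: paired Monte Carlo evaluation of both
# strategies under common sampled parameter sets.

# Deterministic per-draw substream seed: changing n never reshuffles
# earlier draws, and every value stays below 2^31 - 1.
draw_seed <- function(master, i) {
  ((as.numeric(master) + as.numeric(i) * 982451653) %% 2147483629) + 1
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw, samples one parameter set ([sample_parameter_set()]) and
#' evaluates both strategies on it — a paired design with common random
#' parameters, without which the Monte Carlo error on the incremental
#' outcomes would be far larger.  Acceptance and compliance pairs are
#' sampled with a common quantile by default (see [sample_parameter_set()]).
#'
#' @param model a [cea_model()] fit supplying parameters, settings and the
#'   willingness-to-pay threshold.
#' @param n number of Monte Carlo draws (default 10,000).
#' @param seed master seed; each draw uses an independent substream derived
#'   from it, so increasing \code{n} extends the draw sequence without
#'   reshuffling earlier draws.
#' @param correlated_pairs passed to [sample_parameter_set()].
#' @return A \code{cea_psa} object: \code{draws} (a data frame with
#'   per-draw costs and QALYs of both strategies and the incrementals),
#'   \code{n}, \code{seed}, \code{wtp}.
#' @examples
#' m <- cea_model()
#' psa <- run_psa(m, n = 200, seed = 7)
#' summary(psa)
#' @export
run_psa <- function(model, n = 10000, seed = 1, correlated_pairs = TRUE) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  params <- model$params
  settings <- model$settings
  cost_i <- qaly_i <- cost_p <- qaly_p <- numeric(n)
  ss <- make_sampler_set(params, correlated_pairs)
  for (i in seq_len(n)) {
    set.seed(as.integer(draw_seed(seed, i)))
    drawn <- params
    values <- draw_values(ss)
    drawn[names(values)] <- values
    class(drawn) <- "cea_parameters"
    oi <- run_strategy("internet", drawn, settings, keep_trace = FALSE)
    op <- run_strategy("in_person", drawn, settings, keep_trace = FALSE)
    cost_i[i] <- oi$total_cost
    qaly_i[i] <- oi$total_qaly
    cost_p[i] <- op$total_cost
    qaly_p[i] <- op$total_qaly
  }
  draws <- data.frame(
    draw = seq_len(n),
    cost_internet = cost_i, qaly_internet = qaly_i,
    cost_inperson = cost_p, qaly_inperson = qaly_p,
    d_cost = cost_i - cost_p, d_qaly = qaly_i - qaly_p
  )
  structure(list(draws = draws, n = n, seed = seed, wtp = model$wtp,
                 correlated_pairs = correlated_pairs),
            class = "cea_psa")
}

#' Fraction of draws in which the intervention is cost-effective
#'
#' Applies the same acceptance rule as [is_cost_effective()] to every draw.
#'
#' @param psa a \code{cea_psa} object.
#' @param wtp willingness-to-pay threshold; defaults to the model's.
#' @return A proportion in [0, 1].
#' @export
acceptance_fraction <- function(psa, wtp = psa$wtp) {
  if (wtp < 0) stop("wtp must be non-negative", call. = FALSE)
  mean(grid_verdict(psa$draws$d_cost, psa$draws$d_qaly, wtp))
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa a \code{cea_psa} object.
#' @param wtp_grid non-negative willingness-to-pay values; default 0 to
#'   twice the model threshold in 50 steps.
#' @return A data frame with columns \code{wtp} and \code{probability}.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  if (is.null(wtp_grid))
    wtp_grid <- seq(0, 2 * psa$wtp, length.out = 51L)
  if (!length(wtp_grid) || any(wtp_grid < 0))
    stop("wtp_grid must be non-empty and non-negative", call. = FALSE)
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(w)
               acceptance_fraction(psa, w), numeric(1)))
}

#' @export
summary.cea_psa <- function(object, level = 0.95, method = c("percentile", "normal"),
                            ...) {
  method <- match.arg(method)
  d <- object$draws
  a <- (1 - level) / 2
  ci <- function(x) {
    if (method == "percentile") unname(stats::quantile(x, c(a, 1 - a)))
    else mean(x) + stats::qnorm(c(a, 1 - a)) * stats::sd(x)
  }
  se_mean <- function(x) stats::sd(x) / sqrt(length(x))
  saving <- -d$d_cost
  structure(list(
    n = object$n,
    mean_cost_saving = mean(saving),
    se_mean_cost_saving = se_mean(saving),
    ci_mean_cost_saving = mean(saving) + c(-1, 1) * stats::qnorm(1 - a) * se_mean(saving),
    ci_cost_saving = ci(saving),
    mean_d_qaly = mean(d$d_qaly),
    se_mean_d_qaly = se_mean(d$d_qaly),
    ci_mean_d_qaly = mean(d$d_qaly) + c(-1, 1) * stats::qnorm(1 - a) * se_mean(d$d_qaly),
    ci_d_qaly = ci(d$d_qaly),
    frac_cost_saving = mean(d$d_cost < 0),
    frac_qaly_gain = mean(d$d_qaly > 0),
    frac_cost_effective = acceptance_fraction(object),
    wtp = object$wtp,
    level = level,
    method = method
  ), class = "summary.cea_psa")
}

#' @export
print.summary.cea_psa <- function(x, ...) {
  cat(sprintf("PSA over %d draws (WTP $%s/QALY)\n", x$n,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  mean cost saving: $%.1f (%.0f%% CI of mean %.1f-%.1f)\n",
              x$mean_cost_saving, 100 * x$level,
              x$ci_mean_cost_saving[1], x$ci_mean_cost_saving[2]))
  cat(sprintf("  mean QALY gain:   %.5f (%.0f%% CI of mean %.5f-%.5f)\n",
              x$mean_d_qaly, 100 * x$level,
              x$ci_mean_d_qaly[1], x$ci_mean_d_qaly[2]))
  cat(sprintf("  cost-saving draws:    %.2f%%\n", 100 * x$frac_cost_saving))
  cat(sprintf("  QALY-gaining draws:   %.2f%%\n", 100 * x$frac_qaly_gain))
  cat(sprintf("  cost-effective draws: %.2f%%\n", 100 * x$frac_cost_effective))
  invisible(x)
}

#' @export
print.cea_psa <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Plot a probabilistic sensitivity analysis
#'
#' @param x a \code{cea_psa} object.
#' @param type \code{"plane"} for the incremental cost-effectiveness
#'   scatter (with the WTP line), \code{"ceac"} for the acceptability
#'   curve.
#' @param ... passed to the underlying plotting function.
#' @export
plot.cea_psa <- function(x, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    d <- x$draws
    graphics::plot(d$d_qaly, d$d_cost, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "incremental QALYs", ylab = "incremental cost (US $)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey50")
    graphics::abline(a = 0, b = x$wtp, lty = 2)
  } else {
    cv <- ceac(x)
    graphics::plot(cv$wtp, cv$probability, type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "willingness to pay (US $/QALY)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(v = x$wtp, lty = 2)
  }
  invisible(x)
}
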