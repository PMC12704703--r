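# Pairwise cost-effectiveness comparison: incremental outcomes, ICER,
# dominance and the willingness-to-pay acceptance rule.

#' Compare two strategy outcomes
#'
#' @param intervention,comparator \code{cea_outcome} objects evaluated on
#'   the same parameter set (conventionally the internet strategy against
#'   the in-person strategy).
#' @return A \code{cea_comparison}: incremental cost (\code{d_cost}),
#'   QALYs (\code{d_qaly}) and dropout probability (\code{d_dropout}); the
#'   ICER \code{d_cost / d_qaly} (\code{NA} when \code{d_qaly} is zero —
#'   never a division error); and the dominance flag (lower cost and higher
#'   QALYs).  A negative ICER is reported as computed, with the dominance
#'   flag alongside.
#' @examples
#' p <- load_parameters()
#' cmp <- compare_strategies(run_strategy("internet", p),
#'                           run_strategy("in_person", p))
#' cmp$icer
#' @export
compare_strategies <- function(intervention, comparator) {
  d_cost <- intervention$total_cost - comparator$total_cost
  d_qaly <- intervention$total_qaly - comparator$total_qaly
  d_dropout <- intervention$dropout_prob - comparator$dropout_prob
  structure(list(
    d_cost = d_cost,
    d_qaly = d_qaly,
    d_dropout = d_dropout,
    icer = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
    dominant = d_cost < 0 && d_qaly > 0,
    intervention = intervention$strategy,
    comparator = comparator$strategy
  ), class = "cea_comparison")
}

#' Net monetary benefit of the intervention
#'
#' @param cmp a \code{cea_comparison}.
#' @param wtp willingness-to-pay threshold (US $ per QALY).
#' @return \code{d_qaly * wtp - d_cost}.
#' @export
net_monetary_benefit <- function(cmp, wtp) {
  cmp$d_qaly * wtp - cmp$d_cost
}

#' Cost-effectiveness verdict at a willingness-to-pay threshold
#'
#' The intervention is accepted as cost-effective if it is dominant (less
#' costly, more effective), or if it is more costly and more effective with
#' an ICER below the threshold.  It is rejected when dominated.  In the
#' remaining quadrant (less costly, less effective) — which the two-branch
#' rule does not cover — the sign of the net monetary benefit decides, so
#' the verdict is defined for every probabilistic draw.
#'
#' @param cmp a \code{cea_comparison}.
#' @param wtp willingness-to-pay threshold (US $ per QALY), non-negative.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' p <- load_parameters()
#' cmp <- compare_strategies(run_strategy("internet", p),
#'                           run_strategy("in_person", p))
#' is_cost_effective(cmp, wtp = 0)   # dominant, so TRUE at any threshold
#' @export
is_cost_effective <- function(cmp, wtp) {
  if (wtp < 0) stop("wtp must be non-negative", call. = FALSE)
  if (cmp$dominant) return(TRUE)
  if (cmp$d_cost >= 0 && cmp$d_qaly <= 0) return(FALSE)  # dominated (or equal)
  if (cmp$d_cost > 0 && cmp$d_qaly > 0)
    return(cmp$d_cost / cmp$d_qaly < wtp)
  # south-west quadrant: cheaper and less effective
  net_monetary_benefit(cmp, wtp) > 0
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost:    $%.2f\n", x$d_cost))
  cat(sprintf("  incremental QALYs:   %.4f\n", x$d_qaly))
  cat(sprintf("  incremental dropout: %.4f%%\n", 100 * x$d_dropout))
  if (is.na(x$icer)) cat("  ICER: undefined (no QALY difference)\n")
  else cat(sprintf("  ICER: $%.0f per QALY%s\n", x$icer,
                   if (x$dominant) " (dominant)" else ""))
  invisible(x)
}
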