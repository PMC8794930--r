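# Cost-effectiveness comparison and the front-door model function.

#' Compare two strategy results
#'
#' Computes incremental cost and effectiveness (intervention minus
#' comparator), dominance, the ICER where defined, and net monetary
#' benefit (NMB = WTP x QALYs - cost) for each strategy. The intervention
#' dominates when it is cheaper and more effective; when incremental
#' effectiveness is exactly zero but costs differ, dominance is reported by
#' cost alone (cost minimisation) and the ICER left undefined.
#'
#' @param comparator,intervention `strategy_result` objects (or lists with
#'   `total_cost` and `total_qalys`).
#' @param wtp Willingness to pay, dollars per QALY.
#' @return A `cea_comparison` object: `delta_cost`, `delta_effect`, `icer`
#'   (`NA` when undefined), `dominance` (one of `"intervention_dominant"`,
#'   `"comparator_dominant"`, `"none"`), and per-strategy `nmb`.
#' @export
compare_strategies <- function(comparator, intervention, wtp = 100000) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qalys - comparator$total_qalys
  dominance <- if (dc < 0 && de > 0) "intervention_dominant"
  else if (dc > 0 && de < 0) "comparator_dominant"
  else if (de == 0 && dc != 0) {
    if (dc < 0) "intervention_dominant" else "comparator_dominant"
  } else "none"
  icer <- if (dominance == "none" && de != 0) dc / de else NA_real_
  nmb <- c(comparator = wtp * comparator$total_qalys - comparator$total_cost,
           intervention = wtp * intervention$total_qalys - intervention$total_cost)
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 dominance = dominance, nmb = nmb, wtp = wtp,
                 comparator = list(name = comparator$strategy %||% "comparator",
                                   total_cost = comparator$total_cost,
                                   total_qalys = comparator$total_qalys),
                 intervention = list(name = intervention$strategy %||% "intervention",
                                     total_cost = intervention$total_cost,
                                     total_qalys = intervention$total_qalys)),
            class = "cea_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full cost-effectiveness model
#'
#' The main entry point: builds both diagnostic strategies, converts each
#' through the decision tree into a Markov starting cohort, runs the
#' 30-year cohort model for each, and compares them at the stated
#' willingness to pay.
#'
#' @param params Model inputs; defaults to [default_parameters()].
#' @param lt Annual life table for background mortality; defaults to the
#'   package's synthetic US-like table from [synthetic_life_table()].
#' @param wtp Willingness to pay (dollars/QALY); defaults to `params$wtp`.
#' @param reward_timing Within-cycle reward accrual convention, passed to
#'   [run_cohort()]: `"end"` (default), `"begin"`, or `"half_cycle"`.
#' @return A `stroke_cea` object: per-strategy `strategy_result`s, the
#'   `cea_comparison`, and the inputs used.
#' @examples
#' fit <- cea_markov()
#' fit
#' summary(fit)
#' @export
cea_markov <- function(params = default_parameters(),
                       lt = synthetic_life_table(),
                       wtp = params$wtp,
                       reward_timing = c("end", "begin", "half_cycle")) {
  reward_timing <- match.arg(reward_timing)
  validate_parameters(params)
  strat <- default_strategies(params)
  ages <- params$start_age + seq_len(params$n_cycles) - 1
  matrices <- lapply(ages, function(a) build_transition_matrix(params, lt, a))
  results <- lapply(strat, function(s)
    run_cohort_with_matrices(initial_cohort(s, params), params, matrices,
                             reward_timing))
  comparison <- compare_strategies(results$no_additional_imaging,
                                   results$additional_short_protocol_mri,
                                   wtp = wtp)
  structure(list(results = results, comparison = comparison,
                 params = params, life_table = lt,
                 reward_timing = reward_timing),
            class = "stroke_cea")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Incremental cost-effectiveness (intervention minus comparator)\n")
  cat(sprintf("  delta cost:   $%.0f\n", x$delta_cost))
  cat(sprintf("  delta effect: %.4f QALYs\n", x$delta_effect))
  if (!is.na(x$icer)) cat(sprintf("  ICER: $%.0f per QALY\n", x$icer))
  cat(sprintf("  dominance: %s\n", x$dominance))
  cat(sprintf("  NMB at $%s/QALY: comparator $%.0f, intervention $%.0f\n",
              format(x$wtp, big.mark = ","), x$nmb["comparator"],
              x$nmb["intervention"]))
  invisible(x)
}

#' @export
print.stroke_cea <- function(x, ...) {
  cat("Cost-effectiveness of supplemental short-protocol brain MRI\n")
  cat(sprintf("  cohort age %d, %d yearly cycles, %.0f%% discounting\n\n",
              x$params$start_age, x$params$n_cycles,
              100 * x$params$discount_rate))
  print(summary(x))
  invisible(x)
}

#' Base-case results table
#'
#' @param object A `stroke_cea` fit.
#' @param ... Unused.
#' @return A data frame with one row per strategy plus a delta row:
#'   cumulative discounted cost, cumulative QALYs, and the dominance
#'   interpretation.
#' @export
summary.stroke_cea <- function(object, ...) {
  comp <- object$comparison
  interp <- switch(comp$dominance,
    intervention_dominant = c("Dominated strategy", "Dominant strategy"),
    comparator_dominant = c("Dominant strategy", "Dominated strategy"),
    none = if (is.na(comp$icer)) c("", "")
           else c("", sprintf("ICER $%.0f/QALY", comp$icer)))
  out <- data.frame(
    strategy = c(comp$comparator$name, comp$intervention$name, "delta"),
    cumulative_cost = c(comp$comparator$total_cost,
                        comp$intervention$total_cost, comp$delta_cost),
    cumulative_effectiveness = c(comp$comparator$total_qalys,
                                 comp$intervention$total_qalys,
                                 comp$delta_effect),
    interpretation = c(interp, comp$dominance),
    stringsAsFactors = FALSE)
  class(out) <- c("summary.stroke_cea", "data.frame")
  out
}

#' @export
print.summary.stroke_cea <- function(x, ...) {
  disp <- x
  disp$cumulative_cost <- sprintf("$%s", format(round(disp$cumulative_cost),
                                                big.mark = ",", trim = TRUE))
  disp$cumulative_effectiveness <-
    sprintf("%.2f QALYs", x$cumulative_effectiveness)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Coefficients of a fitted cost-effectiveness model
#'
#' @param object A `stroke_cea` fit.
#' @param ... Unused.
#' @return Named numeric vector of the model input parameters.
#' @export
coef.stroke_cea <- function(object, ...) {
  unlist(unclass(object$params))
}

#' Plot a fitted cost-effectiveness model
#'
#' `type = "trace"` draws state occupancy over cycles for both strategies;
#' `type = "cost"` the cumulative discounted cost curves.
#'
#' @param x A `stroke_cea` fit.
#' @param type `"trace"` or `"cost"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stroke_cea <- function(x, type = c("trace", "cost"), ...) {
  type <- match.arg(type)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    if (type == "trace") {
      graphics::matplot(0:x$params$n_cycles, r$trace$occupancy, type = "l",
                        lty = 1, xlab = "cycle (years)",
                        ylab = "state occupancy", main = nm, ...)
      graphics::legend("right", legend = health_states(), col = 1:7,
                       lty = 1, cex = 0.6, bty = "n")
    } else {
      graphics::plot(seq_along(r$trace$cycle_costs),
                     r$upfront_cost + cumsum(r$trace$cycle_costs), type = "l",
                     xlab = "cycle (years)",
                     ylab = "cumulative discounted cost ($)", main = nm, ...)
    }
  }
  invisible(x)
}
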