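# Sensitivity analyses: one-way deterministic (tornado, ICER-vs-parameter
# curves) and probabilistic Monte Carlo over moment-matched beta/gamma
# parameter distributions.

# Distribution family per sampled parameter: beta for probabilities and
# utilities, gamma for costs and for the relative mortality risk (whose
# mean exceeds 1 and so admits no beta distribution). Structural settings
# (age, cycles, discounting, WTP) and boundary utilities/specificities are
# fixed. Untreated major-stroke risks are re-derived per draw, never
# sampled directly.
.psa_families <- c(
  prevalence_minor = "beta", sens_no_imaging = "beta", sens_mri = "beta",
  cost_ct = "gamma", cost_mri = "gamma", cost_acute_minor = "gamma",
  cost_acute_major = "gamma", cost_year_detected_minor = "gamma",
  cost_year_post_major = "gamma", utility_post_major = "beta",
  add_death_undetected = "beta", add_death_detected = "beta",
  rr_death_post_major = "gamma", risk_new_minor = "beta",
  detection_rate_undetected = "beta", risk_major_from_well = "beta",
  risk_major_detected_y1 = "beta", risk_major_detected_later = "beta",
  rrr_prophylaxis = "beta"
)

#' Moment-match a beta, gamma, or point-mass distribution
#'
#' Beta: with mean m and sd s, `nu = m(1-m)/s^2 - 1`, `shape1 = m nu`,
#' `shape2 = (1-m) nu`; requires `s^2 < m(1-m)`. Gamma: `shape = m^2/s^2`,
#' `scale = s^2/m`. Boundary means (0 or 1 for beta, 0 for gamma) have zero
#' feasible variance and are coerced to a point mass (`family = "fixed"`).
#'
#' @param family `"beta"`, `"gamma"`, or `"fixed"`.
#' @param mean Target mean.
#' @param sd Target standard deviation.
#' @return A list with `family` and its shape parameters (`shape1`/`shape2`
#'   for beta, `shape`/`scale` for gamma, `value` for fixed).
#' @export
moment_match <- function(family = c("beta", "gamma", "fixed"), mean, sd) {
  family <- match.arg(family)
  if (family == "beta" && (mean <= 0 || mean >= 1)) {
    if (mean %in% c(0, 1)) family <- "fixed"
    else stop("beta mean must lie in (0, 1), got ", mean)
  }
  if (family == "gamma" && mean <= 0) {
    if (mean == 0) family <- "fixed" else stop("gamma mean must be > 0")
  }
  switch(family,
    fixed = list(family = "fixed", value = mean),
    beta = {
      nu <- mean * (1 - mean) / sd^2 - 1
      if (nu <= 0)
        stop("infeasible spread for beta: sd^2 = ", sd^2,
             " >= mean(1-mean) = ", mean * (1 - mean))
      list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
    },
    gamma = list(family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean))
}

# Draw one value from a moment-matched spec using the session RNG.
.draw_one <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = stats::rbeta(1, spec$shape1, spec$shape2),
    gamma = stats::rgamma(1, shape = spec$shape, scale = spec$scale))
}

# One PSA parameter draw: every non-fixed parameter from its moment-matched
# distribution (sd = spread_cv * mean), untreated risks re-derived from the
# sampled treated risks and sampled rrr, truncated at 1 (a draw with rrr
# close to 1 can push treated/(1 - rrr) past certainty).
.sample_parameter_set <- function(params, spread_cv) {
  p <- unclass(params)
  for (nm in names(.psa_families)) {
    m <- p[[nm]]
    if (m == 0 || (.psa_families[[nm]] == "beta" && m == 1)) next
    spec <- moment_match(.psa_families[[nm]], m, spread_cv * m)
    p[[nm]] <- .draw_one(spec)
  }
  p$risk_major_undetected_y1 <-
    min(1, p$risk_major_detected_y1 / (1 - p$rrr_prophylaxis))
  p$risk_major_undetected_later <-
    min(1, p$risk_major_detected_later / (1 - p$rrr_prophylaxis))
  structure(p, class = "stroke_params")
}

#' Default one-way sensitivity ranges
#'
#' Cohort age 50-70, supplemental-MRI cost $155-$500, and no-imaging
#' sensitivity 0.40-0.80 use the ranges investigated in the deterministic
#' analysis; every other varied parameter spans +/-50% of its default,
#' truncated to validity (probabilities to `[0, 1]`, the risk reduction to
#' `[0, 0.9]` so the derived untreated risks stay below 1).
#'
#' @param params Base parameter set.
#' @return Data frame with columns `parameter`, `low`, `high`.
#' @export
default_dsa_ranges <- function(params = default_parameters()) {
  half <- function(nm, lo = 0, hi = Inf) {
    v <- params[[nm]]
    c(max(lo, 0.5 * v), min(hi, 1.5 * v))
  }
  rows <- list(
    start_age = c(50, 70),
    cost_mri = c(155, 500),
    sens_no_imaging = c(0.40, 0.80),
    prevalence_minor = half("prevalence_minor", hi = 1),
    sens_mri = half("sens_mri", hi = 1),
    cost_ct = half("cost_ct"),
    cost_acute_minor = half("cost_acute_minor"),
    cost_acute_major = half("cost_acute_major"),
    cost_year_detected_minor = half("cost_year_detected_minor"),
    cost_year_post_major = half("cost_year_post_major"),
    utility_post_major = half("utility_post_major", hi = 1),
    add_death_undetected = half("add_death_undetected", hi = 1),
    add_death_detected = half("add_death_detected", hi = 1),
    rr_death_post_major = half("rr_death_post_major"),
    risk_new_minor = half("risk_new_minor", hi = 1),
    detection_rate_undetected = half("detection_rate_undetected", hi = 1),
    risk_major_from_well = half("risk_major_from_well", hi = 1),
    risk_major_detected_y1 = half("risk_major_detected_y1", hi = 1),
    risk_major_detected_later = half("risk_major_detected_later", hi = 1),
    rrr_prophylaxis = c(max(0, 0.5 * params$rrr_prophylaxis),
                        min(0.9, 1.5 * params$rrr_prophylaxis)),
    discount_rate = half("discount_rate")
  )
  data.frame(parameter = names(rows),
             low = vapply(rows, `[`, numeric(1), 1),
             high = vapply(rows, `[`, numeric(1), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Incremental NMB of the MRI strategy for one parameter setting.
.eval_point <- function(params, lt, name, value, wtp) {
  p <- update_parameters(params, name, value)
  fit <- cea_markov(p, lt, wtp = wtp)
  c(inmb = unname(fit$comparison$nmb["intervention"] -
                    fit$comparison$nmb["comparator"]),
    dominant = fit$comparison$dominance == "intervention_dominant")
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each listed parameter is set to its low and high value with all others
#' at their base values; the outcome is the incremental net monetary
#' benefit (NMB) of the MRI strategy at the stated willingness to pay — a
#' single signed scalar whose sign encodes which strategy is preferred.
#' Entries are sorted by descending swing.
#'
#' @param params Base parameter set.
#' @param lt Life table.
#' @param ranges Data frame as produced by [default_dsa_ranges()].
#' @param wtp Willingness to pay; defaults to `params$wtp`.
#' @return A `tornado` data frame: `parameter`, `low`, `high`, `inmb_low`,
#'   `inmb_high`, `swing`, `dominant_throughout` (intervention dominant at
#'   both endpoints).
#' @export
one_way_dsa <- function(params = default_parameters(),
                        lt = synthetic_life_table(),
                        ranges = default_dsa_ranges(params),
                        wtp = params$wtp) {
  stopifnot(all(c("parameter", "low", "high") %in% names(ranges)),
            all(ranges$low <= ranges$high))
  res <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- .eval_point(params, lt, ranges$parameter[i], ranges$low[i], wtp)
    hi <- .eval_point(params, lt, ranges$parameter[i], ranges$high[i], wtp)
    data.frame(parameter = ranges$parameter[i],
               low = ranges$low[i], high = ranges$high[i],
               inmb_low = lo[["inmb"]], inmb_high = hi[["inmb"]],
               swing = abs(hi[["inmb"]] - lo[["inmb"]]),
               dominant_throughout = as.logical(lo[["dominant"]] && hi[["dominant"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' ICER (and dominance) along a grid of one parameter
#'
#' Evaluates the full model at each grid value of the named parameter,
#' holding all other inputs at their base values.
#'
#' @param params Base parameter set.
#' @param lt Life table.
#' @param name Parameter to vary.
#' @param grid Numeric vector of values.
#' @param wtp Willingness to pay.
#' @return Data frame: `value`, `delta_cost`, `delta_effect`, `icer`,
#'   `dominance`, `inmb`.
#' @export
icer_vs_parameter <- function(params = default_parameters(),
                              lt = synthetic_life_table(),
                              name, grid, wtp = params$wtp) {
  stopifnot(length(grid) >= 1)
  rows <- lapply(grid, function(v) {
    p <- update_parameters(params, name, v)
    comp <- cea_markov(p, lt, wtp = wtp)$comparison
    data.frame(value = v, delta_cost = comp$delta_cost,
               delta_effect = comp$delta_effect, icer = comp$icer,
               dominance = comp$dominance,
               inmb = unname(comp$nmb["intervention"] - comp$nmb["comparator"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the joint parameter uncertainty: each iteration draws
#' every sampled parameter from its moment-matched beta (probabilities,
#' utilities) or gamma (costs, relative risk) distribution with
#' `sd = spread_cv * mean`, re-derives the untreated major-stroke risks,
#' and evaluates both strategies on the shared transition matrices of that
#' draw. Identical `(seed, n_iterations, spread_cv)` reproduce the result
#' exactly.
#'
#' @param params Base parameter set (distribution means).
#' @param lt Life table.
#' @param n_iterations Number of Monte Carlo iterations (30,000 in the full
#'   analysis; smaller values for exploration).
#' @param seed Integer RNG seed.
#' @param spread_cv Coefficient of variation applied to every sampled
#'   parameter (default 0.2).
#' @param wtp Willingness to pay for the dominance/CEAC summaries.
#' @param wtp_grid Grid for the cost-effectiveness acceptability curve.
#' @return A `psa_result`: per-iteration cost/effect per strategy,
#'   `fraction_intervention_dominant`, mean costs/effects, and `ceac`
#'   points.
#' @export
run_psa <- function(params = default_parameters(),
                    lt = synthetic_life_table(),
                    n_iterations = 30000, seed = 1, spread_cv = 0.2,
                    wtp = params$wtp,
                    wtp_grid = seq(0, 200000, by = 20000)) {
  stopifnot(n_iterations >= 1, spread_cv > 0)
  validate_parameters(params)
  set.seed(seed)
  cost_c <- cost_i <- eff_c <- eff_i <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    p <- .sample_parameter_set(params, spread_cv)
    strat <- default_strategies(p)
    ages <- p$start_age + seq_len(p$n_cycles) - 1
    mats <- lapply(ages, function(a) build_transition_matrix(p, lt, a))
    rc <- run_cohort_with_matrices(initial_cohort(strat[[1]], p), p, mats)
    ri <- run_cohort_with_matrices(initial_cohort(strat[[2]], p), p, mats)
    cost_c[it] <- rc$total_cost; eff_c[it] <- rc$total_qalys
    cost_i[it] <- ri$total_cost; eff_i[it] <- ri$total_qalys
  }
  iterations <- data.frame(
    iteration = seq_len(n_iterations),
    cost_comparator = cost_c, effect_comparator = eff_c,
    cost_intervention = cost_i, effect_intervention = eff_i)
  out <- structure(list(iterations = iterations, seed = seed,
                        n_iterations = n_iterations, spread_cv = spread_cv,
                        wtp = wtp,
                        fraction_intervention_dominant =
                          mean(cost_i < cost_c & eff_i > eff_c),
                        mean_cost = c(comparator = mean(cost_c),
                                      intervention = mean(cost_i)),
                        mean_effect = c(comparator = mean(eff_c),
                                        intervention = mean(eff_i))),
                   class = "psa_result")
  out$ceac <- ceac(out, wtp_grid)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which the intervention's net monetary benefit exceeds the comparator's.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty numeric vector of WTP values.
#' @return Data frame with columns `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  it <- psa$iterations
  prob <- vapply(wtp_grid, function(w) {
    mean(w * it$effect_intervention - it$cost_intervention >
           w * it$effect_comparator - it$cost_comparator)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d, cv %.2f)\n",
              x$n_iterations, x$seed, x$spread_cv))
  cat(sprintf("  mean cost:   comparator $%.0f, intervention $%.0f\n",
              x$mean_cost["comparator"], x$mean_cost["intervention"]))
  cat(sprintf("  mean effect: comparator %.4f, intervention %.4f QALYs\n",
              x$mean_effect["comparator"], x$mean_effect["intervention"]))
  cat(sprintf("  intervention dominant in %.1f%% of iterations\n",
              100 * x$fraction_intervention_dominant))
  invisible(x)
}

#' Plot a PSA cloud on the cost-effectiveness plane
#'
#' @param x A `psa_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psa_result <- function(x, ...) {
  it <- x$iterations
  de <- it$effect_intervention - it$effect_comparator
  dc <- it$cost_intervention - it$cost_comparator
  graphics::plot(de, dc, pch = ".", xlab = "incremental QALYs",
                 ylab = "incremental cost ($)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(0, x$wtp, lty = 2)
  invisible(x)
}

#' Plot a tornado diagram
#'
#' @param x A `tornado` data frame from [one_way_dsa()].
#' @param ... Unused.
#' @export
plot.tornado <- function(x, ...) {
  y <- rev(seq_len(nrow(x)))
  base <- stats::median(c(x$inmb_low, x$inmb_high))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(range(c(x$inmb_low, x$inmb_high)), range(y) + c(-0.5, 0.5),
                 type = "n", yaxt = "n", xlab = "incremental NMB ($)",
                 ylab = "", main = "One-way sensitivity")
  graphics::segments(x$inmb_low, y, x$inmb_high, y, lwd = 8, col = "steelblue")
  graphics::axis(2, at = y, labels = x$parameter, las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
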