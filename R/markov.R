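# Markov cohort engine: seven health states, yearly cycles, age-indexed
# transition matrices, discounted cost and QALY accrual.
#
# States: well (no indication for prophylaxis), undetected_y1 /
# undetected_post (minor stroke missed at evaluation; first year vs later
# tunnel), detected_y1 / detected_post (minor stroke under secondary
# prophylaxis), post_major (after major stroke, average mRS 4), dead
# (absorbing). The Y1/POST split realises the first-year vs later-year
# recurrence risks as tunnel states anchored to the stroke event.

#' Health-state labels of the Markov model
#'
#' @return Character vector of the 7 state names, in matrix order.
#' @export
health_states <- function() {
  c("well", "undetected_y1", "undetected_post", "detected_y1",
    "detected_post", "post_major", "dead")
}

#' Discount factor for cycle t
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param t Cycle index (0 = model entry), vectorised.
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' One-cycle transition matrix at a given age
#'
#' Competing risks are resolved in a fixed order that guarantees a
#' row-stochastic matrix without renormalisation: death first; among
#' survivors, major stroke; among survivors without a major stroke,
#' detection (from the undetected states) or a new minor stroke (from
#' well). Background mortality comes from the life table; the undetected
#' and detected minor-stroke states carry additive excess mortality, the
#' post-major state multiplicative (relative-risk) excess mortality.
#' Detection from either undetected tunnel routes to `detected_post`
#' because the index stroke is by then more than a year old. The dead row
#' is the identity.
#'
#' @param params A `stroke_params` object.
#' @param lt A `life_table` covering `age`.
#' @param age Age in years governing this cycle's background mortality.
#' @return A 7x7 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(params, lt, age) {
  q <- annual_death_prob(lt, age)
  s <- health_states()
  M <- matrix(0, 7, 7, dimnames = list(s, s))

  # well: background mortality only
  d <- q
  surv <- 1 - d
  M["well", "dead"] <- d
  M["well", "post_major"] <- surv * params$risk_major_from_well
  M["well", "undetected_y1"] <-
    surv * (1 - params$risk_major_from_well) * params$risk_new_minor
  M["well", "well"] <-
    surv * (1 - params$risk_major_from_well) * (1 - params$risk_new_minor)

  # undetected minor stroke, first year then later years
  d <- adjust_mortality_additive(q, params$add_death_undetected)
  surv <- 1 - d
  for (st in c("undetected_y1", "undetected_post")) {
    risk <- if (st == "undetected_y1") params$risk_major_undetected_y1
            else params$risk_major_undetected_later
    M[st, "dead"] <- d
    M[st, "post_major"] <- surv * risk
    nostroke <- surv * (1 - risk)
    M[st, "detected_post"] <- nostroke * params$detection_rate_undetected
    M[st, "undetected_post"] <- nostroke * (1 - params$detection_rate_undetected)
  }

  # detected minor stroke under secondary prophylaxis
  d <- adjust_mortality_additive(q, params$add_death_detected)
  surv <- 1 - d
  M["detected_y1", "dead"] <- d
  M["detected_y1", "post_major"] <- surv * params$risk_major_detected_y1
  M["detected_y1", "detected_post"] <- surv * (1 - params$risk_major_detected_y1)
  M["detected_post", "dead"] <- d
  M["detected_post", "post_major"] <- surv * params$risk_major_detected_later
  M["detected_post", "detected_post"] <- surv * (1 - params$risk_major_detected_later)

  # after major stroke: elevated mortality, no further modelled strokes
  d <- adjust_mortality_relative(q, params$rr_death_post_major)
  M["post_major", "dead"] <- d
  M["post_major", "post_major"] <- 1 - d

  M["dead", "dead"] <- 1

  if (any(M < 0))
    stop("transition matrix has a negative entry; invalid parameters")
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  M
}

# Iterate the cohort through pre-built matrices (shared by run_cohort and
# the PSA, where both strategies reuse one matrix sequence per draw).
run_cohort_with_matrices <- function(initial, params, matrices,
                                     reward_timing = c("end", "begin",
                                                       "half_cycle")) {
  reward_timing <- match.arg(reward_timing)
  n <- params$n_cycles
  states <- health_states()
  pm <- match("post_major", states)
  occ <- matrix(0, n + 1, 7, dimnames = list(0:n, states))
  occ[1, ] <- initial$state_distribution
  cycle_costs <- cycle_qalys <- numeric(n)
  alive_u1 <- c("well", "undetected_y1", "undetected_post",
                "detected_y1", "detected_post")
  for (t in seq_len(n)) {
    M <- matrices[[t]]
    occ[t + 1, ] <- occ[t, ] %*% M
    # flow into post_major from other living states (one-time acute cost)
    entrants <- sum(occ[t, -pm] * M[-pm, pm])
    w <- switch(reward_timing,
                end = occ[t + 1, ],
                begin = occ[t, ],
                half_cycle = (occ[t, ] + occ[t + 1, ]) / 2)
    # state rewards valued at the occupancy above; under "begin" they are
    # discounted at the cycle start (t - 1), otherwise at the cycle end.
    df_state <- discount_factor(params$discount_rate,
                                if (reward_timing == "begin") t - 1 else t)
    df_end <- discount_factor(params$discount_rate, t)
    cost <- df_state *
      ((w["detected_y1"] + w["detected_post"]) * params$cost_year_detected_minor +
         w["post_major"] * params$cost_year_post_major) +
      df_end * entrants * params$cost_acute_major
    qaly <- df_state * (params$utility_no_major * sum(w[alive_u1]) +
                          params$utility_post_major * w["post_major"])
    cycle_costs[t] <- cost
    cycle_qalys[t] <- qaly
  }
  trace <- structure(list(occupancy = occ, cycle_costs = cycle_costs,
                          cycle_qalys = cycle_qalys),
                     class = "cohort_trace")
  structure(list(total_cost = initial$upfront_cost + sum(cycle_costs),
                 total_qalys = sum(cycle_qalys),
                 upfront_cost = initial$upfront_cost,
                 strategy = initial$strategy,
                 trace = trace),
            class = "strategy_result")
}

#' Run the Markov cohort model for one strategy
#'
#' Starting from the decision-tree distribution, the cohort is advanced
#' `n_cycles` times; the matrix governing cycle `t` uses age
#' `start_age + t - 1`. Each cycle accrues, discounted at that cycle:
#' yearly post-stroke care costs for the detected states, yearly care costs
#' for the post-major state, a one-time acute major-stroke cost for new
#' entrants into the post-major state, and utility-weighted life years.
#' Upfront (cycle-0) costs enter undiscounted.
#'
#' `reward_timing` controls where within the cycle state rewards are
#' valued: `"end"` (default) uses end-of-cycle occupancy discounted at the
#' cycle end; `"begin"` uses start-of-cycle occupancy discounted at the
#' cycle start, the accrual convention of common decision-modelling
#' software, which credits each member alive at a cycle's start with that
#' cycle's reward; `"half_cycle"` uses the mean of start and end occupancy
#' (half-cycle correction). The one-time acute major-stroke cost is always
#' discounted at the cycle of entry.
#'
#' @param initial An `initial_cohort` from [initial_cohort()].
#' @param params A `stroke_params` object.
#' @param lt A `life_table` covering ages `start_age` through
#'   `start_age + n_cycles - 1` (clamping applies beyond the table end).
#' @param reward_timing `"end"`, `"begin"`, or `"half_cycle"`.
#' @return A `strategy_result`: `total_cost`, `total_qalys` (both
#'   discounted), `upfront_cost`, and a `cohort_trace` with the
#'   `(n_cycles + 1) x 7` occupancy matrix and per-cycle discounted
#'   cost/QALY streams.
#' @export
run_cohort <- function(initial, params, lt,
                       reward_timing = c("end", "begin", "half_cycle")) {
  validate_parameters(params)
  ages <- params$start_age + seq_len(params$n_cycles) - 1
  matrices <- lapply(ages, function(a) build_transition_matrix(params, lt, a))
  run_cohort_with_matrices(initial, params, matrices, match.arg(reward_timing))
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s': total discounted cost $%s, %.4f QALYs (upfront $%.2f)\n",
              x$strategy, format(round(x$total_cost), big.mark = ","),
              x$total_qalys, x$upfront_cost))
  invisible(x)
}
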