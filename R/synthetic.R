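# Synthetic inputs: a parametric adult life table standing in for national
# period life tables, perturbed parameter fixtures, and an individual-level
# microsimulation used to validate the cohort engine.

#' Synthetic adult life table from a Gompertz-Makeham mortality law
#'
#' Annual death probabilities are generated as
#' `qx(a) = 1 - exp(-(makeham + scale * exp(growth * (a - min_age))))`:
#' a constant background hazard plus an exponentially age-increasing
#' component, the classical three-parameter description of adult human
#' mortality. The defaults are calibrated once to the magnitude of recent
#' US period mortality (qx near 0.012 at age 61 rising to about 0.15 by
#' age 90); they stand in for a national table, which the user can supply
#' instead via [read_life_table()] for exact reproduction of published
#' dollar/QALY figures.
#'
#' @param min_age First tabulated age (reference age of the hazard scale).
#' @param max_age Last tabulated age.
#' @param makeham Age-independent baseline annual hazard (>= 0).
#' @param scale Hazard at `min_age` from the age-dependent component (>= 0).
#' @param growth Log-hazard increase per year of age (> 0).
#' @return A `life_table` over `min_age:max_age`. By construction every qx
#'   lies in `[0, 1)`.
#' @export
synthetic_life_table <- function(min_age = 50, max_age = 110,
                                 makeham = 5e-4, scale = 4.3e-3,
                                 growth = 0.092) {
  stopifnot(min_age < max_age, makeham >= 0, scale >= 0, growth > 0)
  ages <- seq.int(min_age, max_age)
  hazard <- makeham + scale * exp(growth * (ages - min_age))
  life_table(ages, 1 - exp(-hazard))
}

#' Individual-level microsimulation of the cohort model
#'
#' An independent implementation of the same state, transition and reward
#' rules as [run_cohort()], by sequential event sampling per individual and
#' cycle in the engine's composition order (death, then major stroke, then
#' detection or new minor stroke). It shares no transition-matrix code with
#' the cohort engine, so agreement between the two is a genuine
#' cross-check. Returns Monte Carlo estimates of the discounted totals with
#' standard errors.
#'
#' @param initial An `initial_cohort`.
#' @param params A `stroke_params` object.
#' @param lt A `life_table`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer RNG seed; identical seeds give identical estimates.
#' @return A `microsim_result`: `total_cost`, `total_qalys` (means over
#'   individuals, including the deterministic upfront cost), `se_cost`,
#'   `se_qalys`, `n`.
#' @export
microsim_oracle <- function(initial, params, lt, n_individuals = 200000,
                            seed = 1) {
  stopifnot(n_individuals >= 1)
  validate_parameters(params)
  set.seed(seed)
  states <- health_states()
  state <- sample.int(7, n_individuals, replace = TRUE,
                      prob = initial$state_distribution)
  # indices: 1 well, 2 undetected_y1, 3 undetected_post, 4 detected_y1,
  # 5 detected_post, 6 post_major, 7 dead
  cost <- rep(initial$upfront_cost, n_individuals)
  qaly <- numeric(n_individuals)
  for (t in seq_len(params$n_cycles)) {
    age <- params$start_age + t - 1
    q <- annual_death_prob(lt, age)
    df <- (1 + params$discount_rate)^(-t)
    u_death <- stats::runif(n_individuals)
    u_major <- stats::runif(n_individuals)
    u_second <- stats::runif(n_individuals)

    p_death <- c(q,
                 min(1, q + params$add_death_undetected),
                 min(1, q + params$add_death_undetected),
                 min(1, q + params$add_death_detected),
                 min(1, q + params$add_death_detected),
                 min(1, q * params$rr_death_post_major),
                 1)[state]
    p_major <- c(params$risk_major_from_well,
                 params$risk_major_undetected_y1,
                 params$risk_major_undetected_later,
                 params$risk_major_detected_y1,
                 params$risk_major_detected_later,
                 0, 0)[state]

    died <- state != 7L & u_death < p_death
    major <- state != 7L & !died & u_major < p_major

    new_state <- state
    new_state[died] <- 7L
    new_state[major] <- 6L
    rest <- state != 7L & !died & !major
    # well survivors: a new minor stroke starts the undetected tunnel
    i <- rest & state == 1L
    new_state[i] <- ifelse(u_second[i] < params$risk_new_minor, 2L, 1L)
    # undetected survivors: yearly detection, else the post-year-1 tunnel
    i <- rest & (state == 2L | state == 3L)
    new_state[i] <- ifelse(u_second[i] < params$detection_rate_undetected, 5L, 3L)
    # detected survivors leave the first-year tunnel
    new_state[rest & state == 4L] <- 5L
    # detected_post (5) and post_major (6) survivors stay put

    entrant <- new_state == 6L & state != 6L
    cost <- cost + df * (
      (new_state == 4L | new_state == 5L) * params$cost_year_detected_minor +
      (new_state == 6L) * params$cost_year_post_major +
      entrant * params$cost_acute_major)
    qaly <- qaly + df * (
      (new_state <= 5L) * params$utility_no_major +
      (new_state == 6L) * params$utility_post_major)
    state <- new_state
  }
  structure(list(total_cost = mean(cost), total_qalys = mean(qaly),
                 se_cost = stats::sd(cost) / sqrt(n_individuals),
                 se_qalys = stats::sd(qaly) / sqrt(n_individuals),
                 n = n_individuals, seed = seed,
                 strategy = initial$strategy),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation (%d individuals, seed %d): cost $%.2f (SE %.2f), %.4f QALYs (SE %.5f)\n",
              x$n, x$seed, x$total_cost, x$se_cost, x$total_qalys, x$se_qalys))
  invisible(x)
}

#' Perturbed parameter sets for testing
#'
#' Draws validated parameter sets by the probabilistic-sensitivity-analysis
#' sampling rules (moment-matched beta/gamma with `sd = spread_cv * mean`,
#' untreated risks re-derived per draw).
#'
#' @param params Base parameter set (distribution means).
#' @param n Number of sets.
#' @param seed Integer RNG seed.
#' @param spread_cv Coefficient of variation (default 0.2).
#' @return A list of `n` `stroke_params` objects.
#' @export
fixture_parameter_sets <- function(params = default_parameters(), n = 5,
                                   seed = 1, spread_cv = 0.2) {
  stopifnot(n >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- .sample_parameter_set(params, spread_cv)
    validate_parameters(p)
    p
  })
}
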