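# Shared fixtures: tiny life tables and degenerate parameter sets built in
# code at test time.

# flat annual mortality across an age range
flat_life_table <- function(q, ages = 50:110) life_table(ages, rep(q, length(ages)))

# parameters with every stroke/detection/excess-death risk switched off
inert_parameters <- function(...) {
  stroke_parameters(
    risk_new_minor = 0, detection_rate_undetected = 0,
    risk_major_from_well = 0, risk_major_detected_y1 = 0,
    risk_major_detected_later = 0, add_death_undetected = 0,
    add_death_detected = 0, rr_death_post_major = 1, ...)
}

# a cohort starting wholly in one state with no upfront cost
single_state_cohort <- function(state) {
  dist <- stats::setNames(numeric(7), health_states())
  dist[state] <- 1
  structure(list(state_distribution = dist, upfront_cost = 0,
                 strategy = paste0("all_", state)),
            class = "initial_cohort")
}
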