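# Diagnostic decision tree: converts a strategy's diagnostic performance and
# the minor-stroke prevalence into the Markov starting distribution and the
# cycle-0 upfront cost per patient.

#' Define a diagnostic strategy
#'
#' @param name Strategy label.
#' @param sensitivity Probability a minor stroke present at evaluation is
#'   detected.
#' @param specificity Probability a patient without minor stroke is not
#'   falsely labelled; the model only supports 1 (no false positives can
#'   occur in this setting).
#' @param imaging_costs Numeric vector of per-patient imaging costs charged
#'   to everyone in the arm (CT alone, or CT plus supplemental MRI).
#' @return A `strategy_definition` object.
#' @export
strategy_definition <- function(name, sensitivity, specificity, imaging_costs) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must lie in [0, 1]")
  if (specificity < 0 || specificity > 1) stop("specificity must lie in [0, 1]")
  if (any(imaging_costs < 0)) stop("imaging costs must be non-negative")
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity, imaging_costs = imaging_costs),
            class = "strategy_definition")
}

#' The two modelled strategies
#'
#' Builds the comparator ("no_additional_imaging": head CT only, clinical
#' assessment detecting 60% of minor strokes by default) and the
#' intervention ("additional_short_protocol_mri": CT plus short-protocol
#' MRI at 94% sensitivity by default) from a parameter set.
#'
#' @param params A `stroke_params` object.
#' @return Named list of two `strategy_definition` objects, comparator first.
#' @export
default_strategies <- function(params = default_parameters()) {
  list(
    no_additional_imaging = strategy_definition(
      "no_additional_imaging",
      sensitivity = params$sens_no_imaging,
      specificity = params$spec_no_imaging,
      imaging_costs = c(ct = params$cost_ct)),
    additional_short_protocol_mri = strategy_definition(
      "additional_short_protocol_mri",
      sensitivity = params$sens_mri,
      specificity = params$spec_mri,
      imaging_costs = c(ct = params$cost_ct, mri = params$cost_mri))
  )
}

#' Markov starting distribution and upfront cost for a strategy
#'
#' True positives (prevalence x sensitivity) enter the first-year detected
#' tunnel state, false negatives (prevalence x (1 - sensitivity)) the
#' first-year undetected tunnel, and true negatives (1 - prevalence) the
#' well state. The upfront cycle-0 cost charges the arm's imaging to every
#' patient and acute minor-stroke care to detected cases only; undetected
#' minor strokes accrue no acute cost.
#'
#' @param strategy A `strategy_definition` with specificity 1.
#' @param params A `stroke_params` object.
#' @return An `initial_cohort` object: `state_distribution` (probability per
#'   health state, summing to 1) and `upfront_cost` (dollars per patient,
#'   undiscounted).
#' @export
initial_cohort <- function(strategy, params) {
  if (strategy$specificity < 1)
    stop("specificity < 1 is not supported: no false positives can occur ",
         "in this setting, so the decision tree has no false-positive branch")
  prev <- params$prevalence_minor
  sens <- strategy$sensitivity
  dist <- stats::setNames(numeric(7), health_states())
  dist["detected_y1"] <- prev * sens
  dist["undetected_y1"] <- prev * (1 - sens)
  dist["well"] <- 1 - prev
  stopifnot(abs(sum(dist) - 1) < 1e-12)
  upfront <- sum(strategy$imaging_costs) + prev * sens * params$cost_acute_minor
  structure(list(state_distribution = dist, upfront_cost = upfront,
                 strategy = strategy$name),
            class = "initial_cohort")
}
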