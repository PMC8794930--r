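# Model inputs: every probability, cost, utility and rate used by the
# decision tree and the Markov engine, with literature-based defaults.

.param_defaults <- list(
  start_age                = 61L,
  n_cycles                 = 30L,
  discount_rate            = 0.03,
  wtp                      = 100000,
  prevalence_minor         = 0.1017,
  sens_no_imaging          = 0.60,
  spec_no_imaging          = 1.00,
  sens_mri                 = 0.94,
  spec_mri                 = 1.00,
  cost_ct                  = 155,
  cost_mri                 = 309,
  cost_acute_minor         = 3000,
  cost_acute_major         = 6500,
  cost_year_detected_minor = 7023,
  cost_year_post_major     = 19062,
  utility_no_major         = 1.00,
  utility_post_major       = 0.33,
  utility_dead             = 0.00,
  add_death_undetected     = 0.075,
  add_death_detected       = 0.06,
  rr_death_post_major      = 1.71,
  risk_new_minor           = 0.003,
  detection_rate_undetected = 0.1,
  risk_major_from_well     = 0.006,
  risk_major_detected_y1   = 0.051,
  risk_major_detected_later = 0.011,
  rrr_prophylaxis          = 0.80,
  risk_major_undetected_y1 = NA_real_,   # derived unless overridden
  risk_major_undetected_later = NA_real_ # derived unless overridden
)

.derived_fields <- c("risk_major_undetected_y1", "risk_major_undetected_later")

.prob_fields <- c(
  "prevalence_minor", "sens_no_imaging", "spec_no_imaging", "sens_mri",
  "spec_mri", "utility_no_major", "utility_post_major", "utility_dead",
  "add_death_undetected", "add_death_detected", "risk_new_minor",
  "detection_rate_undetected", "risk_major_from_well",
  "risk_major_detected_y1", "risk_major_detected_later",
  "risk_major_undetected_y1", "risk_major_undetected_later"
)

.cost_fields <- c(
  "cost_ct", "cost_mri", "cost_acute_minor", "cost_acute_major",
  "cost_year_detected_minor", "cost_year_post_major"
)

#' Untreated major-stroke risk implied by a treated risk and a risk reduction
#'
#' Post-minor-stroke major-stroke risks are reported for patients under
#' secondary prophylaxis; the corresponding risk without treatment is
#' recovered by undoing the relative risk reduction attributed to
#' prophylaxis: `treated_risk / (1 - rrr)`.
#'
#' @param treated_risk Annual probability of major stroke under secondary
#'   prophylaxis, in `[0, 1]`.
#' @param rrr Relative risk reduction achieved by prophylaxis, in `[0, 1)`.
#' @return The untreated annual probability. Errors if the derived value
#'   exceeds 1 (the inputs are then jointly inconsistent).
#' @examples
#' derive_untreated_risk(0.051, 0.80)  # first-year risk -> 0.255
#' derive_untreated_risk(0.011, 0.80)  # later-year risk -> 0.055
#' @export
derive_untreated_risk <- function(treated_risk, rrr) {
  stopifnot(is.numeric(treated_risk), is.numeric(rrr))
  if (treated_risk < 0 || treated_risk > 1)
    stop("`treated_risk` must lie in [0, 1], got ", treated_risk)
  if (rrr < 0 || rrr >= 1)
    stop("`rrr` must lie in [0, 1), got ", rrr)
  out <- treated_risk / (1 - rrr)
  if (out > 1)
    stop("derived untreated risk ", signif(out, 4),
         " exceeds 1; treated_risk and rrr are inconsistent")
  out
}

#' Construct a validated model parameter set
#'
#' Returns the default inputs, with any field overridden by name. The
#' untreated major-stroke risks (`risk_major_undetected_y1`,
#' `risk_major_undetected_later`) are re-derived from the treated risks and
#' `rrr_prophylaxis` via [derive_untreated_risk()] whenever they are not
#' explicitly supplied, so that sensitivity analyses on the treated risks or
#' on the risk reduction propagate consistently.
#'
#' @param ... Named overrides of default fields (see [default_parameters()]
#'   for the full list). Unknown names are an error.
#' @return An object of class `stroke_params` (a named list).
#' @export
stroke_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(overrides), names(.param_defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- .param_defaults
  p[names(overrides)] <- overrides
  for (f in .derived_fields) {
    if (!f %in% names(overrides) || is.na(p[[f]])) {
      treated <- if (f == "risk_major_undetected_y1")
        p$risk_major_detected_y1 else p$risk_major_detected_later
      p[[f]] <- derive_untreated_risk(treated, p$rrr_prophylaxis)
    }
  }
  p$start_age <- as.integer(p$start_age)
  p$n_cycles <- as.integer(p$n_cycles)
  p <- structure(p, class = "stroke_params")
  validate_parameters(p)
  p
}

#' Default model inputs
#'
#' The base-case parameter set: cohort age 61 at entry, 30 yearly cycles,
#' 3% annual discounting of costs and QALYs, willingness to pay $100,000
#' per QALY, minor-stroke prevalence 10.17% in the modelled collective,
#' clinical sensitivity 60% without supplemental MRI versus 94% with it
#' (specificity 100% in both arms), Medicare-based imaging costs and
#' literature-based acute and yearly care costs, and annual transition
#' probabilities for stroke and death risk adjustments.
#'
#' @return A `stroke_params` object.
#' @export
default_parameters <- function() stroke_parameters()

#' Validate a parameter set
#'
#' Checks range constraints strictly (errors, never clamping): all
#' probabilities and utilities in `[0, 1]`, risk reduction in `[0, 1)`,
#' non-negative costs and discount rate, at least one cycle. `utility_dead`
#' is fixed at 0.
#'
#' @param params A `stroke_params` object (or named list with its fields).
#' @return `params`, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field.
#' @export
validate_parameters <- function(params) {
  for (f in names(.param_defaults)) {
    if (is.null(params[[f]]) || length(params[[f]]) != 1 || is.na(params[[f]]))
      stop("parameter `", f, "` is missing or not a scalar")
  }
  for (f in .prob_fields) {
    v <- params[[f]]
    if (v < 0 || v > 1)
      stop("parameter `", f, "` must lie in [0, 1], got ", v)
  }
  if (params$rrr_prophylaxis < 0 || params$rrr_prophylaxis >= 1)
    stop("parameter `rrr_prophylaxis` must lie in [0, 1), got ",
         params$rrr_prophylaxis)
  for (f in .cost_fields) {
    if (params[[f]] < 0)
      stop("parameter `", f, "` must be non-negative, got ", params[[f]])
  }
  if (params$discount_rate < 0)
    stop("parameter `discount_rate` must be non-negative")
  if (params$wtp < 0)
    stop("parameter `wtp` must be non-negative")
  if (params$n_cycles < 1)
    stop("parameter `n_cycles` must be at least 1")
  if (params$start_age < 0)
    stop("parameter `start_age` must be non-negative")
  if (params$rr_death_post_major < 0)
    stop("parameter `rr_death_post_major` must be non-negative")
  if (params$utility_dead != 0)
    stop("parameter `utility_dead` is fixed at 0")
  invisible(params)
}

#' Update one parameter, re-deriving dependent risks
#'
#' Sets `name` to `value` and, unless `name` is itself one of the derived
#' untreated risks, recomputes `risk_major_undetected_y1` and
#' `risk_major_undetected_later` from the (possibly updated) treated risks
#' and risk reduction. This is the update rule used by the deterministic
#' sensitivity analysis.
#'
#' @param params A `stroke_params` object.
#' @param name Field name.
#' @param value New value.
#' @return A validated `stroke_params` object.
#' @export
update_parameters <- function(params, name, value) {
  if (!name %in% names(.param_defaults))
    stop("unknown parameter: ", name)
  p <- unclass(params)
  p[[name]] <- value
  if (!name %in% .derived_fields) {
    p$risk_major_undetected_y1 <-
      derive_untreated_risk(p$risk_major_detected_y1, p$rrr_prophylaxis)
    p$risk_major_undetected_later <-
      derive_untreated_risk(p$risk_major_detected_later, p$rrr_prophylaxis)
  }
  p$start_age <- as.integer(p$start_age)
  p$n_cycles <- as.integer(p$n_cycles)
  validate_parameters(structure(p, class = "stroke_params"))
  structure(p, class = "stroke_params")
}

#' Read model parameters from a flat YAML or JSON file
#'
#' The file is a flat key/value mapping using the field names of
#' [default_parameters()]. Missing keys fall back to defaults; unknown keys
#' are reported as a warning and ignored. Untreated risks are re-derived
#' unless the file sets them explicitly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `stroke_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  vals <- as.list(vals)
  unknown <- setdiff(names(vals), names(.param_defaults))
  if (length(unknown)) {
    warning("ignoring unknown parameter key(s): ",
            paste(unknown, collapse = ", "))
    vals <- vals[setdiff(names(vals), unknown)]
  }
  do.call(stroke_parameters, vals)
}

#' Write model parameters to a flat YAML or JSON file
#'
#' Inverse of [load_parameters()]: all fields (including the derived
#' untreated risks) are written explicitly, so a write/load round trip
#' reproduces the object exactly.
#'
#' @param params A `stroke_params` object.
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  vals <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.stroke_params <- function(x, ...) {
  cat("Markov cost-effectiveness model parameters\n")
  cat(sprintf("  cohort: start age %d, %d yearly cycles, discount %.1f%%, WTP $%s/QALY\n",
              x$start_age, x$n_cycles, 100 * x$discount_rate,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  diagnosis: prevalence %.2f%%; sensitivity %.0f%% (no imaging) vs %.0f%% (MRI)\n",
              100 * x$prevalence_minor, 100 * x$sens_no_imaging, 100 * x$sens_mri))
  cat(sprintf("  untreated major-stroke risks (derived): %.3f (year 1), %.3f (later)\n",
              x$risk_major_undetected_y1, x$risk_major_undetected_later))
  cat("  fields: ", paste(names(.param_defaults), collapse = ", "), "\n", sep = "")
  invisible(x)
}
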