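# Annual life tables (age -> qx, the probability of dying within the year)
# and the mortality adjustments applied to the post-stroke states.

#' Construct a life table
#'
#' @param age Integer vector of ages; must be strictly increasing and
#'   contiguous.
#' @param qx Annual probability of death within the year at each age, in
#'   `[0, 1]`.
#' @return A `life_table` object (a data frame with columns `age`, `qx`).
#' @export
life_table <- function(age, qx) {
  if (length(age) == 0) stop("life table must be non-empty")
  if (length(age) != length(qx)) stop("`age` and `qx` lengths differ")
  if (any(age != as.integer(age))) stop("ages must be integers")
  age <- as.integer(age)
  if (length(age) > 1 && any(diff(age) != 1L))
    stop("ages must be strictly increasing and contiguous")
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1))
    stop("every qx must lie in [0, 1]")
  structure(data.frame(age = age, qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Read an annual life table from CSV
#'
#' Expects header columns `age` and `qx`; additional columns are ignored.
#'
#' @param path Path to the CSV file.
#' @return A validated `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life-table CSV must have `age` and `qx` columns")
  life_table(df$age, df$qx)
}

#' Write a life table to CSV in the `age,qx` dialect
#'
#' @param lt A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Background annual probability of death at a given age
#'
#' Ages beyond the last tabulated age clamp to the final `qx` (the least
#' surprising extrapolation when the cohort outlives a short table); ages
#' below the first tabulated age are an error.
#'
#' @param lt A `life_table`.
#' @param age Age(s) in years (vectorised).
#' @return Annual death probability at each age.
#' @export
annual_death_prob <- function(lt, age) {
  if (any(age < lt$age[1]))
    stop("age ", min(age), " below life-table start (", lt$age[1], ")")
  idx <- pmin(floor(age) - lt$age[1] + 1, nrow(lt))
  lt$qx[idx]
}

#' Additive excess mortality
#'
#' Used for the minor-stroke states, whose excess risk of death is reported
#' as an additional annual probability. Capped at 1.
#'
#' @param q_base Background annual death probability.
#' @param add Additional annual death probability.
#' @return `min(1, q_base + add)`, vectorised.
#' @export
adjust_mortality_additive <- function(q_base, add) {
  stopifnot(all(q_base >= 0 & q_base <= 1), all(add >= 0 & add <= 1))
  pmin(1, q_base + add)
}

#' Multiplicative excess mortality
#'
#' Used for the post-major-stroke state, whose excess risk of death is
#' reported as a relative risk. Capped at 1.
#'
#' @param q_base Background annual death probability.
#' @param rr Relative risk (>= 0).
#' @return `min(1, q_base * rr)`, vectorised.
#' @export
adjust_mortality_relative <- function(q_base, rr) {
  stopifnot(all(q_base >= 0 & q_base <= 1), all(rr >= 0))
  pmin(1, q_base * rr)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Annual life table: ages %d-%d, qx %.4g to %.4g\n",
              x$age[1], x$age[nrow(x)], x$qx[1], x$qx[nrow(x)]))
  invisible(x)
}
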