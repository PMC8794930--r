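res <- function(cost, qaly, name = "s")
  list(total_cost = cost, total_qalys = qaly, strategy = name)

test_that("incremental comparison computes deltas, ICER, NMB and dominance", {
  # published base-case magnitudes give the published deltas
  cmp <- compare_strategies(res(27109, 14.25), res(26304, 14.31), wtp = 100000)
  expect_equal(cmp$delta_cost, -805)
  expect_equal(cmp$delta_effect, 0.06)
  expect_identical(cmp$dominance, "intervention_dominant")
  expect_true(is.na(cmp$icer))
  expect_equal(unname(cmp$nmb["intervention"]), 100000 * 14.31 - 26304)

  cmp2 <- compare_strategies(res(100, 10.00), res(600, 10.05))
  expect_identical(cmp2$dominance, "none")
  expect_equal(cmp2$icer, 10000)
})

test_that("dominance labelling covers the degenerate branches", {
  # equal effect, different cost: cost minimisation decides
  expect_identical(compare_strategies(res(100, 10), res(90, 10))$dominance,
                   "intervention_dominant")
  expect_identical(compare_strategies(res(90, 10), res(100, 10))$dominance,
                   "comparator_dominant")
  eq <- compare_strategies(res(100, 10), res(100, 10))
  expect_identical(eq$dominance, "none")
  expect_true(is.na(eq$icer))
  # intervention dearer and less effective: comparator dominates
  expect_identical(compare_strategies(res(100, 10.0), res(600, 9.5))$dominance,
                   "comparator_dominant")
  # cheaper but less effective is a trade-off, not dominance
  tr <- compare_strategies(res(600, 10.0), res(100, 9.5))
  expect_identical(tr$dominance, "none")
  expect_equal(tr$icer, 1000)
})

test_that("comparison is antisymmetric and NMB ranking agrees with dominance", {
  set.seed(3)
  for (i in 1:10) {
    a <- res(runif(1, 1e4, 3e4), runif(1, 5, 15))
    b <- res(runif(1, 1e4, 3e4), runif(1, 5, 15))
    ab <- compare_strategies(a, b)
    ba <- compare_strategies(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_effect, -ba$delta_effect)
    if (ab$dominance == "intervention_dominant")
      expect_gt(ab$nmb[["intervention"]], ab$nmb[["comparator"]])
    if (ab$dominance == "comparator_dominant")
      expect_lt(ab$nmb[["intervention"]], ab$nmb[["comparator"]])
  }
})

test_that("the fitted model object is internally consistent", {
  fit <- cea_markov()
  rs <- fit$results
  expect_named(rs, c("no_additional_imaging", "additional_short_protocol_mri"))
  expect_equal(fit$comparison$delta_cost,
               rs$additional_short_protocol_mri$total_cost -
                 rs$no_additional_imaging$total_cost)
  expect_equal(fit$comparison$delta_effect,
               rs$additional_short_protocol_mri$total_qalys -
                 rs$no_additional_imaging$total_qalys)
  tab <- summary(fit)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cumulative_cost[1], rs$no_additional_imaging$total_cost)
  expect_true(all(c("strategy", "cumulative_cost", "cumulative_effectiveness",
                    "interpretation") %in% names(tab)))
  expect_type(coef(fit), "double")
  expect_equal(unname(coef(fit)["wtp"]), 100000)
})

test_that("print and plot methods run quietly", {
  fit <- cea_markov()
  expect_output(print(fit), "Dominant|Dominated|ICER")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit, type = "trace"))
})
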