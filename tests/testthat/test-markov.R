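test_that("discount factors follow (1 + r)^(-t)", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0, 17), 1.0)
  expect_equal(discount_factor(0.03, 0:3), 1.03^-(0:3))
})

test_that("transition matrix realises the competing-risk composition", {
  p <- default_parameters()
  lt <- flat_life_table(0.010)
  M <- build_transition_matrix(p, lt, 61)
  expect_equal(rowSums(M), setNames(rep(1, 7), health_states()))
  expect_true(all(M >= 0))
  # undetected first-year tunnel: death first, then major stroke among
  # survivors, then detection among survivors without a stroke
  expect_equal(M["undetected_y1", "dead"], 0.085)
  expect_equal(M["undetected_y1", "post_major"], (1 - 0.085) * 0.255)
  expect_equal(M["undetected_y1", "detected_post"],
               (1 - 0.085) * (1 - 0.255) * 0.1)
  expect_equal(M["undetected_y1", "undetected_post"],
               (1 - 0.085) * (1 - 0.255) * 0.9)
  # detected tunnel leaves year 1 after one cycle; dead is absorbing
  expect_equal(M["detected_y1", "detected_y1"], 0)
  expect_equal(M["detected_y1", "detected_post"], (1 - 0.07) * (1 - 0.051))
  expect_equal(M["post_major", "dead"], 0.0171)
  expect_equal(M["dead", ], setNames(c(0, 0, 0, 0, 0, 0, 1), health_states()))
})

test_that("with all event risks off, living states only persist or die", {
  p <- inert_parameters()
  M <- build_transition_matrix(p, flat_life_table(0.02), 70)
  for (st in setdiff(health_states(), "dead")) {
    expect_equal(M[st, "dead"], 0.02)
    moved <- M[st, setdiff(health_states(), c(st, "dead",
      if (st == "undetected_y1") "undetected_post",
      if (st == "detected_y1") "detected_post"))]
    expect_equal(unname(moved), rep(0, length(moved)))
  }
})

test_that("discounted QALY totals reproduce the closed-form annuity", {
  lt0 <- flat_life_table(0)
  well <- single_state_cohort("well")
  p0 <- inert_parameters(discount_rate = 0)
  expect_equal(run_cohort(well, p0, lt0)$total_qalys, 30)
  p3 <- inert_parameters(discount_rate = 0.03)
  # end-of-cycle accrual: ordinary annuity (1 - 1.03^-30)/0.03
  expect_equal(run_cohort(well, p3, lt0)$total_qalys,
               (1 - 1.03^-30) / 0.03, tolerance = 1e-12)
  # begin-of-cycle accrual: annuity-due, one factor of 1.03 larger
  expect_equal(run_cohort(well, p3, lt0, reward_timing = "begin")$total_qalys,
               1.03 * (1 - 1.03^-30) / 0.03, tolerance = 1e-12)
  # with constant occupancy, half-cycle correction coincides with
  # end-of-cycle accrual (the averaged occupancies are identical)
  hc <- run_cohort(well, p3, lt0, reward_timing = "half_cycle")$total_qalys
  expect_equal(hc, (1 - 1.03^-30) / 0.03)
  # with mortality, it lands strictly between end and begin accrual
  ltm <- flat_life_table(0.05)
  e <- run_cohort(well, p3, ltm)$total_qalys
  h <- run_cohort(well, p3, ltm, reward_timing = "half_cycle")$total_qalys
  b <- run_cohort(well, p3, ltm, reward_timing = "begin")$total_qalys
  expect_gt(h, e)
  expect_lt(h, b)
})

test_that("one-cycle rewards match a hand computation", {
  p <- update_parameters(default_parameters(), "n_cycles", 1)
  lt <- flat_life_table(0.010)
  r <- run_cohort(single_state_cohort("undetected_y1"), p, lt)
  # by hand: death 0.085; survivors 0.915; major 0.915*0.255; of the
  # non-stroke remainder 0.915*0.745, 10% detected
  pm <- 0.915 * 0.255
  det <- 0.915 * 0.745 * 0.1
  undet <- 0.915 * 0.745 * 0.9
  expect_equal(r$total_cost,
               (det * 7023 + pm * 19062 + pm * 6500) / 1.03)
  expect_equal(r$total_qalys, ((det + undet) * 1 + pm * 0.33) / 1.03)
  expect_equal(unname(r$trace$occupancy[2, c("post_major", "dead")]),
               c(pm, 0.085))
})

test_that("acute major-stroke cost is charged once, on entry only", {
  # cohort already post-major: no entrants, only yearly care costs
  p <- inert_parameters(discount_rate = 0)
  lt0 <- flat_life_table(0)
  r <- run_cohort(single_state_cohort("post_major"), p, lt0)
  expect_equal(r$total_cost, 30 * p$cost_year_post_major)
  expect_equal(r$total_qalys, 30 * p$utility_post_major)
})

test_that("cohort traces conserve mass and death is monotone", {
  lt <- synthetic_life_table()
  for (p in fixture_parameter_sets(n = 3, seed = 5)) {
    for (s in default_strategies(p)) {
      r <- run_cohort(initial_cohort(s, p), p, lt)
      expect_true(all(abs(rowSums(r$trace$occupancy) - 1) < 1e-10))
      expect_true(all(r$trace$occupancy >= -1e-15))
      expect_true(all(diff(r$trace$occupancy[, "dead"]) >= 0))
      expect_gte(r$total_cost, r$upfront_cost)
      expect_true(r$total_qalys >= 0 && r$total_qalys <= p$n_cycles)
    }
  }
})

test_that("discounting can only shrink totals", {
  lt <- synthetic_life_table()
  p0 <- update_parameters(default_parameters(), "discount_rate", 0)
  p3 <- default_parameters()
  s <- default_strategies(p3)$additional_short_protocol_mri
  r0 <- run_cohort(initial_cohort(s, p0), p0, lt)
  r3 <- run_cohort(initial_cohort(s, p3), p3, lt)
  expect_lt(r3$total_cost, r0$total_cost)
  expect_lt(r3$total_qalys, r0$total_qalys)
})

test_that("strategies with identical accuracy differ only by the MRI charge", {
  lt <- synthetic_life_table()
  p <- update_parameters(default_parameters(), "sens_no_imaging",
                         default_parameters()$sens_mri)
  fit <- cea_markov(p, lt)
  expect_equal(fit$comparison$delta_effect, 0)
  expect_equal(fit$comparison$delta_cost, p$cost_mri, tolerance = 1e-10)
})
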