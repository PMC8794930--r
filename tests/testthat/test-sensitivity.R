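test_that("moment matching reproduces the closed-form shapes", {
  b <- moment_match("beta", 0.06, 0.012)
  expect_equal(b$shape1, 23.44, tolerance = 5e-3)
  expect_equal(b$shape2, 367.23, tolerance = 5e-5)
  g <- moment_match("gamma", 309, 61.8)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 12.36)
  # boundary means carry no feasible variance and collapse to point masses
  expect_identical(moment_match("beta", 1, 0.1)$family, "fixed")
  expect_identical(moment_match("beta", 0, 0.1)$family, "fixed")
  expect_identical(moment_match("gamma", 0, 0.1)$family, "fixed")
  expect_error(moment_match("beta", 0.5, 0.6), "infeasible")
})

test_that("moment-matched distributions recover their means and stay in range", {
  sets <- fixture_parameter_sets(n = 400, seed = 21, spread_cv = 0.2)
  for (nm in c("prevalence_minor", "cost_mri", "utility_post_major",
               "rrr_prophylaxis", "rr_death_post_major")) {
    draws <- vapply(sets, `[[`, numeric(1), nm)
    target <- default_parameters()[[nm]]
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - target), 3 * se + 1e-12)
  }
  probs <- unlist(lapply(sets, function(p)
    c(p$prevalence_minor, p$sens_mri, p$utility_post_major,
      p$risk_major_detected_y1, p$rrr_prophylaxis)))
  expect_true(all(probs >= 0 & probs <= 1))
  costs <- unlist(lapply(sets, function(p) c(p$cost_ct, p$cost_year_post_major)))
  expect_true(all(costs >= 0))
})

test_that("one-way DSA: degenerate ranges and base-case consistency", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  base <- cea_markov(p, lt)$comparison
  base_inmb <- unname(base$nmb["intervention"] - base$nmb["comparator"])
  ranges <- data.frame(parameter = c("cost_mri", "utility_post_major"),
                       low = c(309, 0.33), high = c(309, 0.33))
  tor <- one_way_dsa(p, lt, ranges)
  # a parameter pinned at its default reproduces the base case exactly
  expect_equal(tor$inmb_low, rep(base_inmb, 2))
  expect_equal(tor$inmb_high, tor$inmb_low)
  expect_equal(tor$swing, c(0, 0))
  expect_error(one_way_dsa(p, lt, data.frame(parameter = "prevalence_minor",
                                             low = 0.5, high = 1.5)))
})

test_that("tornado entries are sorted by swing with finite outcomes", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  ranges <- default_dsa_ranges(p)
  ranges <- ranges[ranges$parameter %in%
                     c("cost_mri", "utility_post_major", "rrr_prophylaxis",
                       "detection_rate_undetected"), ]
  tor <- one_way_dsa(p, lt, ranges)
  expect_equal(nrow(tor), 4)
  expect_true(all(is.finite(tor$inmb_low)) && all(is.finite(tor$inmb_high)))
  expect_true(all(diff(tor$swing) <= 0))
})

test_that("ICER-vs-parameter grid reduces to the base case at a single default", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  base <- cea_markov(p, lt)$comparison
  curve <- icer_vs_parameter(p, lt, "sens_no_imaging", p$sens_no_imaging)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$delta_cost, base$delta_cost)
  expect_equal(curve$delta_effect, base$delta_effect)
  curve3 <- icer_vs_parameter(p, lt, "sens_no_imaging", c(0.5, 0.6, 0.7))
  expect_equal(nrow(curve3), 3)
  # a less sensitive comparator makes the MRI strategy look better
  expect_true(all(diff(curve3$inmb) < 0))
})

test_that("PSA is seed-reproducible and collapses to the base case as cv -> 0", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  a <- run_psa(p, lt, n_iterations = 40, seed = 9)
  b <- run_psa(p, lt, n_iterations = 40, seed = 9)
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$fraction_intervention_dominant,
                   b$fraction_intervention_dominant)
  c_ <- run_psa(p, lt, n_iterations = 40, seed = 10)
  expect_false(identical(a$iterations, c_$iterations))

  base <- cea_markov(p, lt)
  tiny <- run_psa(p, lt, n_iterations = 30, seed = 2, spread_cv = 0.01)
  expect_true(all(abs(tiny$iterations$cost_intervention /
                        base$results$additional_short_protocol_mri$total_cost
                      - 1) < 0.05))
  expect_true(all(abs(tiny$iterations$effect_comparator /
                        base$results$no_additional_imaging$total_qalys
                      - 1) < 0.05))
})

test_that("CEAC limits follow the net-monetary-benefit definition", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  psa <- run_psa(p, lt, n_iterations = 60, seed = 13)
  cc <- ceac(psa, c(0, 1e5, 1e9))
  it <- psa$iterations
  # wtp = 0: NMB reduces to minus cost
  expect_equal(cc$probability_cost_effective[1],
               mean(it$cost_intervention < it$cost_comparator))
  # wtp -> infinity: the effect term dominates
  expect_equal(cc$probability_cost_effective[3],
               mean(it$effect_intervention > it$effect_comparator))
  expect_true(all(cc$probability_cost_effective >= 0 &
                    cc$probability_cost_effective <= 1))
  expect_error(ceac(psa, numeric(0)))
})
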