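# Frozen expected values below were hand-derived by enumerating the two
# branches of each arm with the base-case inputs:
#   baseline utility 0.68*0.51 + 0.32*0.37            = 0.4652
#   comparator cost  0.10*15*103.87 + 0.26*70.96*0.25
#                    + 0.65*173.30*1.5                = 329.3849
#   CBT cost         15*103.87 + (1 - 0.35 - 1/10.08)*173.30*1.5 = 1701.2288
#   QALYs            [rem*0.73 + (1-rem)*0.4652] * 0.25

test_that("arm evaluation reproduces hand-enumerated base-case costs and QALYs", {
  p <- default_parameters()

  soc <- arm_outcomes(p, "standard_of_care", p$cost_per_session)
  expect_equal(soc$expected_cost, 329.3849, tolerance = 1e-6)
  expect_equal(soc$expected_qaly, 0.139470, tolerance = 1e-5)
  expect_equal(soc$remission_probability, 0.35)

  cbt <- arm_outcomes(p, "CBT", p$cost_per_session)
  expect_equal(cbt$expected_cost, 1701.2288, tolerance = 1e-6)
  expect_equal(cbt$expected_qaly, 0.1460373, tolerance = 1e-5)
  expect_equal(cbt$remission_probability, 0.35 + 1 / 10.08)

  expect_error(arm_outcomes(p, "placebo", 100), "should be one of")
})

test_that("no treatment effect means no QALY difference between arms", {
  p <- default_parameters()
  p$abs_remission_reduction <- param_value(0)
  cbt <- arm_outcomes(p, "CBT", p$cost_per_session)
  soc <- arm_outcomes(p, "standard_of_care", p$cost_per_session)
  expect_equal(cbt$expected_qaly, soc$expected_qaly)
})

test_that("base-case incremental results match the hand reconstruction", {
  p <- default_parameters()
  inc <- incremental(arm_outcomes(p, "CBT", p$cost_per_session),
                     arm_outcomes(p, "standard_of_care", p$cost_per_session))

  expect_equal(inc$delta_qaly, (1 / 10.08) * 0.2648 * 0.25, tolerance = 1e-12)
  expect_equal(round(inc$delta_qaly, 3), 0.007)
  expect_equal(inc$delta_cost, 1371.8439, tolerance = 1e-6)
  expect_equal(inc$icer, 208885, tolerance = 1e-4)

  same <- incremental(arm_outcomes(p, "CBT", 10), arm_outcomes(p, "CBT", 10))
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_false(same$icer_defined)
  expect_true(is.na(same$icer))
})

test_that("branch-enumeration oracle agrees with the algebraic evaluation", {
  p <- default_parameters()
  for (arm in c("CBT", "standard_of_care")) {
    a <- arm_outcomes(p, arm, p$cost_per_session)
    o <- enumerate_tree_oracle(p, arm, p$cost_per_session)
    expect_equal(o$expected_cost, a$expected_cost, tolerance = 1e-9)
    expect_equal(o$expected_qaly, a$expected_qaly, tolerance = 1e-9)
    expect_equal(sum(attr(o, "branches")$prob), 1, tolerance = 1e-12)
  }

  # zero fee removes the comparator psychotherapy cost contribution
  free <- enumerate_tree_oracle(p, "standard_of_care", 0)
  paid <- enumerate_tree_oracle(p, "standard_of_care", p$cost_per_session)
  expect_equal(paid$expected_cost - free$expected_cost,
               0.10 * 15 * 103.87, tolerance = 1e-9)
})

test_that("oracle equivalence holds across randomly generated parameter sets", {
  set.seed(20260930)
  for (i in seq_len(250)) {
    p <- random_params()
    fee <- runif(1, 0, 200)
    arm <- sample(c("CBT", "standard_of_care"), 1)
    a <- arm_outcomes(p, arm, fee)
    o <- enumerate_tree_oracle(p, arm, fee)
    expect_equal(o$expected_cost, a$expected_cost, tolerance = 1e-9)
    expect_equal(o$expected_qaly, a$expected_qaly, tolerance = 1e-9)
  }
})

test_that("QALY gain is monotone in effect size, remission utility, horizon and baseline utility", {
  h_of <- function(p) {
    incremental(arm_outcomes(p, "CBT", p$cost_per_session),
                arm_outcomes(p, "standard_of_care", p$cost_per_session))$delta_qaly
  }
  base <- default_parameters()
  h0 <- h_of(base)

  p <- default_parameters(); p$abs_remission_reduction <- param_value(0.15)
  expect_gt(h_of(p), h0)
  p <- default_parameters(); p$utility_remission <- param_value(0.80)
  expect_gt(h_of(p), h0)
  p <- default_parameters(); p$horizon_years <- 0.5
  expect_gt(h_of(p), h0)
  # higher baseline utility (more moderate cases) shrinks the gain
  p <- default_parameters(); p$prop_moderate <- param_value(0.80)
  expect_lt(h_of(p), h0)
})

test_that("continuous discounting matches numerical integration and is a no-op at rate zero", {
  expect_identical(discount_factor(0, 0.25), 1)
  for (case in list(c(0.03, 1), c(0.05, 46 / 12), c(0.10, 0.25))) {
    r <- case[1]; horizon <- case[2]
    numeric <- stats::integrate(function(t) exp(-r * t), 0, horizon)$value / horizon
    expect_equal(discount_factor(r, horizon), numeric, tolerance = 1e-8)
  }

  p <- default_parameters()
  p$discount_rate_annual <- 0.05
  discounted <- arm_outcomes(p, "CBT", p$cost_per_session)
  undiscounted <- arm_outcomes(default_parameters(), "CBT", p$cost_per_session)
  expect_lt(discounted$expected_qaly, undiscounted$expected_qaly)
  expect_lt(discounted$expected_cost, undiscounted$expected_cost)
})
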