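# Hand-solved reference fees (from the Table-1 inputs):
#   induced savings at zero fee: 0.26*70.96*0.25 + (1/10.08)*173.30*1.5
#                              = 4.61240 + 25.78869 = 30.40109
#   effective billed sessions under self-referential comparator pricing:
#                                15 * (1 - 0.10) = 13.5
#   fee(lambda) = (lambda * 0.00656746 + 30.40109) / 13.5

test_that("value-based fee at the EUR 88,000 threshold is EUR 45 per session", {
  p <- default_parameters()
  pr <- value_based_price(p, wtp = 88000)
  expect_equal(pr$fee_per_session, 45.06204, tolerance = 1e-5)
  expect_equal(round(pr$fee_per_session), 45)
  expect_equal(pr$total_price, 15 * pr$fee_per_session)
  # threshold identity on the reported fields: (p + b) / h = lambda
  expect_equal((pr$total_price + pr$induced_costs) / pr$qaly_gain, 88000,
               tolerance = 1e-9)

  # at a zero threshold only the induced savings are rebated
  expect_equal(value_based_price(p, wtp = 0)$fee_per_session,
               30.40109 / 13.5, tolerance = 1e-5)
})

test_that("re-evaluating the decision model at the solved fee returns the threshold as ICER", {
  p <- default_parameters()
  for (lambda in c(1000, 20000, 88000, 150000)) {
    fee <- value_based_price(p, lambda)$fee_per_session
    inc <- incremental(arm_outcomes(p, "CBT", fee),
                       arm_outcomes(p, "standard_of_care", fee))
    expect_equal(inc$icer, lambda, tolerance = 1e-9)
  }
})

test_that("pricing at the model's own ICER returns the current fee exactly", {
  p <- default_parameters()
  inc <- incremental(arm_outcomes(p, "CBT", p$cost_per_session),
                     arm_outcomes(p, "standard_of_care", p$cost_per_session))
  expect_equal(value_based_price(p, inc$icer)$fee_per_session,
               p$cost_per_session, tolerance = 1e-9)
})

test_that("pricing round-trip is exact across random parameter sets and thresholds", {
  set.seed(4821)
  for (i in seq_len(200)) {
    p <- random_params()
    lambda <- runif(1, 0, 250000)
    fee <- value_based_price(p, lambda)$fee_per_session
    inc <- incremental(arm_outcomes(p, "CBT", fee),
                       arm_outcomes(p, "standard_of_care", fee))
    expect_equal(inc$icer, lambda, tolerance = 1e-9)
  }
})

test_that("the fee-threshold curve is the expected affine map", {
  p <- default_parameters()
  grid <- c(0, 44000, 88000, 132000)
  curve <- fee_curve(p, grid)
  expect_equal(curve$fee_per_session[c(1, 3)],
               c(30.40109 / 13.5, 45.06204), tolerance = 1e-5)
  expect_true(all(diff(curve$fee_per_session) > 0))

  # any three points are exactly collinear
  slopes <- diff(curve$fee_per_session) / diff(curve$wtp)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  # analytic slope h / (n * (1 - prop_psychotherapy))
  expect_equal(slopes[1], ((1 / 10.08) * 0.2648 * 0.25) / 13.5,
               tolerance = 1e-9)

  expect_error(fee_curve(p, c(1000, 1000)), "strictly increasing")
})

test_that("fee rises with effect size and with larger induced savings", {
  base_fee <- value_based_price(default_parameters())$fee_per_session

  p <- default_parameters(); p$abs_remission_reduction <- param_value(0.15)
  expect_gt(value_based_price(p)$fee_per_session, base_fee)

  p <- default_parameters(); p$indirect_cost_2mo <- param_value(200.64)
  expect_gt(value_based_price(p)$fee_per_session, base_fee)
})

test_that("degenerate and undefined pricing problems raise declared errors", {
  p <- default_parameters()
  p$utility_remission <- param_value(0.40)  # below baseline: h < 0
  expect_error(value_based_price(p), "not positive")

  expect_error(value_based_price(default_parameters(), wtp = -1), "negative")

  p <- default_parameters()
  p$prop_psychotherapy <- param_value(1)  # comparator absorbs every session
  expect_error(value_based_price(p), "degenerate")
})

test_that("current-price comparator psychotherapy is exposed as an alternative convention", {
  p <- default_parameters()
  self_ref <- value_based_price(p, comparator_pricing = "value_based")
  current <- value_based_price(p, comparator_pricing = "current_price")
  # billing the comparator's psychotherapy at the (higher) current fee
  # leaves more headroom for the CBT fee
  expect_gt(current$fee_per_session, self_ref$fee_per_session)
  fee <- current$fee_per_session
  inc <- incremental(arm_outcomes(p, "CBT", fee),
                     arm_outcomes(p, "standard_of_care", p$cost_per_session))
  expect_equal(inc$icer, 88000, tolerance = 1e-9)
})

test_that("threshold-priced follow-up therapy leaves the ICER invariant", {
  p <- default_parameters()
  base <- incremental(arm_outcomes(p, "CBT", p$cost_per_session),
                      arm_outcomes(p, "standard_of_care", p$cost_per_session))

  expect_equal(followup_invariance(base, 0), base)

  doubled <- followup_invariance(base, 1)
  expect_equal(doubled$delta_cost, 2 * base$delta_cost)
  expect_equal(doubled$delta_qaly, 2 * base$delta_qaly)
  expect_equal(doubled$icer, base$icer)

  spec <- followup_spec(c(0.4, 1.8, 1.5))
  expect_equal(spec$x, 3.7)
  expect_identical(spec$n, 3L)
  seq3 <- followup_invariance(base, spec)
  expect_equal(seq3$delta_cost, 4.7 * base$delta_cost)
  expect_equal(seq3$icer, base$icer, tolerance = 1e-12)

  set.seed(99)
  for (x in runif(250, 0, 100)) {
    expect_equal(followup_invariance(base, x)$icer, base$icer,
                 tolerance = 1e-12)
  }

  expect_error(followup_spec(-0.1))
  zero <- incremental(arm_outcomes(p, "CBT", 10), arm_outcomes(p, "CBT", 10))
  expect_error(followup_invariance(zero, 1), "zero QALY difference")
})
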