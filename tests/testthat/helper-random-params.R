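# Random *valid* parameter sets spanning the legal domain, for property
# tests. Deliberately independent of sample_parameters(): uniform over wide
# ranges rather than normal around the base case, and constructed so the
# model stays meaningful (positive utility gain, feasible remission total).
random_params <- function() {
  p <- default_parameters()
  u_sev <- runif(1, 0.20, 0.45)
  u_mod <- runif(1, u_sev + 0.01, 0.60)
  u_rem <- runif(1, u_mod + 0.05, 0.95)
  control <- runif(1, 0.10, 0.50)
  reduction <- runif(1, 0.01, min(0.40, 1 - control - 0.01))

  p$abs_remission_reduction <- param_value(reduction)
  p$control_remission_rate <- control
  p$utility_remission <- param_value(u_rem)
  p$utility_moderate <- param_value(u_mod)
  p$utility_severe <- param_value(u_sev)
  p$prop_moderate <- param_value(runif(1))
  p$cost_per_session <- runif(1, 20, 300)
  p$n_sessions <- sample(5:30, 1)
  p$cost_antidepressant_12mo <- runif(1, 0, 500)
  p$prop_psychotherapy <- param_value(runif(1, 0, 0.5))
  p$prop_antidepressant <- param_value(runif(1))
  p$cost_depression_2mo <- runif(1, 0, 500)
  p$indirect_cost_2mo <- param_value(runif(1, 0, 300))
  p$horizon_years <- runif(1, 0.1, 2)
  p$wtp_threshold <- runif(1, 1000, 200000)
  p$discount_rate_annual <- runif(1, 0, 0.1)
  p
}
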