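# Two-arm decision-tree evaluation.
#
# Each arm resolves into remission / no remission over the model horizon.
# Remitters hold the remission utility for the whole horizon and incur no
# further depression-care costs; non-remitters hold the severity-weighted
# baseline utility and accrue depression-care (and, when enabled, indirect)
# costs. The comparator arm additionally carries the treatment-as-usual
# utilisation mix: a fraction receiving psychotherapy and a fraction on
# antidepressants.

.arm_labels <- c("CBT", "standard_of_care")

#' Continuous-time discount factor over a horizon
#'
#' Average of `exp(-rate * t)` over `t` in `[0, horizon]`, i.e.
#' `(1 - exp(-rate * horizon)) / (rate * horizon)`. Applied to QALYs and
#' to recurring costs; equals 1 when the rate is 0 (the base case for a
#' sub-year horizon).
#'
#' @param rate Annual discount rate (proportion, >= 0).
#' @param horizon Horizon in years (> 0).
#' @return Scalar factor in (0, 1].
#' @export
discount_factor <- function(rate, horizon) {
  stopifnot(rate >= 0, horizon > 0)
  if (rate == 0) return(1)
  (1 - exp(-rate * horizon)) / (rate * horizon)
}

#' Expected cost and QALYs of one treatment arm
#'
#' Evaluates one arm of the decision tree over the model horizon.
#'
#' In the CBT arm the remission probability is the control remission rate
#' plus the absolute remission reduction, and the course of
#' `n_sessions` sessions is billed at `session_fee`. In the comparator
#' (treatment-as-usual) arm the remission probability is the control rate;
#' `prop_psychotherapy` of patients receive a psychotherapy course billed
#' at `session_fee` (so the caller controls whether comparator
#' psychotherapy is priced at the current or at a candidate value-based
#' fee) and `prop_antidepressant` are on antidepressants, whose 12-month
#' cost is prorated to the horizon. In both arms non-remitters accrue the
#' two-monthly depression-care cost (plus the indirect cost when enabled)
#' scaled to the horizon. QALYs weight remitters at the remission utility
#' and non-remitters at the severity-weighted baseline utility for the
#' whole horizon. Recurring costs and QALYs are discounted with
#' [discount_factor()]; session fees, paid during treatment, are not.
#'
#' @param params A valid `cbt_parameters` object.
#' @param arm `"CBT"` or `"standard_of_care"`.
#' @param session_fee Fee in euros per 50-minute session applied to the
#'   psychotherapy delivered in this arm.
#' @return An `arm_result`: list with `arm`, `expected_cost` (euros per
#'   patient), `expected_qaly` (QALYs per patient over the horizon) and
#'   `remission_probability`.
#' @seealso [incremental()], [enumerate_tree_oracle()]
#' @export
#' @examples
#' p <- default_parameters()
#' arm_outcomes(p, "CBT", p$cost_per_session)
arm_outcomes <- function(params, arm = .arm_labels, session_fee) {
  arm <- match.arg(arm, .arm_labels)
  stopifnot(is.numeric(session_fee), length(session_fee) == 1L,
            is.finite(session_fee))

  horizon <- params$horizon_years
  dfac <- discount_factor(params$discount_rate_annual, horizon)
  rem <- pv_mean(params$control_remission_rate) +
    if (arm == "CBT") pv_mean(params$abs_remission_reduction) else 0
  if (rem < 0 || rem > 1) {
    stop(sprintf("remission probability %g outside [0, 1] in arm %s", rem, arm),
         call. = FALSE)
  }

  u_rem <- pv_mean(params$utility_remission)
  u_base <- baseline_utility(params)
  qaly <- (rem * u_rem + (1 - rem) * u_base) * horizon * dfac

  # horizon expressed in two-month blocks (e.g. 0.25 y -> 1.5 blocks)
  blocks <- horizon * 6
  illness_cost <- (1 - rem) *
    (params$cost_depression_2mo + pv_mean(params$indirect_cost_2mo)) *
    blocks * dfac

  cost <- if (arm == "CBT") {
    params$n_sessions * session_fee + illness_cost
  } else {
    pv_mean(params$prop_psychotherapy) * params$n_sessions * session_fee +
      pv_mean(params$prop_antidepressant) * params$cost_antidepressant_12mo *
        horizon * dfac +
      illness_cost
  }

  structure(
    list(arm = arm, expected_cost = cost, expected_qaly = qaly,
         remission_probability = rem, session_fee = session_fee),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm: expected cost EUR %.2f, expected QALYs %.5f, P(remission) %.4f\n",
              x$arm, x$expected_cost, x$expected_qaly, x$remission_probability))
  invisible(x)
}

#' Incremental cost, incremental QALYs and the ICER
#'
#' Differences (CBT minus comparator) of expected cost and expected
#' QALYs, and their ratio, the incremental cost-effectiveness ratio
#' (euros per QALY). A zero QALY difference leaves the ICER undefined
#' (`NA` with `icer_defined = FALSE`) rather than raising an error.
#'
#' @param cbt,soc `arm_result` objects evaluated under the same
#'   parameters and fee convention.
#' @return An `incremental_result`: list with `delta_cost` (euros),
#'   `delta_qaly` (QALYs), `icer` (euros/QALY or `NA`) and `icer_defined`.
#' @export
incremental <- function(cbt, soc) {
  stopifnot(inherits(cbt, "arm_result"), inherits(soc, "arm_result"))
  dc <- cbt$expected_cost - soc$expected_cost
  dq <- cbt$expected_qaly - soc$expected_qaly
  defined <- dq != 0
  structure(
    list(delta_cost = dc, delta_qaly = dq,
         icer = if (defined) dc / dq else NA_real_,
         icer_defined = defined),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("incremental cost EUR %.2f, incremental QALYs %.6f\n",
              x$delta_cost, x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("ICER: EUR %.0f per QALY\n", x$icer))
  } else {
    cat("ICER undefined (zero QALY difference)\n")
  }
  invisible(x)
}

#' Brute-force branch-enumeration oracle for one arm
#'
#' Independent re-computation of [arm_outcomes()] that lists every
#' terminal branch of the tree explicitly — remission status crossed with
#' each treatment-utilisation state (psychotherapy yes/no, antidepressant
#' yes/no in the comparator arm) — with its probability, cost payoff and
#' QALY payoff, then sums probability-weighted payoffs. Exists purely as
#' a correctness oracle: it shares no arithmetic shortcuts with
#' [arm_outcomes()] and must agree with it to accumulation tolerance.
#'
#' @inheritParams arm_outcomes
#' @return An `arm_result` (as [arm_outcomes()]) whose `"branches"`
#'   attribute is a data frame enumerating the terminal branches.
#' @export
enumerate_tree_oracle <- function(params, arm = .arm_labels, session_fee) {
  arm <- match.arg(arm, .arm_labels)
  stopifnot(is.numeric(session_fee), length(session_fee) == 1L,
            is.finite(session_fee))

  horizon <- params$horizon_years
  dfac <- discount_factor(params$discount_rate_annual, horizon)
  rem_p <- pv_mean(params$control_remission_rate) +
    if (arm == "CBT") pv_mean(params$abs_remission_reduction) else 0
  if (rem_p < 0 || rem_p > 1) {
    stop(sprintf("remission probability %g outside [0, 1] in arm %s",
                 rem_p, arm), call. = FALSE)
  }
  u_rem <- pv_mean(params$utility_remission)
  u_base <- baseline_utility(params)
  blocks <- horizon * 6

  if (arm == "CBT") {
    grid <- expand.grid(remission = c(TRUE, FALSE))
    grid$prob <- ifelse(grid$remission, rem_p, 1 - rem_p)
    grid$cost <- params$n_sessions * session_fee +
      ifelse(grid$remission, 0,
             (params$cost_depression_2mo + pv_mean(params$indirect_cost_2mo)) *
               blocks * dfac)
  } else {
    grid <- expand.grid(remission = c(TRUE, FALSE),
                        psychotherapy = c(TRUE, FALSE),
                        antidepressant = c(TRUE, FALSE))
    p_psy <- pv_mean(params$prop_psychotherapy)
    p_ad <- pv_mean(params$prop_antidepressant)
    grid$prob <- ifelse(grid$remission, rem_p, 1 - rem_p) *
      ifelse(grid$psychotherapy, p_psy, 1 - p_psy) *
      ifelse(grid$antidepressant, p_ad, 1 - p_ad)
    grid$cost <-
      ifelse(grid$psychotherapy, params$n_sessions * session_fee, 0) +
      ifelse(grid$antidepressant,
             params$cost_antidepressant_12mo * horizon * dfac, 0) +
      ifelse(grid$remission, 0,
             (params$cost_depression_2mo + pv_mean(params$indirect_cost_2mo)) *
               blocks * dfac)
  }
  grid$qaly <- ifelse(grid$remission, u_rem, u_base) * horizon * dfac

  res <- structure(
    list(arm = arm,
         expected_cost = sum(grid$prob * grid$cost),
         expected_qaly = sum(grid$prob * grid$qaly),
         remission_probability = rem_p,
         session_fee = session_fee),
    class = "arm_result"
  )
  attr(res, "branches") <- grid
  res
}
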