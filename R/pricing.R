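# Value-based pricing: inversion of the threshold identity.
#
# Value-based pricing sets the price so that the ICER against the
# comparator equals the willingness-to-pay threshold lambda:
#
#     c / h = (p + b) / h = lambda
#
# where c is the incremental cost, h the incremental QALY gain, p the
# price of the CBT course and b the induced (non-price) incremental
# costs — negative when CBT saves money downstream. Because the
# incremental cost is affine in the per-session fee, the fee solving the
# identity is obtained by a closed-form linear solve.

# Incremental result as a function of the candidate per-session fee f.
# Under self-referential comparator pricing the psychotherapy consumed in
# the comparator arm is billed at the same fee f (a value-based fee
# applies to all psychotherapy in the system); under current-price
# comparator pricing it stays at the current fee.
.incremental_at_fee <- function(params, fee,
                                comparator_pricing = c("value_based", "current_price")) {
  comparator_pricing <- match.arg(comparator_pricing)
  soc_fee <- if (comparator_pricing == "value_based") fee else params$cost_per_session
  incremental(
    arm_outcomes(params, "CBT", fee),
    arm_outcomes(params, "standard_of_care", soc_fee)
  )
}

# Affine decomposition of the incremental cost: c(f) = intercept + slope * f.
# The intercept is the induced (non-price) incremental cost b; the slope is
# the number of session-equivalents effectively billed (n * (1 - prop_psy)
# under self-referential pricing, n under current-price pricing).
.pricing_coefficients <- function(params, comparator_pricing = "value_based") {
  i0 <- .incremental_at_fee(params, 0, comparator_pricing)
  i1 <- .incremental_at_fee(params, 1, comparator_pricing)
  list(h = i0$delta_qaly,
       intercept = i0$delta_cost,
       slope = i1$delta_cost - i0$delta_cost)
}

#' Value-based price and per-session fee at a willingness-to-pay threshold
#'
#' Solves for the session fee `f` at which the decision model's ICER
#' equals the threshold `wtp`. By default the comparator arm's
#' psychotherapy is billed at the same candidate fee (self-referential
#' pricing, giving an effective multiplier of
#' `n_sessions * (1 - prop_psychotherapy)` billed session-equivalents);
#' `comparator_pricing = "current_price"` instead holds comparator
#' psychotherapy at the current fee. An optional `extra_qaly_gain` is
#' added to the model's incremental QALYs before solving (used by the
#' suicide-aversion extension).
#'
#' Negative fees — arithmetically possible at low thresholds when the
#' induced costs are positive — are returned as-is with a warning, since
#' the fee-threshold relationship is an unconstrained affine map.
#'
#' @param params A valid `cbt_parameters` object with a positive
#'   incremental QALY gain.
#' @param wtp Willingness-to-pay threshold in euros per QALY
#'   (default: `params$wtp_threshold`).
#' @param comparator_pricing `"value_based"` (default) or
#'   `"current_price"`; see Details.
#' @param extra_qaly_gain Additional incremental QALYs per patient beyond
#'   the remission pathway (default 0).
#' @return A `pricing_result`: list with `fee_per_session` (euros per
#'   50-minute session), `total_price` (`n_sessions * fee`),
#'   `induced_costs` (net non-price incremental costs `b`, negative =
#'   savings; satisfies `(total_price + b) / h = wtp`), `qaly_gain`
#'   (the `h` used) and `wtp`.
#' @seealso [fee_curve()], [adjusted_fee()]
#' @export
#' @examples
#' value_based_price(default_parameters(), wtp = 88000)
value_based_price <- function(params, wtp = params$wtp_threshold,
                              comparator_pricing = c("value_based", "current_price"),
                              extra_qaly_gain = 0) {
  comparator_pricing <- match.arg(comparator_pricing)
  stopifnot(is.numeric(wtp), length(wtp) == 1L, is.finite(wtp))
  if (wtp < 0) stop("negative willingness-to-pay threshold", call. = FALSE)
  stopifnot(extra_qaly_gain >= 0)

  co <- .pricing_coefficients(params, comparator_pricing)
  h <- co$h + extra_qaly_gain
  if (h <= 0) {
    stop("value-based pricing is undefined: incremental QALY gain is not positive",
         call. = FALSE)
  }
  if (co$slope <= 0) {
    stop("degenerate model: no net billed session-equivalents (prop_psychotherapy >= 1?)",
         call. = FALSE)
  }

  fee <- (wtp * h - co$intercept) / co$slope
  if (fee < 0) {
    warning(sprintf("value-based fee is negative (EUR %.2f) at threshold %g",
                    fee, wtp))
  }
  total <- params$n_sessions * fee
  structure(
    list(fee_per_session = fee,
         total_price = total,
         induced_costs = wtp * h - total,
         qaly_gain = h,
         wtp = wtp,
         comparator_pricing = comparator_pricing),
    class = "pricing_result"
  )
}

#' @export
print.pricing_result <- function(x, ...) {
  cat(sprintf("value-based fee: EUR %.2f per 50-minute session (EUR %.0f rounded)\n",
              x$fee_per_session, round(x$fee_per_session)))
  cat(sprintf("  course price EUR %.2f over the treatment course\n", x$total_price))
  cat(sprintf("  induced costs EUR %.2f (negative = net savings)\n", x$induced_costs))
  cat(sprintf("  QALY gain %.6f at threshold EUR %g per QALY\n", x$qaly_gain, x$wtp))
  invisible(x)
}

#' Value-based fee across a grid of willingness-to-pay thresholds
#'
#' Evaluates [value_based_price()] on a strictly increasing grid of
#' thresholds. The fee is an affine function of the threshold with slope
#' `h / (n_sessions * (1 - prop_psychotherapy))`, so the curve is a
#' straight line.
#'
#' @inheritParams value_based_price
#' @param wtp_grid Strictly increasing vector of non-negative thresholds
#'   (euros per QALY).
#' @return A data frame with columns `wtp` and `fee_per_session`.
#' @export
#' @examples
#' fee_curve(default_parameters(), seq(0, 150000, by = 25000))
fee_curve <- function(params, wtp_grid,
                      comparator_pricing = c("value_based", "current_price")) {
  comparator_pricing <- match.arg(comparator_pricing)
  stopifnot(is.numeric(wtp_grid), length(wtp_grid) >= 1L, all(wtp_grid >= 0))
  if (length(wtp_grid) > 1L && any(diff(wtp_grid) <= 0)) {
    stop("wtp_grid must be strictly increasing", call. = FALSE)
  }
  fees <- vapply(
    wtp_grid,
    function(l) value_based_price(params, l, comparator_pricing)$fee_per_session,
    numeric(1)
  )
  data.frame(wtp = wtp_grid, fee_per_session = fees)
}

#' Follow-up therapy specification
#'
#' Describes one or more subsequent (e.g. maintenance) therapies whose
#' incremental costs and health benefits are each proportional to those
#' of the initial course, with total proportionality factor
#' `x = sum(components)`. The factor can absorb time discounting and
#' probabilities of later therapies.
#'
#' @param components Non-negative proportionality factors, one per
#'   subsequent therapy.
#' @return A `followup_spec`: list with `components`, their count `n`
#'   and total `x`.
#' @export
followup_spec <- function(components) {
  stopifnot(is.numeric(components), all(is.finite(components)),
            all(components >= 0))
  structure(list(components = as.numeric(components),
                 n = length(components),
                 x = sum(components)),
            class = "followup_spec")
}

#' Offset invariance of the ICER under threshold-priced follow-up therapy
#'
#' When subsequent therapies are themselves priced at the threshold,
#' their incremental costs and health benefits are proportional to those
#' of the initial course, and folding them in rescales numerator and
#' denominator identically: `(c(1+x)) / (h(1+x)) = c/h`. The ICER of the
#' initial course is therefore invariant to any sequence of
#' threshold-priced follow-up therapies — which is why the model's
#' horizon can stop at the end of the acute course.
#'
#' @param base An `incremental_result` with a non-zero QALY difference.
#' @param spec A [followup_spec()] (or a single non-negative number,
#'   taken as the total factor `x`).
#' @return An `incremental_result` with `delta_cost` and `delta_qaly`
#'   scaled by `1 + x`; its ICER equals `base$icer` up to floating-point
#'   error.
#' @export
#' @examples
#' p <- default_parameters()
#' base <- incremental(arm_outcomes(p, "CBT", p$cost_per_session),
#'                     arm_outcomes(p, "standard_of_care", p$cost_per_session))
#' followup_invariance(base, followup_spec(c(0.4, 1.8, 1.5)))$icer - base$icer
followup_invariance <- function(base, spec) {
  stopifnot(inherits(base, "incremental_result"))
  if (!inherits(spec, "followup_spec")) spec <- followup_spec(spec)
  if (!base$icer_defined) {
    stop("base incremental result has a zero QALY difference", call. = FALSE)
  }
  scale <- 1 + spec$x
  dc <- base$delta_cost * scale
  dq <- base$delta_qaly * scale
  structure(
    list(delta_cost = dc, delta_qaly = dq, icer = dc / dq,
         icer_defined = TRUE),
    class = "incremental_result"
  )
}
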