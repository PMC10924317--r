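# Parameter registry and configuration I/O.
#
# All model inputs live in a single flat `cbt_parameters` list. Quantities
# that carry a published 95% confidence interval (or an explicit sensitivity
# range) are stored as `param_value` objects holding mean/low/high; fixed
# quantities (unit costs, session counts, conventions) are plain numerics.

#' Create a parameter value with optional uncertainty bounds
#'
#' A `param_value` bundles a point estimate with the bounds of its 95%
#' confidence interval, when one is available. Fixed quantities are stored
#' as plain numerics instead.
#'
#' @param mean Point estimate (base-case value).
#' @param low,high Lower/upper bound of the 95% confidence interval, or `NA`
#'   when no interval is available.
#' @param range_type `"ci"` for a genuine 95% confidence interval (eligible
#'   for probabilistic sampling), `"scenario"` for a deterministic
#'   sensitivity range that is not a confidence interval (varied in one-way
#'   analyses but never sampled).
#' @return An object of class `param_value`.
#' @export
#' @examples
#' param_value(0.73, 0.69, 0.77)
param_value <- function(mean, low = NA_real_, high = NA_real_,
                        range_type = c("ci", "scenario")) {
  range_type <- match.arg(range_type)
  stopifnot(is.numeric(mean), length(mean) == 1L)
  structure(
    list(mean = as.numeric(mean), low = as.numeric(low),
         high = as.numeric(high), range_type = range_type),
    class = "param_value"
  )
}

#' @export
print.param_value <- function(x, ...) {
  if (has_bounds(x)) {
    cat(sprintf("%g (%g-%g)\n", x$mean, x$low, x$high))
  } else {
    cat(sprintf("%g\n", x$mean))
  }
  invisible(x)
}

has_bounds <- function(x) {
  inherits(x, "param_value") && is.finite(x$low) && is.finite(x$high)
}

# Point estimate of either a param_value or a plain numeric.
pv_mean <- function(x) if (inherits(x, "param_value")) x$mean else x

# Field classification used by validation, sensitivity and sampling.
.proportion_fields <- c(
  "abs_remission_reduction", "control_remission_rate", "prop_moderate",
  "prop_psychotherapy", "prop_antidepressant", "discount_rate_annual"
)
.utility_fields <- c("utility_remission", "utility_moderate", "utility_severe")
.cost_fields <- c(
  "cost_per_session", "cost_antidepressant_12mo", "cost_depression_2mo",
  "indirect_cost_2mo"
)
.pv_fields <- c(
  "abs_remission_reduction", "utility_remission", "utility_moderate",
  "utility_severe", "prop_moderate", "prop_psychotherapy",
  "prop_antidepressant", "indirect_cost_2mo"
)

#' Base-case model parameters
#'
#' Returns the full base-case parameterisation of the depression
#' cost-utility model from the German statutory health insurance
#' perspective: the absolute remission-rate reduction of CBT over
#' treatment as usual (stored as the reciprocal of the meta-analytic
#' number needed to treat, 1/10.08), EQ-5D preference weights for
#' remission and for moderate/severe depression, the 68%/32%
#' moderate/severe case mix, unit costs in 2019 euros, treatment-as-usual
#' utilisation fractions, the 15-session course at the current fee of
#' EUR 103.87 per 50-minute session, a 12-week (0.25-year) horizon and a
#' willingness-to-pay threshold of EUR 88,000 per QALY.
#'
#' Indirect (productivity) costs default to zero; the EUR 200.64
#' two-month figure is carried as a deterministic sensitivity range.
#' With a sub-year horizon the annual discount rate defaults to 0.
#'
#' @return An object of class `cbt_parameters`: a named list whose
#'   uncertain entries are [param_value] objects and whose fixed entries
#'   are plain numerics.
#' @seealso [validate_parameters()], [load_parameters()], [write_config()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$cost_per_session
#' p$abs_remission_reduction
default_parameters <- function() {
  structure(list(
    abs_remission_reduction = param_value(1 / 10.08, 0.027, 0.172),
    control_remission_rate  = 0.35,
    utility_remission       = param_value(0.73, 0.69, 0.77),
    utility_moderate        = param_value(0.51, 0.47, 0.55),
    utility_severe          = param_value(0.37, 0.33, 0.41),
    prop_moderate           = param_value(0.68, 0.61, 0.75),
    cost_per_session        = 103.87,
    n_sessions              = 15,
    cost_antidepressant_12mo = 70.96,
    prop_psychotherapy      = param_value(0.10, 0.06, 0.15),
    prop_antidepressant     = param_value(0.26, 0.19, 0.33),
    cost_depression_2mo     = 173.30,
    indirect_cost_2mo       = param_value(0, 0, 200.64, range_type = "scenario"),
    horizon_years           = 0.25,
    wtp_threshold           = 88000,
    discount_rate_annual    = 0
  ), class = "cbt_parameters")
}

#' @export
print.cbt_parameters <- function(x, ...) {
  cat("Depression cost-utility model parameters\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "param_value")) {
      if (has_bounds(v)) {
        cat(sprintf("  %-26s %g (%g-%g)%s\n", nm, v$mean, v$low, v$high,
                    if (v$range_type == "scenario") " [scenario range]" else ""))
      } else {
        cat(sprintf("  %-26s %g\n", nm, v$mean))
      }
    } else {
      cat(sprintf("  %-26s %g\n", nm, v))
    }
  }
  invisible(x)
}

# Severity-weighted preference score of untreated (non-remitted) depression.
baseline_utility <- function(params) {
  pm <- pv_mean(params$prop_moderate)
  pm * pv_mean(params$utility_moderate) +
    (1 - pm) * pv_mean(params$utility_severe)
}

issue <- function(parameter, message, severity) {
  data.frame(parameter = parameter, message = message, severity = severity,
             stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: confidence
#' bounds ordered around the mean, proportions and utilities in \[0, 1\],
#' non-negative costs, at least one session, a positive horizon, and a
#' combined remission probability (control rate plus treatment effect)
#' not exceeding 1. A baseline utility at or above the remission utility
#' is reported as a warning: the model is still evaluable but yields a
#' non-positive QALY gain, so value-based pricing is undefined.
#'
#' @param params A `cbt_parameters` object.
#' @return A data frame with columns `parameter`, `message` and
#'   `severity` (`"error"` or `"warning"`); zero rows when all
#'   invariants hold.
#' @export
#' @examples
#' validate_parameters(default_parameters())  # zero rows
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cbt_parameters"))
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue(...)

  for (nm in names(params)) {
    v <- params[[nm]]
    if (inherits(v, "param_value") && has_bounds(v) &&
        !(v$low <= v$mean && v$mean <= v$high)) {
      add(nm, sprintf("bounds must satisfy low <= mean <= high (got %g <= %g <= %g)",
                      v$low, v$mean, v$high), "error")
    }
  }
  for (nm in c(.proportion_fields, .utility_fields)) {
    m <- pv_mean(params[[nm]])
    kind <- if (nm %in% .utility_fields) "utility" else "proportion"
    if (!is.finite(m) || m < 0 || m > 1) {
      add(nm, sprintf("%s must lie in [0, 1] (got %g)", kind, m), "error")
    }
  }
  for (nm in .cost_fields) {
    m <- pv_mean(params[[nm]])
    if (!is.finite(m) || m < 0) {
      add(nm, sprintf("cost must be non-negative (got %g)", m), "error")
    }
  }
  if (params$n_sessions < 1) {
    add("n_sessions", "at least one session is required", "error")
  }
  if (!is.finite(params$horizon_years) || params$horizon_years <= 0) {
    add("horizon_years", "time horizon must be positive", "error")
  }
  if (params$wtp_threshold < 0) {
    add("wtp_threshold", "willingness-to-pay threshold must be non-negative", "error")
  }

  rem_total <- pv_mean(params$control_remission_rate) +
    pv_mean(params$abs_remission_reduction)
  if (is.finite(rem_total) && rem_total > 1) {
    add("abs_remission_reduction",
        sprintf("control remission rate plus treatment effect exceeds 1 (got %g)",
                rem_total), "error")
  }

  u_rem <- pv_mean(params$utility_remission)
  u_base <- baseline_utility(params)
  if (is.finite(u_rem) && is.finite(u_base) && u_base >= u_rem) {
    add("utility_remission",
        sprintf("baseline utility (%g) is at or above the remission utility (%g); the model yields a non-positive QALY gain",
                u_base, u_rem), "warning")
  }

  if (length(issues) == 0L) {
    return(data.frame(parameter = character(), message = character(),
                      severity = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

# Coerce one config entry onto the corresponding default field.
.merge_field <- function(nm, value, default) {
  if (inherits(default, "param_value")) {
    if (is.list(value)) {
      allowed <- c("mean", "low", "high", "range_type")
      extra <- setdiff(names(value), allowed)
      if (length(extra) > 0L) {
        stop(sprintf("unknown key '%s.%s' in configuration", nm, extra[[1L]]),
             call. = FALSE)
      }
      if (is.null(value$mean)) {
        stop(sprintf("configuration entry '%s' must supply a mean", nm),
             call. = FALSE)
      }
      grab <- function(k) {
        if (is.null(value[[k]])) NA_real_ else as.numeric(value[[k]])
      }
      param_value(as.numeric(value$mean), grab("low"), grab("high"),
                  range_type = if (is.null(value$range_type)) "ci"
                               else value$range_type)
    } else if (is.numeric(value) && length(value) == 1L) {
      # A bare scalar replaces the point estimate and drops any bounds:
      # the default interval need not contain the user's value.
      param_value(as.numeric(value))
    } else {
      stop(sprintf("configuration entry '%s' must be a number or a {mean, low, high} object",
                   nm), call. = FALSE)
    }
  } else {
    if (!is.numeric(value) || length(value) != 1L) {
      stop(sprintf("configuration entry '%s' must be a single number", nm),
           call. = FALSE)
    }
    as.numeric(value)
  }
}

#' Read model parameters from a configuration document
#'
#' Reads a flat JSON key-value document (or an equivalent named list) with
#' one key per model parameter; uncertain quantities may be given either
#' as a bare number (point estimate, no interval) or as a nested
#' `{mean, low, high}` object. Keys absent from the document fall back to
#' [default_parameters()]; unknown keys are rejected. The merged set is
#' validated and any validation *error* aborts the load.
#'
#' @param config Path to a JSON file, or a named list already parsed.
#' @return A validated `cbt_parameters` object.
#' @export
#' @examples
#' p <- load_parameters(list(wtp_threshold = 50000))
#' p$wtp_threshold
load_parameters <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    doc <- tryCatch(
      jsonlite::fromJSON(config, simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("cannot parse configuration '%s': %s", config,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  } else if (is.list(config)) {
    doc <- config
  } else {
    stop("config must be a file path or a named list", call. = FALSE)
  }
  if (length(doc) > 0L && (is.null(names(doc)) || any(names(doc) == ""))) {
    stop("configuration entries must all be named", call. = FALSE)
  }

  params <- default_parameters()
  unknown <- setdiff(names(doc), names(params))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key '%s'", unknown[[1L]]),
         call. = FALSE)
  }
  for (nm in names(doc)) {
    params[[nm]] <- .merge_field(nm, doc[[nm]], params[[nm]])
  }

  problems <- validate_parameters(params)
  errs <- problems[problems$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop(sprintf("invalid configuration: %s",
                 paste(sprintf("%s: %s", errs$parameter, errs$message),
                       collapse = "; ")), call. = FALSE)
  }
  params
}

#' Write model parameters to a JSON configuration file
#'
#' Emits the flat key-value document read back by [load_parameters()];
#' the round trip reproduces the parameter set exactly. Uncertain
#' quantities are written as `{mean, low, high}` objects (bounds omitted
#' when absent); fixed quantities as bare numbers.
#'
#' @param params A valid `cbt_parameters` object.
#' @param path Destination file path; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "cbt_parameters"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write configuration: directory '%s' does not exist",
                 dirname(path)), call. = FALSE)
  }
  doc <- lapply(params, function(v) {
    if (inherits(v, "param_value")) {
      out <- list(mean = v$mean)
      if (is.finite(v$low)) out$low <- v$low
      if (is.finite(v$high)) out$high <- v$high
      if (!identical(v$range_type, "ci")) out$range_type <- v$range_type
      out
    } else {
      v
    }
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
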