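# Seeded sampling of parameter sets from the published 95% confidence
# intervals, so every pipeline stage can be exercised on plausible "new
# study" inputs without any external data.

#' Sampling specification
#'
#' @param n_draws Number of parameter sets to draw (>= 1).
#' @param seed Integer seed; identical `(spec, base)` pairs produce
#'   identical draws. Mandatory — there is no silent nondeterminism.
#' @return A `sampling_spec` object.
#' @export
sampling_spec <- function(n_draws, seed) {
  stopifnot(is.numeric(n_draws), length(n_draws) == 1L, n_draws >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "sampling_spec")
}

# Legal domain of one sampled field, beyond which a draw is resampled.
.field_domain <- function(name) {
  if (name %in% c(.proportion_fields, .utility_fields)) c(0, 1) else c(0, Inf)
}

#' Draw parameter sets from the published confidence intervals
#'
#' Each parameter carrying a genuine 95% confidence interval is drawn
#' independently from a normal distribution with the base-case mean and
#' standard deviation `(high - low) / 3.92` (the CI width in standard
#' errors), resampled until it falls in its legal domain (proportions and
#' utilities into \[0, 1\], costs non-negative) and until the joint
#' constraint on the total remission probability holds. Parameters
#' without an interval — and deterministic scenario ranges such as the
#' indirect-cost toggle — are held fixed. Drawn sets carry point
#' estimates only (the bounds describe the uncertainty *about* the base
#' case, not about a draw) and every draw passes [validate_parameters()]
#' with zero errors.
#'
#' @param base A valid `cbt_parameters` object to sample around.
#' @param spec A [sampling_spec()], or `n_draws` and `seed` given
#'   directly.
#' @param n_draws,seed Convenience alternative to `spec`.
#' @return A `parameter_draws` object: list with `draws` (a list of
#'   `cbt_parameters`) and `spec` (the generating [sampling_spec()]).
#' @export
#' @examples
#' d <- sample_parameters(default_parameters(), n_draws = 5, seed = 42)
#' length(d$draws)
sample_parameters <- function(base = default_parameters(), spec = NULL,
                              n_draws = NULL, seed = NULL) {
  if (is.null(spec)) {
    if (is.null(n_draws) || is.null(seed)) {
      stop("either a sampling_spec or both n_draws and seed must be given",
           call. = FALSE)
    }
    spec <- sampling_spec(n_draws, seed)
  }
  stopifnot(inherits(spec, "sampling_spec"))
  problems <- validate_parameters(base)
  if (any(problems$severity == "error")) {
    stop("base parameter set fails validation", call. = FALSE)
  }

  sampled_fields <- names(base)[vapply(
    base, function(v) has_bounds(v) && identical(v$range_type, "ci"),
    logical(1)
  )]

  draw_field <- function(nm) {
    pv <- base[[nm]]
    sd <- (pv$high - pv$low) / 3.92
    dom <- .field_domain(nm)
    for (i in seq_len(1000L)) {
      x <- stats::rnorm(1L, mean = pv$mean, sd = sd)
      if (x >= dom[1] && x <= dom[2]) return(x)
    }
    stop(sprintf("could not draw '%s' inside its legal domain after 1000 attempts",
                 nm), call. = FALSE)
  }

  control <- pv_mean(base$control_remission_rate)
  one_draw <- function() {
    p <- base
    for (nm in sampled_fields) {
      x <- draw_field(nm)
      # joint constraint: total remission probability must stay in [0, 1]
      if (nm == "abs_remission_reduction") {
        tries <- 0L
        while (control + x > 1 && tries < 1000L) {
          x <- draw_field(nm)
          tries <- tries + 1L
        }
        if (control + x > 1) {
          stop("could not draw a feasible remission reduction", call. = FALSE)
        }
      }
      p[[nm]] <- param_value(x)
    }
    p
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  draws <- replicate(spec$n_draws, one_draw(), simplify = FALSE)

  structure(list(draws = draws, spec = spec), class = "parameter_draws")
}

#' @export
print.parameter_draws <- function(x, ...) {
  cat(sprintf("%d parameter draw(s) sampled with seed %d\n",
              length(x$draws), x$spec$seed))
  invisible(x)
}
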