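#' Growth-curve parameters of the Zwietering logistic model
#'
#' Bundles the four parameters that describe one bacterial growth curve:
#' the absorbance at inoculation `y0` (OD units), the lag time `lag`
#' (hours), the maximum growth rate `mu` (OD per hour, the slope at the
#' inflection point), and the biomass yield `A` (the asymptotic OD reached
#' in stationary phase).
#'
#' A well is considered non-growing when the asymptote does not exceed the
#' starting absorbance (`A <= y0`); [amplitude()] returns `A - y0`, the
#' total biomass accumulated over the experiment.
#'
#' @param y0 Starting absorbance (OD), `>= 0`.
#' @param lag Lag time (hours), `>= 0`.
#' @param mu Maximum growth rate (OD/h), `>= 0`.
#' @param A Biomass yield / asymptote (OD), `> 0`.
#'
#' @return An object of class `growth_params`.
#' @examples
#' p <- growth_params(y0 = 0.05, lag = 10, mu = 0.2, A = 1.0)
#' amplitude(p)
#' @export
growth_params <- function(y0, lag, mu, A) {
  stopifnot(is.numeric(y0), is.numeric(lag), is.numeric(mu), is.numeric(A),
            length(y0) == 1L, length(lag) == 1L, length(mu) == 1L,
            length(A) == 1L)
  if (!all(is.finite(c(y0, lag, mu, A))))
    stop("growth parameters must be finite", call. = FALSE)
  if (y0 < 0) stop("y0 must be non-negative", call. = FALSE)
  if (lag < 0) stop("lag must be non-negative", call. = FALSE)
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (A <= 0) stop("asymptote must be positive", call. = FALSE)
  structure(list(y0 = y0, lag = lag, mu = mu, A = A),
            class = "growth_params")
}

#' @rdname growth_params
#' @param params A `growth_params` object.
#' @export
amplitude <- function(params) params$A - params$y0

#' @rdname growth_params
#' @export
is_non_growing <- function(params) params$A <= params$y0

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Zwietering parameters: y0 = %.4g, lag = %.4g h, mu = %.4g OD/h, A = %.4g%s\n",
    x$y0, x$lag, x$mu, x$A,
    if (is_non_growing(x)) "  [non-growing]" else ""))
  invisible(x)
}

#' A single well's absorbance time series
#'
#' @param time Time points in hours; strictly increasing, all `>= 0`.
#' @param od Absorbance readings (OD), same length as `time`. Values are
#'   assumed to be blank-corrected; no background subtraction is applied.
#' @param well_id Optional well label, e.g. `"A01"`.
#' @param sample Optional sample / condition name.
#'
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time, od, well_id = NULL, sample = NULL) {
  stopifnot(is.numeric(time), is.numeric(od))
  if (length(time) != length(od))
    stop("time and od must have the same length", call. = FALSE)
  if (length(time) < 3L)
    stop("a growth curve needs at least 3 time points", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("time points must be finite and non-negative", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time points must be strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time), od = as.numeric(od),
                 well_id = well_id, sample = sample),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  lab <- paste(c(x$sample, x$well_id), collapse = " / ")
  cat(sprintf("Growth curve%s: %d points over %.4g-%.4g h, OD %.3g-%.3g\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              length(x$time), min(x$time), max(x$time),
              min(x$od), max(x$od)))
  invisible(x)
}

# Exponent clamp: beyond +-700 exp() over/underflows in double precision;
# clamping returns the exact asymptote instead of Inf/NaN.
.EXP_CLAMP <- 700

#' Evaluate the Zwietering logistic growth model
#'
#' Computes the modeled absorbance
#' \deqn{\hat y(t) = y_0 + \frac{A - y_0}{1 + \exp[(4\mu/A)(\lambda - t) + 2]}}
#' elementwise on a time grid. This reparameterization of the logistic
#' curve makes the lag time the intercept of the inflection-point tangent
#' with the baseline, and `mu` the slope (OD/h) at the inflection point.
#'
#' @param params A [growth_params()] object (`A > 0` required).
#' @param time Numeric vector of times in hours; may be empty.
#'
#' @return Numeric vector of modeled OD values, one per time point. For
#'   finite times every value lies strictly between `y0` and `A`.
#' @examples
#' p <- growth_params(0.05, 10, 0.2, 1.0)
#' zwietering(p, c(0, 10, 50, 240))
#' @export
zwietering <- function(params, time) {
  stopifnot(inherits(params, "growth_params"), is.numeric(time))
  if (length(time) == 0L) return(numeric(0))
  z <- (4 * params$mu / params$A) * (params$lag - time) + 2
  z <- pmin(pmax(z, -.EXP_CLAMP), .EXP_CLAMP)
  params$y0 + (params$A - params$y0) / (1 + exp(z))
}
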