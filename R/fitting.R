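#' Options controlling the logistic fit
#'
#' @param max_iterations Maximum optimizer iterations.
#' @param tolerance Relative convergence tolerance applied to both the cost
#'   and the parameter step.
#' @param smoothing_window Odd window length (in time points) of the moving
#'   median used only to build the starting values; the objective always
#'   uses the raw readings.
#' @param multistart If `TRUE`, also try 5 seeded perturbed starts and keep
#'   the best fit; useful for hard curves. The single-start fit is fully
#'   deterministic.
#' @param multistart_seed Seed for the perturbed starts.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 200L, tolerance = 1e-10,
                        smoothing_window = 3L, multistart = FALSE,
                        multistart_seed = 1L) {
  stopifnot(tolerance > 0, smoothing_window >= 1L,
            smoothing_window %% 2L == 1L, max_iterations >= 1L)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 smoothing_window = as.integer(smoothing_window),
                 multistart = isTRUE(multistart),
                 multistart_seed = as.integer(multistart_seed)),
            class = "fit_options")
}

.smooth_od <- function(od, window) {
  if (window <= 1L || length(od) < window) return(od)
  as.numeric(stats::runmed(od, window, endrule = "median"))
}

.MU_FLOOR <- 1e-6

#' Starting values for the Zwietering logistic fit
#'
#' Heuristic estimates from a median-smoothed copy of the curve: `y0` is
#' the median of the first readings, `A` the smoothed maximum, and `lag`
#' the intercept of the tangent through the steepest point with the `y0`
#' baseline, clipped to the observed time window. The `mu` start inverts
#' the steepest finite-difference slope through the amplitude ratio: the
#' model's inflection slope is `mu (A - y0)/A`, so the observed slope is
#' scaled by `A / (A - y0)` (floored at a small positive value). A flat
#' curve gets `mu` at the floor and `lag = 0`.
#'
#' @param curve A [growth_curve()].
#' @param opts A [fit_options()].
#' @return A [growth_params()] starting point.
#' @export
initial_guess <- function(curve, opts = fit_options()) {
  stopifnot(inherits(curve, "growth_curve"), inherits(opts, "fit_options"))
  t <- curve$time
  od <- .smooth_od(curve$od, opts$smoothing_window)
  n <- length(od)
  y0 <- stats::median(od[seq_len(min(3L, n))])
  A <- max(A_raw <- max(od), .Machine$double.eps)
  slopes <- diff(od) / diff(t)
  k <- which.max(slopes)
  s <- slopes[k]
  if (s <= 0) {
    mu <- .MU_FLOOR
    lag <- 0
  } else {
    # amplitude guard keeps the inversion bounded on near-flat curves
    amp <- max(A - y0, 0.05 * A)
    mu <- max(s * A / amp, .MU_FLOOR)
    # midpoint of the steepest segment; tangent through it crosses y0 at lag
    tm <- (t[k] + t[k + 1]) / 2
    ym <- (od[k] + od[k + 1]) / 2
    lag <- min(max(tm - (ym - y0) / s, 0), max(t))
  }
  growth_params(y0 = max(y0, 0), lag = lag, mu = mu, A = A)
}

.zw_eval <- function(p, t) {
  z <- (4 * p[3] / p[4]) * (p[2] - t) + 2
  z <- pmin(pmax(z, -.EXP_CLAMP), .EXP_CLAMP)
  p[1] + (p[4] - p[1]) / (1 + exp(z))
}

.fit_once <- function(start, t, od, lower, upper, opts) {
  start <- pmin(pmax(start, lower), upper)
  out <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p) od - .zw_eval(p, t),
    control = minpack.lm::nls.lm.control(
      maxiter = opts$max_iterations,
      ftol = opts$tolerance, ptol = opts$tolerance, gtol = 0))
  list(par = out$par, rss = out$deviance, converged = out$info %in% 1:4)
}

#' Fit the Zwietering logistic model by bounded least squares
#'
#' Minimises the unweighted residual sum of squares
#' \eqn{\sum_i (od_i - \hat y_i)^2} over the four parameters with the
#' Levenberg-Marquardt algorithm, inside box bounds chosen to keep the
#' exponent well scaled and the parameters physical: `y0` in
#' `[0, max(od)]`, `A` in `[min(od), 2 max(od)]` (floored at a tiny
#' positive value), `mu` in `[1e-6, 10 x the amplitude-corrected slope
#' estimate of the initial guess]`, `lag` in `[0, max(time)]`. The start comes from [initial_guess()]; the fit is
#' deterministic unless `opts$multistart` is set.
#'
#' @param curve A [growth_curve()] with at least 4 points and finite OD.
#' @param opts A [fit_options()].
#' @return An object of class `fit_result`: `params` ([growth_params()]),
#'   `fitted` (modeled OD on the input grid), `rss`, `converged`,
#'   `n_points`. On non-convergence the best iterate is returned with
#'   `converged = FALSE`.
#' @examples
#' p <- growth_params(0.05, 20, 0.3, 1.0)
#' cv <- growth_curve(seq(0, 240, 0.5), zwietering(p, seq(0, 240, 0.5)))
#' fit_logistic(cv)$params
#' @export
fit_logistic <- function(curve, opts = fit_options()) {
  stopifnot(inherits(curve, "growth_curve"), inherits(opts, "fit_options"))
  t <- curve$time
  od <- curve$od
  if (length(t) < 4L)
    stop("need at least 4 points to fit 4 parameters", call. = FALSE)
  if (any(!is.finite(od)))
    stop("non-finite readings", call. = FALSE)

  g <- initial_guess(curve, opts)
  start <- c(g$y0, g$lag, g$mu, g$A)
  # mu bound uses the amplitude-corrected slope estimate from the guess:
  # on shallow curves the raw observed slope is mu (A - y0)/A, far below mu
  lower <- c(0, 0, .MU_FLOOR, max(min(od), .Machine$double.eps))
  upper <- c(max(od), max(t), 10 * g$mu, 2 * max(od))
  upper <- pmax(upper, lower + .Machine$double.eps)

  best <- .fit_once(start, t, od, lower, upper, opts)
  if (opts$multistart) {
    withr::with_seed(opts$multistart_seed, {
      for (i in 1:5) {
        s <- start * stats::runif(4, 0.7, 1.3)
        cand <- .fit_once(s, t, od, lower, upper, opts)
        if (cand$rss < best$rss) best <- cand
      }
    })
  }

  p <- best$par
  params <- growth_params(y0 = p[1], lag = p[2], mu = p[3], A = p[4])
  structure(list(params = params,
                 fitted = .zw_eval(p, t),
                 rss = best$rss,
                 converged = best$converged,
                 n_points = length(t)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Logistic fit on %d points: rss = %.4g, converged = %s\n",
              x$n_points, x$rss, x$converged))
  print(x$params)
  invisible(x)
}
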