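#' Configuration of the synthetic growth-curve cohort
#'
#' Defines the study conditions for the GL-vs-GS comparison: 1,000
#' noise-free Zwietering logistic curves on a 0-240 h grid, with parameters
#' drawn uniformly from realistic phenotype-assay ranges. The growth-rate
#' range is tied to the drawn yield: `mu` between `A / total_time` (yield
#' reached only at the end of the experiment, very slow growth) and
#' `1.1 * A` (yield reached within about an hour, very fast growth).
#'
#' @param n_curves Number of curves (default 1000).
#' @param total_time Experiment length in hours (default 240).
#' @param dt Grid spacing in hours (default 0.5, i.e. 481 points). GL
#'   averages over grid points, so `dt` matters to GL and is recorded in
#'   outputs.
#' @param seed Optional RNG seed for reproducible cohorts.
#' @param y0_range,lag_range,A_range Uniform sampling intervals for the
#'   starting absorbance, lag time (h), and yield.
#' @param mu_upper_factor Upper bound of `mu` as a multiple of the drawn
#'   `A` (default 1.1).
#' @param noise_sd Standard deviation of optional Gaussian observation
#'   noise added to the OD readings (default 0: noise-free, the comparison
#'   condition; nonzero values are for exercising the fitter).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_curves = 1000L, total_time = 240,
                              dt = 0.5, seed = NULL,
                              y0_range = c(0.05, 0.10),
                              lag_range = c(0, 120),
                              A_range = c(0.1, 1.2),
                              mu_upper_factor = 1.1,
                              noise_sd = 0) {
  stopifnot(n_curves >= 1L, total_time > 0, dt > 0,
            y0_range[1] < y0_range[2], lag_range[1] < lag_range[2],
            A_range[1] < A_range[2], mu_upper_factor > 0, noise_sd >= 0)
  structure(list(n_curves = as.integer(n_curves), total_time = total_time,
                 dt = dt, seed = seed, y0_range = y0_range,
                 lag_range = lag_range, A_range = A_range,
                 mu_upper_factor = mu_upper_factor, noise_sd = noise_sd),
            class = "simulation_config")
}

#' Draw growth-curve parameters from the configured uniform ranges
#'
#' One uniform draw per parameter and curve, in the fixed order `y0`,
#' `lag`, `A`, then `mu`, so that seeded cohorts are reproducible across
#' versions. `A` is drawn before `mu` because the rate range depends on
#' the yield: `mu ~ U(A / total_time, mu_upper_factor * A)`.
#'
#' Uses the current RNG state; seed handling lives in [simulate_cohort()].
#'
#' @param config A [simulation_config()].
#' @param n Number of parameter sets (default `config$n_curves`).
#' @return A data.frame with columns `y0`, `lag`, `mu`, `A`.
#' @export
sample_parameters <- function(config, n = config$n_curves) {
  stopifnot(inherits(config, "simulation_config"))
  y0 <- stats::runif(n, config$y0_range[1], config$y0_range[2])
  lag <- stats::runif(n, config$lag_range[1], config$lag_range[2])
  A <- stats::runif(n, config$A_range[1], config$A_range[2])
  mu <- stats::runif(n, A / config$total_time, config$mu_upper_factor * A)
  data.frame(y0 = y0, lag = lag, mu = mu, A = A)
}

#' Simulate a cohort of noise-free logistic growth curves
#'
#' Draws `n_curves` parameter sets ([sample_parameters()]) and evaluates
#' the Zwietering model on the shared grid `0, dt, ..., total_time`. When
#' `config$noise_sd > 0`, i.i.d. Gaussian noise is added to every reading.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the
#'   whole cohort is a deterministic function of the config; the global
#'   RNG state is left untouched.
#' @return An object of class `growth_cohort`: list with `params`
#'   (data.frame, one row per curve), `time` (shared grid), `od` (matrix,
#'   one row per curve) and `config`. [cohort_curve()] extracts one curve.
#' @examples
#' co <- simulate_cohort(simulation_config(n_curves = 5, seed = 1))
#' dim(co$od)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  build <- function() {
    time <- seq(0, config$total_time, by = config$dt)
    params <- sample_parameters(config)
    od <- t(vapply(seq_len(nrow(params)), function(i) {
      p <- growth_params(params$y0[i], params$lag[i],
                         params$mu[i], params$A[i])
      y <- zwietering(p, time)
      if (config$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, config$noise_sd)
      y
    }, numeric(length(time))))
    structure(list(params = params, time = time, od = od, config = config),
              class = "growth_cohort")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, build()) else build()
}

#' @rdname simulate_cohort
#' @param cohort A `growth_cohort`.
#' @param i Curve index.
#' @export
cohort_curve <- function(cohort, i) {
  stopifnot(inherits(cohort, "growth_cohort"))
  growth_curve(cohort$time, cohort$od[i, ],
               well_id = NULL, sample = sprintf("sim%04d", i))
}

#' @export
print.growth_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d curves x %d time points (0-%g h, dt = %g h)\n",
              nrow(x$od), ncol(x$od), x$config$total_time, x$config$dt))
  invisible(x)
}

#' Per-curve GL and GS for a simulated cohort
#'
#' GL is the harmonic-mean metric over each model curve on its grid; GS is
#' computed from the true simulated parameters. For noise-free cohorts a
#' refit would reproduce the generating parameters, so the metrics are
#' taken directly from the truth; the fitter is exercised separately.
#'
#' @param cohort A `growth_cohort` from [simulate_cohort()].
#' @return A data.frame: the parameter columns plus `gl` and `gs`.
#' @export
cohort_scores <- function(cohort) {
  stopifnot(inherits(cohort, "growth_cohort"))
  p <- cohort$params
  x <- (cohort$od - p$y0) + (p$A - p$y0)   # recycles by row: n_curves rows
  gl <- ifelse(apply(x <= 0, 1L, any), 0,
               ncol(x) / rowSums(1 / x))
  gs <- (p$A - p$y0) + 0.25 * p$mu
  cbind(p, gl = gl, gs = gs)
}

#' Compare Growth Level and Growth Score over a simulated cohort
#'
#' Computes the statistics behind the metric comparison: Pearson
#' correlation between GL and GS (with two-sided p-value), adjusted
#' Fisher-Pearson sample skewness of each metric, the least-squares
#' regression of GS on GL, and the class-agreement counts -- how many
#' curves receive different qualitative labels under the two metrics, and
#' how many of those cross the no-growth boundary (move between `"-"` and
#' any `"+"` class).
#'
#' @param cohort A `growth_cohort` with at least 3 curves.
#' @param gl_thresholds,gs_thresholds [class_thresholds()] used for the
#'   class-change counts; defaults from [default_thresholds()].
#' @return An object of class `comparison_report`: `pearson_r`, `p_value`,
#'   `skew_gl`, `skew_gs`, `regression` (named vector: slope, intercept),
#'   `n_reclassified`, `n_sign_flips`, `n_curves`, `dt`.
#' @examples
#' co <- simulate_cohort(simulation_config(n_curves = 100, seed = 7))
#' compare_metrics(co)
#' @export
compare_metrics <- function(cohort,
                            gl_thresholds = default_thresholds()$gl,
                            gs_thresholds = default_thresholds()$gs) {
  stopifnot(inherits(cohort, "growth_cohort"))
  if (nrow(cohort$od) < 3L)
    stop("need at least 3 curves to compare metrics", call. = FALSE)
  sc <- cohort_scores(cohort)
  .compare_scores(sc, gl_thresholds, gs_thresholds, dt = cohort$config$dt)
}

# Comparison statistics from a table with gl and gs columns; shared by
# compare_metrics() and the CLI `compare` verb.
.compare_scores <- function(sc, gl_thresholds, gs_thresholds, dt = NA_real_) {
  if (nrow(sc) < 3L)
    stop("need at least 3 curves to compare metrics", call. = FALSE)
  ct <- stats::cor.test(sc$gl, sc$gs, method = "pearson")
  reg <- stats::lm(gs ~ gl, data = sc)
  gl_class <- classify(sc$gl, gl_thresholds)
  gs_class <- classify(sc$gs, gs_thresholds)
  changed <- gl_class != gs_class
  lowest_gl <- gl_class == gl_thresholds$labels[1]
  lowest_gs <- gs_class == gs_thresholds$labels[1]
  structure(list(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    skew_gl = e1071::skewness(sc$gl, type = 2),
    skew_gs = e1071::skewness(sc$gs, type = 2),
    regression = c(slope = unname(stats::coef(reg)[2]),
                   intercept = unname(stats::coef(reg)[1])),
    n_reclassified = sum(changed),
    n_sign_flips = sum(changed & (lowest_gl != lowest_gs)),
    n_curves = nrow(sc),
    dt = dt), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("GL vs GS over %d curves (dt = %g h):\n", x$n_curves, x$dt))
  cat(sprintf("  Pearson r      %.4f  (p = %.3g)\n", x$pearson_r, x$p_value))
  cat(sprintf("  skewness       GL %.4f, GS %.4f\n", x$skew_gl, x$skew_gs))
  cat(sprintf("  GS ~ GL        slope %.4f, intercept %.4f\n",
              x$regression["slope"], x$regression["intercept"]))
  cat(sprintf("  reclassified   %d  (of which %d cross the no-growth line)\n",
              x$n_reclassified, x$n_sign_flips))
  invisible(x)
}
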