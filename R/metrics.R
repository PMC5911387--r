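#' Growth Level: harmonic-mean growth metric over the fitted curve
#'
#' The legacy metric used by PMAnalyzer-style pipelines. Each fitted OD
#' value is shifted by the curve's amplitude,
#' \eqn{x_i = (\hat y_i - y_0) + (A - y_0)}, and GL is the harmonic mean
#' \eqn{n / \sum_i 1/x_i}. Because it averages over the whole observed
#' time window, GL depends implicitly on lag time and experiment length.
#'
#' GL is always computed on the model curve \eqn{\hat y}, not on the raw
#' readings. If any \eqn{x_i \le 0} (possible for non-growing wells where
#' `A <= y0`), the metric is defined as 0 and the result carries the
#' attribute `degenerate = TRUE`; flat wells are routine inputs and must
#' not error.
#'
#' @param fitted Numeric vector of modeled OD values on the observed grid.
#' @param y0 Starting absorbance of the fit.
#' @param A Asymptote of the fit.
#'
#' @return The GL value (OD units); attribute `degenerate` is `TRUE` when
#'   the zero rule was applied.
#' @examples
#' growth_level(c(0.2, 0.6, 1.0), y0 = 0.1, A = 1.0)
#' @export
growth_level <- function(fitted, y0, A) {
  stopifnot(is.numeric(fitted), length(y0) == 1L, length(A) == 1L)
  if (length(fitted) == 0L)
    stop("fitted curve is empty", call. = FALSE)
  x <- (fitted - y0) + (A - y0)
  if (any(x <= 0))
    return(structure(0, degenerate = TRUE))
  structure(length(x) / sum(1 / x), degenerate = FALSE)
}

#' Growth Score: single-number growth metric from fitted parameters
#'
#' \eqn{GS = (A - y_0) + 0.25\mu}: the amplitude (total biomass
#' accumulated) plus a quarter of the maximum growth rate. Unlike the
#' Growth Level it uses only curve parameters, so it is independent of lag
#' time and experiment length and can be computed from any software that
#' reports logistic-fit parameters. The rate enters at 25% weight so that
#' biomass accumulation stays the primary component; a short burst of fast
#' growth with low yield cannot dominate the score.
#'
#' A non-growing fit (`A <= y0`) yields a score `<= 0`, reported as
#' computed (not clamped) so downstream statistics are unbiased;
#' classification maps it to the lowest class.
#'
#' @param params A [growth_params()] object.
#' @return The GS value (OD units).
#' @examples
#' growth_score(growth_params(y0 = 0.1, lag = 30, mu = 0.4, A = 1.1))
#' @export
growth_score <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  (params$A - params$y0) + 0.25 * params$mu
}

#' Ordered class thresholds for qualitative growth labels
#'
#' Growth metrics are discretised into ordinal classes from no growth
#' (`"-"`) to very high growth (`"++++"`). `cutoffs` are inclusive lower
#' bounds: a value exactly equal to a cutoff belongs to the higher class.
#'
#' @param labels Ordered character vector of class labels, lowest first.
#' @param cutoffs Strictly ascending numeric vector of lower bounds, one
#'   per label above the lowest (`length(cutoffs) == length(labels) - 1`).
#' @return An object of class `class_thresholds`.
#' @examples
#' class_thresholds(c("-", "+", "++", "+++", "++++"),
#'                  c(0.25, 0.75, 1.25, 1.75))
#' @export
class_thresholds <- function(labels, cutoffs) {
  stopifnot(is.character(labels), is.numeric(cutoffs))
  if (length(cutoffs) != length(labels) - 1L)
    stop("need exactly one cutoff per label above the lowest", call. = FALSE)
  if (length(cutoffs) > 1L && any(diff(cutoffs) <= 0))
    stop("cutoffs must be strictly ascending", call. = FALSE)
  structure(list(labels = labels, cutoffs = as.numeric(cutoffs)),
            class = "class_thresholds")
}

#' Assign a qualitative growth class to a metric value
#'
#' @param value Numeric vector of metric values (GL or GS).
#' @param thresholds A [class_thresholds()] object.
#' @return Character vector of class labels; the label index is the number
#'   of cutoffs `<=` the value (values below every cutoff get the lowest
#'   label).
#' @examples
#' th <- default_thresholds()$gl
#' classify(c(-0.2, 0.6, 2.1), th)
#' @export
classify <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "class_thresholds"), is.numeric(value))
  idx <- vapply(value, function(v) sum(thresholds$cutoffs <= v), integer(1))
  thresholds$labels[idx + 1L]
}

#' Score one fitted curve with both metrics and their classes
#'
#' Convenience composition of [growth_level()], [growth_score()] and
#' [classify()] for one [fit_logistic()] result.
#'
#' @param fit A `fit_result` from [fit_logistic()].
#' @param gl_thresholds,gs_thresholds [class_thresholds()] for each metric;
#'   defaults come from [default_thresholds()].
#' @param allow_unconverged Score a fit whose optimizer did not converge
#'   (default `FALSE`, which errors).
#' @return An object of class `score_result`: list with `gl`, `gs`,
#'   `gl_class`, `gs_class`, `degenerate_gl`.
#' @export
score_curve <- function(fit,
                        gl_thresholds = default_thresholds()$gl,
                        gs_thresholds = default_thresholds()$gs,
                        allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged && !allow_unconverged)
    stop("fit did not converge; pass allow_unconverged = TRUE to score anyway",
         call. = FALSE)
  gl <- growth_level(fit$fitted, fit$params$y0, fit$params$A)
  gs <- growth_score(fit$params)
  structure(list(gl = as.numeric(gl), gs = gs,
                 gl_class = classify(as.numeric(gl), gl_thresholds),
                 gs_class = classify(gs, gs_thresholds),
                 degenerate_gl = isTRUE(attr(gl, "degenerate"))),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("GL = %.4g (%s)   GS = %.4g (%s)%s\n",
              x$gl, x$gl_class, x$gs, x$gs_class,
              if (x$degenerate_gl) "  [degenerate GL]" else ""))
  invisible(x)
}

#' Read growth-class thresholds from a flat key/value file
#'
#' The file format is plain text, one `key = value` pair per line, with
#' comma-separated lists; `#` starts a comment. Recognised keys: `labels`
#' (shared by both metrics), `gl_cutoffs`, `gs_cutoffs`.
#'
#' @param path Path to the threshold file.
#' @return List with elements `gl` and `gs`, each a [class_thresholds()].
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed threshold line: ", ln, call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(strsplit(trimws(parts[2]), ",")[[1]])
  }
  for (key in c("labels", "gl_cutoffs", "gs_cutoffs"))
    if (is.null(kv[[key]]))
      stop("threshold file is missing key: ", key, call. = FALSE)
  labels <- kv$labels
  list(gl = class_thresholds(labels, as.numeric(kv$gl_cutoffs)),
       gs = class_thresholds(labels, as.numeric(kv$gs_cutoffs)))
}

#' Default growth-class thresholds
#'
#' Implementation defaults shipped with the package (the original
#' PMAnalyzer cutoff values are not published): GL cutoffs 0.25 / 0.75 /
#' 1.25 / 1.75, and GS cutoffs obtained by mapping those through the GS-on-GL
#' regression line of a default simulated cohort, so the two label sets are
#' comparable. Override with [read_thresholds()] or [class_thresholds()].
#'
#' @return List with elements `gl` and `gs`, each a [class_thresholds()].
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds.conf",
                              package = "growthscore", mustWork = TRUE))
}
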