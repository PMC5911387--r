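# Independent scalar oracle for the Zwietering logistic form: direct
# transcription of the closed-form expression, kept separate from the
# package's clamped vectorised implementation.
ref_logistic <- function(y0, lag, mu, A, t) {
  y0 + (A - y0) / (1 + exp((4 * mu / A) * (lag - t) + 2))
}

# Noise-free model curve on a plate-reader style grid.
sim_curve <- function(y0, lag, mu, A, total_time = 240, dt = 0.5) {
  t <- seq(0, total_time, by = dt)
  growth_curve(t, zwietering(growth_params(y0, lag, mu, A), t))
}

# Random parameter draws from the simulation-study ranges.
draw_params <- function(n, total_time = 240) {
  y0 <- runif(n, 0.05, 0.10)
  lag <- runif(n, 0, 120)
  A <- runif(n, 0.1, 1.2)
  mu <- runif(n, A / total_time, 1.1 * A)
  data.frame(y0 = y0, lag = lag, mu = mu, A = A)
}

rel_err <- function(est, true) abs(est - true) / abs(true)
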