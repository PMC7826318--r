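# Shared fixtures: small simulated panels and fast fitting options.

quick_options <- function(seed = 1L, se = FALSE) {
  fit_options(max_extra_attempts = 5L, se = se, seed = seed)
}

small_panel <- function(seed = 1L, n_persons = 6L, n_occasions = 40L,
                        n_series = 2L, noise_sd = rep(0.5, n_series), ...) {
  simulate_panel(sim_config(n_persons = n_persons, n_occasions = n_occasions,
                            n_series = n_series, noise_sd = noise_sd,
                            seed = seed, ...))
}

# Independent 4th-order Runge-Kutta integrator for the DLO initial value
# problem; the numerical oracle for the closed-form trajectory.
rk4_dlo <- function(eta, zeta, x0, v0, t_end, step) {
  n <- ceiling(t_end / step)
  x <- x0; v <- v0
  deriv <- function(x, v) c(v, eta * x + zeta * v)
  for (i in seq_len(n)) {
    h <- min(step, t_end - (i - 1) * step)
    k1 <- deriv(x, v)
    k2 <- deriv(x + h / 2 * k1[1], v + h / 2 * k1[2])
    k3 <- deriv(x + h / 2 * k2[1], v + h / 2 * k2[2])
    k4 <- deriv(x + h * k3[1], v + h * k3[2])
    x <- x + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    v <- v + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  x
}

# Independent dense multivariate-normal log-density: explicit determinant
# and linear solve, no Cholesky/pattern machinery shared with the package.
dense_mvn_logdens <- function(x, mu, Sigma) {
  k <- length(x)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(Sigma)$modulus) +
            as.numeric(d %*% solve(Sigma, d)))
}
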