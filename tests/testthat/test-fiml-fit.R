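# Helper: wrap a raw matrix as a tde_matrix for likelihood tests.
as_tde <- function(values, row_person, D, P,
                   series_names = paste0("series_", seq_len(P))) {
  structure(list(values = values, row_person = row_person, D = as.integer(D),
                 tau = 1L, delta_t = 1,
                 series_names = series_names),
            class = "tde_matrix")
}

# A spec/theta pair with known moments for likelihood checks.
loglik_fixture <- function(P = 3, D = 5, person_ids = 1) {
  spec <- lde_spec(2, D = D, P = P, person_ids = person_ids)
  theta <- theta_template(spec)
  theta[c("eta", "zeta")] <- c(-0.05, -0.1)
  if (P > 1) theta[paste0("l", 2:P)] <- seq(0.7, by = 0.2,
                                            length.out = P - 1)
  theta[c("v_f", "v_df", "c_fdf")] <- c(1.2, 0.1, 0.05)
  theta["v_e_d2"] <- 0.01
  theta[spec$unique_names] <- seq(0.3, by = 0.1, length.out = P)
  theta[spec$mean_names] <- seq(2, by = 1.5,
                                length.out = length(person_ids))
  list(spec = spec, theta = theta)
}

test_that("a standard-normal row contributes the textbook density", {
  spec <- lde_spec(2, D = 5, P = 3, person_ids = 1)
  theta <- theta_template(spec)
  theta[c("eta", "zeta", "c_fdf", "m_1")] <- 0
  # Sigma = I requires zero latent variance and unit unique variances
  theta[c("v_f", "v_df", "v_e_d2")] <- 1e-300
  theta[paste0("u_series_", 1:3)] <- 1
  data <- as_tde(matrix(0, 1, 15), row_person = 1, D = 5, P = 3)
  expect_equal(total_loglik(spec, theta, data), -15 / 2 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("FIML matches an independent dense MVN density on complete rows", {
  fx <- loglik_fixture(person_ids = 1:3)
  Sigma <- implied_covariance(fx$spec, fx$theta)
  set.seed(7)
  W <- matrix(rnorm(9 * 15, sd = 2), 9, 15)
  person <- rep(1:3, each = 3)
  data <- as_tde(W, person, D = 5, P = 3)
  expected <- sum(vapply(1:9, function(i) {
    dense_mvn_logdens(W[i, ], implied_row_mean(fx$spec, fx$theta, person[i]),
                      Sigma)
  }, numeric(1)))
  expect_equal(total_loglik(fx$spec, fx$theta, data), expected,
               tolerance = 1e-10)
})

test_that("rows with deleted cells contribute their analytic marginal density", {
  fx <- loglik_fixture(person_ids = 1)
  Sigma <- implied_covariance(fx$spec, fx$theta)
  mu <- implied_row_mean(fx$spec, fx$theta, 1)
  set.seed(8)
  W <- matrix(rnorm(6 * 15, mean = 2, sd = 2), 6, 15)
  W[2, c(1, 7, 15)] <- NA
  W[4, 1:10] <- NA
  W[5, ] <- NA  # fully missing row contributes 0
  data <- as_tde(W, rep(1, 6), D = 5, P = 3)
  expected <- sum(vapply(1:6, function(i) {
    o <- which(!is.na(W[i, ]))
    if (length(o) == 0) return(0)
    dense_mvn_logdens(W[i, o], mu[o], Sigma[o, o, drop = FALSE])
  }, numeric(1)))
  expect_equal(total_loglik(fx$spec, fx$theta, data), expected,
               tolerance = 1e-10)

  # deleting a cell changes only that row's contribution
  W2 <- W
  W2[3, 4] <- NA
  ll_rows <- function(W, i) {
    total_loglik(fx$spec, fx$theta, as_tde(W[i, , drop = FALSE], 1, 5, 3))
  }
  for (i in c(1, 2, 4, 6)) {
    expect_equal(ll_rows(W2, i), ll_rows(W, i), tolerance = 1e-12)
  }
})

test_that("fit recovers generating parameters on a clean panel", {
  eta_true <- -0.02; zeta_true <- -0.03
  panel <- simulate_panel(sim_config(
    params = dlo_params(eta_true, zeta_true), n_persons = 10,
    n_occasions = 80, n_series = 2, series_loadings = c(1, 0.8),
    equilibrium_mean = 5, equilibrium_sd = 2, init_pos_sd = 4,
    init_vel_sd = 0.3, noise_sd = c(0.05, 0.05), seed = 21))
  tde <- embed_panel(panel, D = 6)
  spec <- lde_spec(2, D = 6, P = 2, person_ids = unique(panel$person_id))
  fit <- fit_lde(spec, tde, quick_options(seed = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["eta"]] - eta_true) / abs(eta_true), 0.10)
  expect_lt(abs(fit$estimates[["zeta"]] - zeta_true) / abs(zeta_true), 0.10)
  expect_lt(abs(fit$estimates[["l2"]] - 0.8), 0.05)
  # person equilibria recovered
  m_hat <- fit$estimates[paste0("m_", 1:10)]
  expect_lt(max(abs(m_hat - attr(panel, "equilibria"))), 0.5)

  # reported -2 lnL reproducible from the estimates
  expect_equal(fit$minus2ll, -2 * total_loglik(spec, fit$estimates, tde),
               tolerance = 1e-6)
  # stationary point: gradient of the profiled objective is tiny
  expect_lt(fit$grad_norm, 1e-2 * max(1, abs(fit$loglik)))

  # determinism: identical seed and options give identical results
  fit2 <- fit_lde(spec, tde, quick_options(seed = 2))
  expect_identical(fit2$estimates, fit$estimates)
  expect_identical(fit2$minus2ll, fit$minus2ll)

  # refitting from the solution converges immediately to the same optimum
  refit <- fit_lde(spec, tde, fit_options(max_extra_attempts = 1, se = FALSE,
                                          seed = 3),
                   start = fit$estimates)
  expect_true(refit$converged)
  expect_lt(abs(refit$minus2ll - fit$minus2ll), 1e-4)
})

test_that("FIML on complete data equals the pattern-free likelihood", {
  fx <- loglik_fixture(person_ids = 1:2)
  Sigma <- implied_covariance(fx$spec, fx$theta)
  Rchol <- chol(Sigma)
  set.seed(9)
  W <- matrix(rnorm(8 * 15), 8, 15)
  person <- rep(1:2, each = 4)
  data <- as_tde(W, person, D = 5, P = 3)
  # complete-data likelihood computed directly, no missingness machinery
  logdet <- 2 * sum(log(diag(Rchol)))
  ll_direct <- sum(vapply(1:8, function(i) {
    d <- W[i, ] - implied_row_mean(fx$spec, fx$theta, person[i])
    z <- backsolve(Rchol, d, transpose = TRUE)
    -0.5 * (15 * log(2 * pi) + logdet + sum(z^2))
  }, numeric(1)))
  expect_equal(total_loglik(fx$spec, fx$theta, data), ll_direct,
               tolerance = 1e-12)
})

test_that("two-stage derivative regression agrees with FIML at low noise", {
  eta_true <- -0.03; zeta_true <- -0.04
  panel <- simulate_panel(sim_config(
    params = dlo_params(eta_true, zeta_true), n_persons = 10,
    n_occasions = 80, n_series = 1, series_loadings = 1,
    equilibrium_mean = 0, equilibrium_sd = 0, init_pos_sd = 4,
    init_vel_sd = 0.3, noise_sd = 0.01, seed = 31))
  D <- 7
  tde <- embed_panel(panel, D = D)
  spec <- lde_spec(2, D = D, P = 1, person_ids = unique(panel$person_id))
  fit <- fit_lde(spec, tde, quick_options(seed = 4))

  # independent closed-form route: project each window on the Taylor basis
  # (ordinary least squares), then regress f'' on (f, f')
  L <- build_loading_matrix(D, 2, 1)
  derivs <- t(solve(t(L) %*% L, t(L) %*% t(tde$values)))
  ols <- stats::lm.fit(cbind(derivs[, 1], derivs[, 2]), derivs[, 3])
  eta_ols <- ols$coefficients[1]
  zeta_ols <- ols$coefficients[2]

  expect_equal(unname(sign(eta_ols)), sign(fit$estimates[["eta"]]))
  expect_equal(unname(sign(zeta_ols)), sign(fit$estimates[["zeta"]]))
  expect_lt(abs(eta_ols - fit$estimates[["eta"]]) / abs(eta_ols), 0.15)
  expect_lt(abs(zeta_ols - fit$estimates[["zeta"]]) / abs(zeta_ols), 0.15)
})

test_that("non-positive-definite implied covariance is rejected, not crashed", {
  fx <- loglik_fixture()
  theta <- fx$theta
  theta[c("u_series_1", "u_series_2", "u_series_3")] <- 1e-300
  theta[c("v_f", "v_df", "v_e_d2")] <- 1e-300
  data <- as_tde(matrix(rnorm(15), 1, 15), 1, 5, 3)
  ll <- total_loglik(fx$spec, theta, data)
  expect_identical(ll, structure(-Inf, npd = TRUE))
})

test_that("likelihood-ratio test compares SOLDE and FOLDE with 2 df", {
  panel <- small_panel(seed = 13, n_persons = 5, n_occasions = 30,
                       n_series = 1, noise_sd = 0.3)
  tde <- embed_panel(panel, D = 5)
  ids <- unique(panel$person_id)
  s2 <- lde_spec(2, D = 5, P = 1, person_ids = ids)
  s4 <- lde_spec(4, D = 5, P = 1, person_ids = ids)
  f2 <- fit_lde(s2, tde, quick_options(seed = 6))
  f4 <- fit_lde(s4, tde, quick_options(seed = 6))
  lrt <- likelihood_ratio_test(f2, f4)
  expect_equal(lrt$df, 2L)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 2, lower.tail = FALSE))

  # identical log-likelihoods give statistic 0, p = 1
  f2b <- f2
  f2b$minus2ll <- f4$minus2ll
  lrt0 <- likelihood_ratio_test(f2b, f4)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)

  # a negative statistic is clipped with a warning
  f2c <- f2
  f2c$minus2ll <- f4$minus2ll - 0.5
  expect_warning(lrt_neg <- likelihood_ratio_test(f2c, f4), "clipped")
  expect_equal(lrt_neg$statistic, 0)

  # non-nested layouts are refused
  tde6 <- embed_panel(panel, D = 6)
  s4b <- lde_spec(4, D = 6, P = 1, person_ids = ids)
  f4b <- fit_lde(s4b, tde6, quick_options(seed = 6))
  expect_error(likelihood_ratio_test(f2, f4b), "not nested")
})

test_that("LRT under a true second-order process rejects at nominal-or-below rate", {
  # scaled-down null simulation (40 small univariate panels rather than 200
  # multivariate ones, to keep the suite fast); the wide acceptance band
  # acknowledges boundary effects on the added variance parameters
  n_rep <- 40
  p_values <- numeric(n_rep)
  opts <- fit_options(max_extra_attempts = 2, se = FALSE, seed = 17)
  for (r in seq_len(n_rep)) {
    panel <- simulate_panel(sim_config(
      params = dlo_params(-0.04, -0.02), n_persons = 6, n_occasions = 35,
      n_series = 1, series_loadings = 1, equilibrium_mean = 0,
      equilibrium_sd = 1, init_pos_sd = 3, init_vel_sd = 0.3,
      noise_sd = 0.3, seed = 1000 + r))
    tde <- embed_panel(panel, D = 5)
    ids <- unique(panel$person_id)
    f2 <- fit_lde(lde_spec(2, D = 5, P = 1, person_ids = ids), tde, opts)
    f4 <- fit_lde(lde_spec(4, D = 5, P = 1, person_ids = ids), tde, opts)
    p_values[r] <- suppressWarnings(likelihood_ratio_test(f2, f4))$p_value
  }
  rate <- mean(p_values < 0.05)
  expect_gte(rate, 0)
  expect_lte(rate, 0.12)
})

test_that("standard errors come back finite and plausibly scaled", {
  panel <- small_panel(seed = 23, n_persons = 6, n_occasions = 50,
                       n_series = 1, noise_sd = 0.3)
  tde <- embed_panel(panel, D = 5)
  spec <- lde_spec(2, D = 5, P = 1, person_ids = unique(panel$person_id))
  fit <- fit_lde(spec, tde, quick_options(seed = 8, se = TRUE))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se)))
  expect_gt(fit$se[["eta"]], 0)
  # the generating eta is inside a wide naive interval
  expect_lt(abs(fit$estimates[["eta"]] - (-0.0095)),
            6 * fit$se[["eta"]] + 0.01)
})
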