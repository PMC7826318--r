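# Full-information ML estimation of an LDE model on a time delay-embedded
# matrix: pattern-wise row likelihood, quasi-Newton fitting with perturbed
# restarts, naive observed-information standard errors, and the
# likelihood-ratio comparison of nested models.

LOG_2PI <- log(2 * pi)

# Group rows of the TDE matrix by missingness pattern. Returns a list of
# groups, each with the observed column indices and the member row indices.
# Computed once per data set and reused across likelihood evaluations.
missingness_patterns <- function(values) {
  obs <- !is.na(values)
  key <- do.call(paste0, as.data.frame(obs * 1L))
  groups <- split(seq_len(nrow(values)), key)
  lapply(groups, function(rows) {
    list(obs = which(obs[rows[1], ]), rows = rows)
  })
}

# Shared per-fit state: data matrix, pattern groups, person index per row.
fiml_state <- function(spec, data) {
  stopifnot(inherits(spec, "lde_spec"), inherits(data, "tde_matrix"))
  if (ncol(data$values) != spec$D * spec$P) {
    stop(sprintf("data has %d columns but spec implies D*P = %d",
                 ncol(data$values), spec$D * spec$P), call. = FALSE)
  }
  person <- as.character(data$row_person)
  unknown <- setdiff(unique(person), spec$person_ids)
  if (length(unknown) > 0L) {
    stop(sprintf("data contains persons not in spec: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  list(W = data$values,
       patterns = missingness_patterns(data$values),
       person_idx = match(person, spec$person_ids),
       n_persons = length(spec$person_ids))
}

# Core pattern-wise log-likelihood given Sigma and a per-row mean matrix.
# Returns -Inf (with attribute "npd" = TRUE) when any observed submatrix of
# Sigma is not positive definite.
loglik_patterns <- function(state, Sigma, mu) {
  ll <- 0
  for (g in state$patterns) {
    k <- length(g$obs)
    if (k == 0L) next  # empty rows contribute 0
    R <- tryCatch(chol(Sigma[g$obs, g$obs, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(R)) {
      out <- -Inf
      attr(out, "npd") <- TRUE
      return(out)
    }
    logdet <- 2 * sum(log(diag(R)))
    resid <- state$W[g$rows, g$obs, drop = FALSE] -
      mu[g$rows, g$obs, drop = FALSE]
    z <- backsolve(R, t(resid), transpose = TRUE)
    ll <- ll - 0.5 * (length(g$rows) * (k * LOG_2PI + logdet) + sum(z^2))
  }
  ll
}

#' Full-information ML log-likelihood of an LDE model
#'
#' Each row of the time delay-embedded matrix contributes the multivariate
#' normal log-density of its OBSERVED cells only, using that row's person
#' mean and the corresponding submatrix of the model-implied covariance
#' (the marginalization property of the normal). Rows with no observed
#' cells contribute 0. Rows are treated as independent despite the window
#' overlap — the standard LDE estimation convention; see the fitted
#' object's documentation for the standard-error caveat this implies.
#'
#' @param spec An [lde_spec()].
#' @param theta Named parameter vector on the natural scale.
#' @param data A `tde_matrix` whose columns match `spec` (`D*P`) and whose
#'   persons are covered by `spec`.
#' @return The log-likelihood; `-Inf` (flagged with attribute `npd`) if an
#'   observed submatrix of the implied covariance is not positive definite.
#' @export
total_loglik <- function(spec, theta, data) {
  state <- fiml_state(spec, data)
  mm <- model_matrices(spec, theta)
  mu <- outer(mm$means[state$person_idx], mm$lambda0)
  loglik_patterns(state, mm$Sigma, mu)
}

# Profile log-likelihood over the person equilibrium means: given the
# structural parameters, the inner maximum over each m_j is closed-form
# generalized least squares across that person's rows and missingness
# patterns. Returns the profiled log-likelihood and the maximizing means.
profiled_loglik <- function(spec, theta_struct, state) {
  theta <- c(theta_struct,
             stats::setNames(rep(0, state$n_persons), spec$mean_names))
  mm <- tryCatch(model_matrices(spec, theta), error = function(e) NULL)
  if (is.null(mm) || !all(is.finite(mm$Sigma))) {
    return(list(loglik = -Inf, means = NULL))
  }
  Sigma <- mm$Sigma
  lambda0 <- mm$lambda0
  num <- numeric(state$n_persons)
  den <- numeric(state$n_persons)
  cache <- vector("list", length(state$patterns))
  for (i in seq_along(state$patterns)) {
    g <- state$patterns[[i]]
    k <- length(g$obs)
    if (k == 0L) next
    R <- tryCatch(chol(Sigma[g$obs, g$obs, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(R)) {
      out <- list(loglik = -Inf, means = NULL)
      return(out)
    }
    lam <- lambda0[g$obs]
    a <- backsolve(R, backsolve(R, lam, transpose = TRUE))  # Sigma_oo^-1 lam
    s <- sum(lam * a)
    w_a <- state$W[g$rows, g$obs, drop = FALSE] %*% a
    pid <- state$person_idx[g$rows]
    cache[[i]] <- list(R = R, lam = lam)
    tab <- rowsum(cbind(as.numeric(w_a), rep(s, length(g$rows))), pid)
    idx <- as.integer(rownames(tab))
    num[idx] <- num[idx] + tab[, 1]
    den[idx] <- den[idx] + tab[, 2]
  }
  means <- ifelse(den > 0, num / den, 0)
  mu <- outer(means, lambda0)[state$person_idx, , drop = FALSE]
  # reuse cached Cholesky factors for the density pass
  ll <- 0
  for (i in seq_along(state$patterns)) {
    g <- state$patterns[[i]]
    k <- length(g$obs)
    if (k == 0L) next
    R <- cache[[i]]$R
    logdet <- 2 * sum(log(diag(R)))
    resid <- state$W[g$rows, g$obs, drop = FALSE] -
      mu[g$rows, g$obs, drop = FALSE]
    z <- backsolve(R, t(resid), transpose = TRUE)
    ll <- ll - 0.5 * (length(g$rows) * (k * LOG_2PI + logdet) + sum(z^2))
  }
  list(loglik = ll, means = stats::setNames(means, spec$person_ids))
}

#' Fitting options
#'
#' @param max_extra_attempts Maximum number of perturbed restarts after the
#'   initial attempt (default 30, mirroring common try-hard practice).
#' @param perturb_half_width Half-width of the Uniform(-h, h) perturbation
#'   applied, per parameter on the transformed (log-variance) scale, to the
#'   best solution so far when restarting. Default 1.
#' @param maxit,reltol Optimizer controls: `maxit` iterations of
#'   box-constrained quasi-Newton (L-BFGS-B, log-variances floored at
#'   `log(1e-10)`), with `reltol` translated to the equivalent `factr`.
#'   An attempt is declared converged when the optimizer reports success
#'   and a fresh polish run
#'   started from its solution cannot improve the objective beyond
#'   `1e-6 * (1 + |objective|)`. The gradient norm at the solution is
#'   reported as a diagnostic (it is not scale-free: very low measurement
#'   noise makes the surface so sharp that a sizeable gradient corresponds
#'   to a negligible parameter displacement).
#' @param se Compute naive observed-information standard errors (finite
#'   difference Hessian). Disable for large simulation sweeps.
#' @param seed Integer seed governing the restart perturbations.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_extra_attempts = 30L, perturb_half_width = 1,
                        maxit = 500L, reltol = 1e-9,
                        se = TRUE, seed = 1L) {
  stopifnot(max_extra_attempts >= 0L, perturb_half_width >= 0,
            maxit >= 1L, reltol > 0)
  structure(list(max_extra_attempts = as.integer(max_extra_attempts),
                 perturb_half_width = perturb_half_width,
                 maxit = as.integer(maxit), reltol = reltol,
                 se = isTRUE(se),
                 seed = as.integer(seed)),
            class = "fit_options")
}

# Data-driven starting values on the natural scale (structural part only).
default_start <- function(spec, state) {
  W <- state$W
  # approximate per-person series span to guess a plausible wavelength
  rows_per_person <- tabulate(state$person_idx, state$n_persons)
  T_bar <- mean(rows_per_person[rows_per_person > 0]) + (spec$D - 1)
  eta0 <- -(2 * pi / (T_bar / 2 * spec$delta_t))^2
  first_block <- seq_len(spec$D)
  center_person <- function(cols) {
    v <- 0
    n <- 0
    for (j in seq_len(state$n_persons)) {
      rows <- which(state$person_idx == j)
      if (length(rows) < 2L) next
      x <- as.numeric(W[rows, cols])
      x <- x[!is.na(x)]
      if (length(x) > 1L) {
        v <- v + stats::var(x) * (length(x) - 1)
        n <- n + length(x) - 1
      }
    }
    if (n > 0) v / n else 1
  }
  w1 <- center_person(first_block)
  loadings0 <- numeric(0)
  u0 <- numeric(spec$P)
  u0[1] <- max(0.3 * w1, 1e-4)
  if (spec$P > 1L) {
    for (s in 2:spec$P) {
      cols <- (s - 1L) * spec$D + first_block
      ws <- center_person(cols)
      loadings0 <- c(loadings0, sqrt(max(ws, 1e-8) / max(w1, 1e-8)))
      u0[s] <- max(0.3 * ws, 1e-4)
    }
  }
  v_f0 <- max(0.7 * w1, 1e-4)
  v_df0 <- v_f0 * abs(eta0)
  resid0 <- rep(v_f0 * eta0^2 * 0.1, length(spec$resid_names))
  stats::setNames(c(eta0, 0, loadings0, v_f0, v_df0, 0, resid0, u0),
                  setdiff(spec$param_names, spec$mean_names))
}

numeric_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

numeric_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hs <- h * (1 + abs(x))
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hs[i]
        xm <- x; xm[i] <- x[i] - hs[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hs[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + hs[i]; xpp[j] <- x[j] + hs[j]
        xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
        xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
        xmm <- x; xmm[i] <- x[i] - hs[i]; xmm[j] <- x[j] - hs[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hs[i] * hs[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Fit an LDE model by full-information maximum likelihood
#'
#' Maximizes the FIML log-likelihood by BFGS on a transformed scale
#' (variances log-transformed; person equilibrium means profiled out in
#' closed form at every evaluation, which leaves a small structural
#' parameter vector for the optimizer). If an attempt fails to converge,
#' up to `max_extra_attempts` restarts are made, each starting from the
#' best solution so far perturbed per-parameter by a Uniform(-h, h) draw
#' on the transformed scale.
#'
#' Standard errors come from the inverse finite-difference observed
#' information of the full (joint) likelihood. Because overlapping embedded
#' rows are treated as independent observations, these SEs are *naive*
#' (anti-conservative); they are reported for comparability with standard
#' LDE practice, not as calibrated uncertainty.
#'
#' @param spec An [lde_spec()].
#' @param data A `tde_matrix` from [embed_panel()].
#' @param options A [fit_options()] list.
#' @param start Optional named starting vector (natural scale, structural
#'   parameters only or full).
#' @return An object of class `lde_fit` with elements `estimates`, `se`,
#'   `loglik`, `minus2ll`, `converged`, `n_attempts`, `grad_norm`,
#'   `history` (per-attempt data frame), `spec` and `options`. Never
#'   throws on non-convergence: the best point found is returned with
#'   `converged = FALSE`.
#' @examples
#' \donttest{
#' panel <- simulate_panel(sim_config(n_persons = 8, n_occasions = 40,
#'                                    n_series = 1, noise_sd = 0.5))
#' tde <- embed_panel(panel, D = 5)
#' spec <- lde_spec(2, D = 5, P = 1, person_ids = unique(panel$person_id))
#' fit <- fit_lde(spec, tde, fit_options(se = FALSE))
#' coef(fit)[c("eta", "zeta")]
#' }
#' @export
fit_lde <- function(spec, data, options = fit_options(), start = NULL) {
  stopifnot(inherits(spec, "lde_spec"), inherits(options, "fit_options"))
  state <- fiml_state(spec, data)
  informative <- sum(rowSums(!is.na(state$W)) > 0L)
  if (informative < spec$q + 1L) {
    stop(sprintf("only %d informative rows; need at least q + 1 = %d",
                 informative, spec$q + 1L), call. = FALSE)
  }
  struct_names <- setdiff(spec$param_names, spec$mean_names)
  struct_is_var <- spec$is_variance[match(struct_names, spec$param_names)]

  to_u <- function(th) { th[struct_is_var] <- log(th[struct_is_var]); th }
  from_u <- function(th) { th[struct_is_var] <- exp(th[struct_is_var]); th }

  if (is.null(start)) {
    start <- default_start(spec, state)
  } else {
    start <- start[intersect(names(start), struct_names)]
    full <- default_start(spec, state)
    full[names(start)] <- start
    start <- full
  }

  objective <- function(x_u) {
    th <- from_u(stats::setNames(x_u, struct_names))
    pl <- profiled_loglik(spec, th, state)
    if (!is.finite(pl$loglik)) return(1e12)
    -pl$loglik
  }

  # log-variances are bounded below so a vanishing variance component (a
  # boundary optimum, e.g. zero structural residual under clean dynamics)
  # terminates at the floor instead of crawling toward -Inf forever
  lower <- ifelse(struct_is_var, log(1e-10), -Inf)
  upper <- ifelse(struct_is_var, log(1e10), Inf)
  # coarse finite-difference gradients for the main descent, fine steps for
  # the polish rounds that settle (and certify) the optimum
  run_optim <- function(x0, ndeps = 1e-3, factr = NULL) {
    if (is.null(factr)) factr <- options$reltol / .Machine$double.eps
    stats::optim(pmin(pmax(x0, lower), upper), objective,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = options$maxit, factr = factr,
                                ndeps = rep(ndeps, length(x0))))
  }

  set.seed(options$seed)
  x_current <- to_u(start)
  best <- NULL
  history <- list()
  n_attempts <- 0L
  for (attempt in 0:options$max_extra_attempts) {
    n_attempts <- attempt + 1L
    opt <- tryCatch(run_optim(x_current), error = function(e) NULL)
    polish_gain <- NA_real_
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e11) {
      # polish: fresh runs from the solution reset the Hessian
      # approximation; failure to improve doubles as the convergence check
      for (round in 1:5) {
        opt2 <- tryCatch(run_optim(opt$par, ndeps = 1e-6, factr = 1e7),
                         error = function(e) NULL)
        if (is.null(opt2) || !is.finite(opt2$value) ||
            opt2$value > opt$value) break
        polish_gain <- opt$value - opt2$value
        opt <- opt2
        if (polish_gain <= 1e-6 * (1 + abs(opt$value))) break
      }
    }
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e11) {
      grad <- numeric_gradient(objective, opt$par)
      grad_norm <- sqrt(sum(grad^2))
      converged <- opt$convergence == 0L && !is.na(polish_gain) &&
        polish_gain <= 1e-6 * (1 + abs(opt$value))
      cand <- list(par = opt$par, value = opt$value, converged = converged,
                   grad_norm = grad_norm)
      history[[n_attempts]] <- data.frame(attempt = attempt,
                                          loglik = -opt$value,
                                          converged = converged,
                                          grad_norm = grad_norm)
      if (is.null(best) || cand$value < best$value ||
          (converged && !best$converged &&
             cand$value <= best$value + 1e-6 * (1 + abs(best$value)))) {
        best <- cand
      }
      if (best$converged) break
    } else {
      history[[n_attempts]] <- data.frame(attempt = attempt,
                                          loglik = NA_real_,
                                          converged = FALSE,
                                          grad_norm = NA_real_)
    }
    base_x <- if (!is.null(best)) best$par else x_current
    x_current <- base_x + stats::runif(length(base_x),
                                       -options$perturb_half_width,
                                       options$perturb_half_width)
  }
  if (is.null(best)) {
    best <- list(par = to_u(start), value = objective(to_u(start)),
                 converged = FALSE, grad_norm = NA_real_)
  }

  theta_struct <- from_u(stats::setNames(best$par, struct_names))
  pl <- profiled_loglik(spec, theta_struct, state)
  estimates <- c(theta_struct,
                 stats::setNames(pl$means, spec$mean_names))
  estimates <- estimates[spec$param_names]
  loglik <- total_loglik(spec, estimates, data)

  se <- stats::setNames(rep(NA_real_, length(estimates)), spec$param_names)
  if (options$se) {
    # Hessian on the transformed full-parameter scale (variances log), then
    # the delta method maps the covariance back to the natural scale.
    full_u <- to_unconstrained(spec, estimates)
    nll_full <- function(x_u) {
      th <- from_unconstrained(spec, stats::setNames(x_u, spec$param_names))
      mm <- model_matrices(spec, th)
      mu <- outer(mm$means[state$person_idx], mm$lambda0)
      ll <- loglik_patterns(state, mm$Sigma, mu)
      if (!is.finite(ll)) return(1e12)
      -ll
    }
    H <- numeric_hessian(nll_full, full_u)
    cov_u <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_u) && all(is.finite(diag(cov_u))) &&
        all(diag(cov_u) > 0)) {
      jac <- ifelse(spec$is_variance, estimates, 1)  # d natural / d transformed
      se <- stats::setNames(sqrt(diag(cov_u)) * abs(jac), spec$param_names)
    } else {
      warning("observed information not positive definite; SEs set to NA",
              call. = FALSE)
    }
  }

  structure(list(estimates = estimates, se = se, loglik = loglik,
                 minus2ll = -2 * loglik, converged = best$converged,
                 n_attempts = n_attempts, grad_norm = best$grad_norm,
                 history = do.call(rbind, history), spec = spec,
                 options = options),
            class = "lde_fit")
}

#' @export
coef.lde_fit <- function(object, ...) object$estimates

#' @export
logLik.lde_fit <- function(object, ...) {
  structure(object$loglik, df = count_free_parameters(object$spec),
            class = "logLik")
}

#' @export
print.lde_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, %d attempt%s)\n",
              if (x$spec$order == 2) "SOLDE" else "FOLDE",
              if (x$converged) "converged" else "NOT converged",
              x$n_attempts, if (x$n_attempts == 1) "" else "s"))
  eta <- x$estimates[["eta"]]; zeta <- x$estimates[["zeta"]]
  cat(sprintf("  eta  = %10.5f (SE %s)\n", eta, format(x$se[["eta"]], digits = 3)))
  cat(sprintf("  zeta = %10.5f (SE %s)\n", zeta, format(x$se[["zeta"]], digits = 3)))
  disc <- -eta - zeta^2 / 4
  if (disc > 0) {
    cat(sprintf("  wavelength = %.3f time units\n", 2 * pi / sqrt(disc)))
  } else {
    cat("  wavelength undefined (non-oscillating estimates)\n")
  }
  cat(sprintf("  -2 log L = %.4f on %d free parameters\n", x$minus2ll,
              count_free_parameters(x$spec)))
  invisible(x)
}

#' Likelihood-ratio test of nested LDE models
#'
#' Compares a SOLDE fit (nested) with a FOLDE fit (full) on the same
#' embedded data. With identical D, P and persons, the two models differ
#' by exactly the two structural residual variances of the third and
#' fourth derivatives, so the test has 2 degrees of freedom. A negative
#' statistic (possible from optimizer noise) is clipped to 0 with a
#' warning.
#'
#' @param nested An `lde_fit` of the order-2 model.
#' @param full An `lde_fit` of the order-4 model.
#' @return A list of class `lde_lrt` with `statistic`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "lde_fit"), inherits(full, "lde_fit"))
  sn <- nested$spec; sf <- full$spec
  if (!(sn$order < sf$order && sn$D == sf$D && sn$P == sf$P &&
        isTRUE(all.equal(sn$delta_t, sf$delta_t)) &&
        identical(sn$person_ids, sf$person_ids))) {
    stop("models are not nested: need a SOLDE fit inside a FOLDE fit with identical D, P, delta_t and persons",
         call. = FALSE)
  }
  statistic <- nested$minus2ll - full$minus2ll
  if (statistic < 0) {
    warning(sprintf("negative likelihood-ratio statistic (%.4g) clipped to 0 (optimizer noise)",
                    statistic), call. = FALSE)
    statistic <- 0
  }
  df <- count_free_parameters(sf) - count_free_parameters(sn)
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p_value = p,
                 minus2ll_nested = nested$minus2ll,
                 minus2ll_full = full$minus2ll),
            class = "lde_lrt")
}

#' @export
print.lde_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: SOLDE (nested) vs FOLDE (full)\n")
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Text report of a fitted LDE model
#'
#' One-page report highlighting the three headline outcomes: the frequency
#' parameter, the damping parameter and the implied wavelength.
#'
#' @param fit An `lde_fit`.
#' @param lrt Optional `lde_lrt` to append.
#' @return Character vector of report lines (invisibly writable with
#'   `writeLines`).
#' @export
fit_report <- function(fit, lrt = NULL) {
  stopifnot(inherits(fit, "lde_fit"))
  eta <- fit$estimates[["eta"]]; zeta <- fit$estimates[["zeta"]]
  disc <- -eta - zeta^2 / 4
  lines <- c(
    sprintf("%s latent differential equation fit",
            if (fit$spec$order == 2) "Second-order (SOLDE)" else "Fourth-order (FOLDE)"),
    sprintf("  D = %d, P = %d, N = %d persons, %d free parameters",
            fit$spec$D, fit$spec$P, length(fit$spec$person_ids),
            count_free_parameters(fit$spec)),
    sprintf("  converged: %s after %d attempt(s); gradient norm %.3g",
            fit$converged, fit$n_attempts, fit$grad_norm),
    "",
    sprintf("  frequency eta  = %10.5f  (SE %s)", eta,
            format(fit$se[["eta"]], digits = 3)),
    sprintf("  damping   zeta = %10.5f  (SE %s)", zeta,
            format(fit$se[["zeta"]], digits = 3)),
    if (disc > 0) {
      sprintf("  wavelength     = %10.3f  time units", 2 * pi / sqrt(disc))
    } else {
      "  wavelength undefined (non-oscillating estimates)"
    },
    sprintf("  -2 log L       = %12.4f", fit$minus2ll))
  if (!is.null(lrt)) {
    lines <- c(lines, "",
               sprintf("  LRT SOLDE vs FOLDE: chi-square = %.4f, df = %d, p = %.4g",
                       lrt$statistic, lrt$df, lrt$p_value))
  }
  lines
}

#' Serialize / deserialize a fitted model as JSON
#'
#' Stores estimates, standard errors, fit statistics and the model layout;
#' enough to recompute implied moments and factor scores.
#'
#' @param fit An `lde_fit`.
#' @param path File path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json`
#'   returns an `lde_fit` (without optimizer history).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lde_fit"))
  jsonlite::write_json(
    list(spec = list(order = fit$spec$order, D = fit$spec$D, P = fit$spec$P,
                     delta_t = fit$spec$delta_t,
                     person_ids = fit$spec$person_ids,
                     series_names = fit$spec$series_names),
         estimates = as.list(fit$estimates),
         se = as.list(fit$se),
         loglik = fit$loglik, minus2ll = fit$minus2ll,
         converged = fit$converged, n_attempts = fit$n_attempts,
         grad_norm = fit$grad_norm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- lde_spec(order = x$spec$order, D = x$spec$D, P = x$spec$P,
                   delta_t = x$spec$delta_t, person_ids = x$spec$person_ids,
                   series_names = x$spec$series_names)
  structure(list(estimates = unlist(x$estimates)[spec$param_names],
                 se = unlist(x$se)[spec$param_names],
                 loglik = x$loglik, minus2ll = x$minus2ll,
                 converged = x$converged, n_attempts = x$n_attempts,
                 grad_norm = x$grad_norm, history = NULL, spec = spec,
                 options = NULL),
            class = "lde_fit")
}
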