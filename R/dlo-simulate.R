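# Damped linear oscillator simulator: closed-form trajectories and
# multi-person, multivariate panel generation with person-specific equilibria.

#' Damped linear oscillator parameters
#'
#' The damped linear oscillator (DLO) is the second-order differential
#' equation f'' = eta * f + zeta * f'. `eta` (the frequency parameter,
#' units 1/time^2) must be negative for oscillation; `zeta` (the damping
#' parameter, 1/time) is negative for amplitude decay. The process
#' oscillates (is underdamped) if and only if the discriminant
#' `-eta - zeta^2/4` is strictly positive.
#'
#' @param eta Frequency parameter (1/time^2).
#' @param zeta Damping parameter (1/time).
#' @param allow_nonoscillating If `TRUE`, accept parameters whose
#'   discriminant is non-positive (over- or critically damped). Default
#'   `FALSE`: such parameters are refused.
#' @return An object of class `dlo_params` with elements `eta`, `zeta` and
#'   `discriminant`.
#' @examples
#' p <- dlo_params(eta = -0.0095, zeta = -0.05)
#' p$discriminant
#' @export
dlo_params <- function(eta, zeta, allow_nonoscillating = FALSE) {
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta),
            is.numeric(zeta), length(zeta) == 1L, is.finite(zeta))
  disc <- -eta - zeta^2 / 4
  if (disc <= 0 && !allow_nonoscillating) {
    stop(sprintf(
      "non-oscillating parameters: discriminant -eta - zeta^2/4 = %.6g <= 0",
      disc), call. = FALSE)
  }
  structure(list(eta = eta, zeta = zeta, discriminant = disc),
            class = "dlo_params")
}

#' @export
print.dlo_params <- function(x, ...) {
  cat(sprintf("Damped linear oscillator: eta = %g, zeta = %g\n", x$eta, x$zeta))
  if (x$discriminant > 0) {
    cat(sprintf("  underdamped; wavelength = %g time units\n",
                2 * pi / sqrt(x$discriminant)))
  } else {
    cat("  non-oscillating (discriminant <= 0)\n")
  }
  invisible(x)
}

#' Closed-form trajectory of the damped linear oscillator
#'
#' Evaluates the exact homogeneous solution of f'' = eta*f + zeta*f' for an
#' underdamped oscillator:
#' x(t) = exp((zeta/2) t) (A cos(omega t) + B sin(omega t)) with
#' omega = sqrt(-eta - zeta^2/4), A = x0 and B = (v0 - (zeta/2) x0)/omega.
#'
#' @param params A [dlo_params()] object (must be underdamped).
#' @param x0,v0 Initial displacement and velocity at time 0.
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of displacements `x(times)`.
#' @seealso [dlo_velocity()] for the exact first derivative.
#' @examples
#' dlo_trajectory(dlo_params(-1, 0), x0 = 1, v0 = 0, times = c(0, pi))
#' @export
dlo_trajectory <- function(params, x0, v0, times) {
  stopifnot(inherits(params, "dlo_params"), is.numeric(times),
            all(is.finite(times)))
  disc <- -params$eta - params$zeta^2 / 4
  if (disc <= 0) {
    stop(sprintf(
      "non-oscillating parameters: discriminant -eta - zeta^2/4 = %.6g <= 0",
      disc), call. = FALSE)
  }
  omega <- sqrt(disc)
  A <- x0
  B <- (v0 - (params$zeta / 2) * x0) / omega
  exp(params$zeta / 2 * times) * (A * cos(omega * times) + B * sin(omega * times))
}

#' Exact velocity of the damped linear oscillator
#'
#' First time-derivative of the closed-form solution returned by
#' [dlo_trajectory()].
#'
#' @inheritParams dlo_trajectory
#' @return Numeric vector of velocities `x'(times)`.
#' @export
dlo_velocity <- function(params, x0, v0, times) {
  stopifnot(inherits(params, "dlo_params"))
  disc <- -params$eta - params$zeta^2 / 4
  if (disc <= 0) {
    stop(sprintf(
      "non-oscillating parameters: discriminant -eta - zeta^2/4 = %.6g <= 0",
      disc), call. = FALSE)
  }
  omega <- sqrt(disc)
  A <- x0
  B <- (v0 - (params$zeta / 2) * x0) / omega
  g <- params$zeta / 2
  exp(g * times) * (g * (A * cos(omega * times) + B * sin(omega * times)) +
                      omega * (-A * sin(omega * times) + B * cos(omega * times)))
}

#' Simulation configuration for multivariate oscillator panels
#'
#' Describes a synthetic daily-diary panel: `n_persons` individuals observed
#' at `n_occasions` equally spaced occasions on `n_series` indicator series
#' of one latent damped-oscillator process. Each person oscillates about a
#' person-specific equilibrium drawn from
#' N(`equilibrium_mean`, `equilibrium_sd`^2); series s measures
#' `series_loadings[s] * (equilibrium + latent)` plus independent Gaussian
#' noise with standard deviation `noise_sd[s]`.
#'
#' Defaults emulate a diary study of perceived stress in older adults:
#' 41 persons, 56 daily occasions, 3 indicator series, a wavelength of about
#' 66 days (`eta = -0.0095`) with mild damping (`zeta = -0.05`), equilibria
#' around 15 scale points, oscillation amplitudes of a few points
#' (`init_pos_sd = 5`), and measurement noise of 1 point per series.
#'
#' @param params [dlo_params()] for the shared dynamics (constant across
#'   persons).
#' @param n_persons,n_occasions,n_series Panel dimensions (N, T, P).
#' @param series_loadings Length-P scale factors; the first must be 1
#'   (reference indicator).
#' @param equilibrium_mean,equilibrium_sd Distribution of person equilibria.
#' @param init_pos_sd,init_vel_sd Distribution of person initial
#'   displacement and velocity (independent of equilibria).
#' @param noise_sd Length-P measurement-noise standard deviations.
#' @param missing_rate Proportion of cells deleted completely at random,
#'   in `[0, 1)`.
#' @param process_noise_sd Standard deviation of optional continuous-time
#'   process noise on the velocity equation; 0 (the default) yields the
#'   exact deterministic trajectory. Intended for robustness experiments
#'   only.
#' @param delta_t Time units per occasion (default 1 day).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params = dlo_params(-0.0095, -0.05),
                       n_persons = 41L,
                       n_occasions = 56L,
                       n_series = 3L,
                       series_loadings = c(1, 0.8, 1.2)[seq_len(n_series)],
                       equilibrium_mean = 15,
                       equilibrium_sd = 4,
                       init_pos_sd = 5,
                       init_vel_sd = 0.5,
                       noise_sd = rep(1, n_series),
                       missing_rate = 0,
                       process_noise_sd = 0,
                       delta_t = 1,
                       seed = 1L) {
  stopifnot(inherits(params, "dlo_params"),
            n_persons >= 1L, n_occasions >= 1L, n_series >= 1L,
            length(noise_sd) == n_series, all(noise_sd >= 0),
            length(series_loadings) == n_series,
            equilibrium_sd >= 0, init_pos_sd >= 0, init_vel_sd >= 0,
            process_noise_sd >= 0, delta_t > 0,
            is.numeric(seed), length(seed) == 1L)
  if (!isTRUE(all.equal(series_loadings[1], 1))) {
    stop("series_loadings[1] must be 1 (reference indicator)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(params = params,
                 n_persons = as.integer(n_persons),
                 n_occasions = as.integer(n_occasions),
                 n_series = as.integer(n_series),
                 series_loadings = as.numeric(series_loadings),
                 equilibrium_mean = equilibrium_mean,
                 equilibrium_sd = equilibrium_sd,
                 init_pos_sd = init_pos_sd,
                 init_vel_sd = init_vel_sd,
                 noise_sd = as.numeric(noise_sd),
                 missing_rate = missing_rate,
                 process_noise_sd = process_noise_sd,
                 delta_t = delta_t,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Euler-Maruyama integration of the DLO with additive process noise on the
# velocity equation, returned at the occasion grid. Used only when
# process_noise_sd > 0.
dlo_trajectory_sde <- function(params, x0, v0, times, process_noise_sd,
                               n_substeps = 100L) {
  out <- numeric(length(times))
  x <- x0; v <- v0; t_cur <- 0
  for (i in seq_along(times)) {
    if (times[i] > t_cur) {
      span <- times[i] - t_cur
      h <- span / n_substeps
      for (k in seq_len(n_substeps)) {
        a <- params$eta * x + params$zeta * v
        x <- x + v * h
        v <- v + a * h + process_noise_sd * sqrt(h) * stats::rnorm(1L)
      }
      t_cur <- times[i]
    }
    out[i] <- x
  }
  out
}

#' Simulate a multivariate multi-person oscillator panel
#'
#' Draws, for each person, an equilibrium and initial conditions, evaluates
#' the latent damped-oscillator trajectory at the occasion grid, scales it
#' onto each indicator series and adds measurement noise. The result is a
#' long-format panel ready for [embed_panel()].
#'
#' @param config A [sim_config()] object.
#' @return A `long_panel` data frame with columns `person_id`, `occasion`
#'   and `series_1` ... `series_P`. The latent states used for generation
#'   are attached as attributes `latent_f` (displacement), `latent_df`
#'   (velocity) and `equilibria` for use as simulation oracles.
#' @examples
#' panel <- simulate_panel(sim_config(n_persons = 2, n_occasions = 10))
#' head(panel)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_persons; Tn <- config$n_occasions; P <- config$n_series
  times <- (seq_len(Tn) - 1) * config$delta_t
  m <- stats::rnorm(N, config$equilibrium_mean, config$equilibrium_sd)
  x0 <- stats::rnorm(N, 0, config$init_pos_sd)
  v0 <- stats::rnorm(N, 0, config$init_vel_sd)
  f <- matrix(0, N, Tn)
  df <- matrix(0, N, Tn)
  for (j in seq_len(N)) {
    if (config$process_noise_sd > 0) {
      f[j, ] <- dlo_trajectory_sde(config$params, x0[j], v0[j], times,
                                   config$process_noise_sd)
      df[j, ] <- NA_real_
    } else {
      f[j, ] <- dlo_trajectory(config$params, x0[j], v0[j], times)
      df[j, ] <- dlo_velocity(config$params, x0[j], v0[j], times)
    }
  }
  vals <- matrix(NA_real_, N * Tn, P)
  for (s in seq_len(P)) {
    latent_s <- config$series_loadings[s] * (m[rep(seq_len(N), each = Tn)] +
                                               as.vector(t(f)))
    noise <- if (config$noise_sd[s] > 0) {
      stats::rnorm(N * Tn, 0, config$noise_sd[s])
    } else 0
    vals[, s] <- latent_s + noise
  }
  panel <- data.frame(person_id = rep(seq_len(N), each = Tn),
                      occasion = rep(seq_len(Tn), N))
  colnames(vals) <- paste0("series_", seq_len(P))
  panel <- cbind(panel, as.data.frame(vals))
  panel <- as_long_panel(panel, delta_t = config$delta_t)
  attr(panel, "latent_f") <- f
  attr(panel, "latent_df") <- df
  attr(panel, "equilibria") <- m
  if (config$missing_rate > 0) {
    panel <- add_missingness(panel, config$missing_rate,
                             seed = config$seed + 10007L)
  }
  panel
}

#' Coerce a data frame to a long panel
#'
#' Validates and labels a long-format panel: one row per person-occasion,
#' columns `person_id`, `occasion` and one numeric column per indicator
#' series. Occasions must be unique within a person; missing values are
#' `NA`.
#'
#' @param x A data frame with columns `person_id`, `occasion` and at least
#'   one series column.
#' @param delta_t Time units per occasion step.
#' @return `x` with class `long_panel` and attributes `series_names` and
#'   `delta_t`.
#' @export
as_long_panel <- function(x, delta_t = 1) {
  stopifnot(is.data.frame(x), all(c("person_id", "occasion") %in% names(x)))
  series_names <- setdiff(names(x), c("person_id", "occasion"))
  if (length(series_names) == 0L) stop("panel has no series columns",
                                       call. = FALSE)
  for (s in series_names) {
    if (!is.numeric(x[[s]])) stop(sprintf("series column '%s' is not numeric", s),
                                  call. = FALSE)
  }
  x$occasion <- as.integer(x$occasion)
  dup <- duplicated(x[c("person_id", "occasion")])
  if (any(dup)) stop("duplicated person/occasion combinations in panel",
                     call. = FALSE)
  x <- x[order(x$person_id, x$occasion), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, series_names = series_names, delta_t = delta_t,
            class = c("long_panel", "data.frame"))
}

#' Delete panel cells completely at random
#'
#' Each observed series cell is independently deleted (set to `NA`) with
#' probability `rate`; the person/occasion skeleton is unchanged. This MCAR
#' mechanism is the simplest one consistent with the missing-at-random
#' assumption of full-information ML estimation.
#'
#' @param panel A `long_panel`.
#' @param rate Deletion probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The panel with cells deleted.
#' @export
add_missingness <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "long_panel"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(panel)
  set.seed(as.integer(seed))
  for (s in attr(panel, "series_names")) {
    drop <- stats::runif(nrow(panel)) < rate
    panel[[s]][drop] <- NA_real_
  }
  panel
}

#' Write / read a long panel as CSV
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header
#' `person_id, occasion, <series names>`, empty cells for missing values.
#'
#' @param panel A `long_panel`.
#' @param path File path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `long_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "long_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @param delta_t Time units per occasion (not stored in the CSV).
#' @export
read_panel_csv <- function(path, delta_t = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("person_id", "occasion") %in% names(raw))) {
    stop(sprintf("'%s' is not a panel CSV: missing person_id/occasion header",
                 path), call. = FALSE)
  }
  series_names <- setdiff(names(raw), c("person_id", "occasion"))
  pid_num <- suppressWarnings(as.numeric(raw$person_id))
  if (!anyNA(pid_num)) {
    raw$person_id <- if (all(pid_num == round(pid_num))) as.integer(pid_num) else pid_num
  }
  for (col in c("occasion", series_names)) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("parse error in '%s', line %d: '%s' in column '%s' is not numeric",
                   path, bad[1] + 1L, v[bad[1]], col), call. = FALSE)
    }
    raw[[col]] <- num
  }
  as_long_panel(raw, delta_t = delta_t)
}
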