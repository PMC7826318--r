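# SOLDE / FOLDE model structure: fixed Taylor-basis loading matrix,
# derivative-regression constraints, person-equilibrium mean model and the
# model-implied moments.

#' Define a latent differential equation model
#'
#' Lays out the structure of a second-order (SOLDE, `order = 2`, latents
#' f, f', f'') or constrained fourth-order (FOLDE, `order = 4`, adding
#' f''' and f'''') latent differential equation model on a `D`-dimensional
#' time delay embedding of `P` indicator series, with one free equilibrium
#' mean per person. The free parameters, in layout order, are:
#'
#' * `eta`, `zeta` — frequency and damping regression coefficients,
#'   shared by all derivative-regression equations;
#' * `l2 ... lP` — indicator loadings (series 1 fixed at 1);
#' * `v_f`, `v_df`, `c_fdf` — variances of and covariance between the
#'   exogenous latents f and f';
#' * `v_e_d2` (SOLDE) or `v_e_d2`, `v_e_d3`, `v_e_d4` (FOLDE) — structural
#'   residual variances of the regressed derivatives;
#' * `u_<series>` — unique (measurement) variances, one per series,
#'   constrained equal across that series' D embedded columns;
#' * `m_<person>` — person equilibrium means.
#'
#' The free-parameter count is therefore
#' `2 + (P-1) + 3 + (1 or 3) + P + N`; a FOLDE model has exactly 2 more
#' free parameters than the SOLDE model with the same D, P and N, which is
#' the 2-df likelihood-ratio comparison between them.
#'
#' @param order 2 (SOLDE) or 4 (FOLDE).
#' @param D Embedding dimension; must be at least `order + 1` for
#'   identification.
#' @param P Number of indicator series.
#' @param delta_t Time units per occasion (enters the loading matrix).
#' @param person_ids Vector of person identifiers.
#' @param series_names Optional series labels (default `series_1` ...).
#' @return An object of class `lde_spec`.
#' @examples
#' spec <- lde_spec(order = 2, D = 5, P = 3, person_ids = 1:41)
#' count_free_parameters(spec)
#' @export
lde_spec <- function(order, D, P, delta_t = 1, person_ids,
                     series_names = paste0("series_", seq_len(P))) {
  if (!order %in% c(2, 4)) stop("order must be 2 (SOLDE) or 4 (FOLDE)",
                                call. = FALSE)
  q <- as.integer(order) + 1L
  if (D < q) {
    stop(sprintf("model not identified: D = %d < %d latent derivatives (order %d)",
                 D, q, order), call. = FALSE)
  }
  stopifnot(P >= 1L, delta_t > 0, length(person_ids) >= 1L,
            length(series_names) == P)
  person_ids <- as.character(person_ids)
  if (anyDuplicated(person_ids)) stop("person_ids must be unique",
                                      call. = FALSE)
  loading_names <- if (P > 1L) paste0("l", 2:P) else character(0)
  resid_names <- if (order == 2) "v_e_d2" else c("v_e_d2", "v_e_d3", "v_e_d4")
  unique_names <- paste0("u_", series_names)
  mean_names <- paste0("m_", person_ids)
  param_names <- c("eta", "zeta", loading_names, "v_f", "v_df", "c_fdf",
                   resid_names, unique_names, mean_names)
  is_variance <- param_names %in% c("v_f", "v_df", resid_names, unique_names)
  structure(list(order = as.integer(order), q = q, D = as.integer(D),
                 P = as.integer(P), delta_t = delta_t,
                 person_ids = person_ids, series_names = series_names,
                 param_names = param_names, is_variance = is_variance,
                 loading_names = loading_names, resid_names = resid_names,
                 unique_names = unique_names, mean_names = mean_names),
            class = "lde_spec")
}

#' @export
print.lde_spec <- function(x, ...) {
  cat(sprintf("%s latent differential equation model\n",
              if (x$order == 2) "Second-order (SOLDE)" else "Constrained fourth-order (FOLDE)"))
  cat(sprintf("  D = %d, P = %d, delta_t = %g, N = %d persons\n",
              x$D, x$P, x$delta_t, length(x$person_ids)))
  cat(sprintf("  %d free parameters\n", count_free_parameters(x)))
  invisible(x)
}

#' Count the free parameters of an LDE model
#'
#' @param spec An [lde_spec()].
#' @return Integer count; FOLDE minus SOLDE at equal D, P, N is always 2.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "lde_spec"))
  length(spec$param_names)
}

#' Fixed Taylor-basis loading matrix for an LDE model
#'
#' Builds the `(D*P) x (order+1)` loading matrix that constrains the
#' common factors to be the derivatives (with respect to time) of the rows
#' of the time delay-embedded matrix. Lag offsets are centered at the
#' window midpoint: lag index i (0-based) has offset
#' `(i - (D-1)/2) * delta_t`, so the entry for series s, lag i, derivative
#' k is `l_s * offset^k / k!`. At D = 5, delta_t = 1 this reproduces the
#' familiar offsets -2, -1, 0, 1, 2; even D gives half-integer offsets
#' extending the same symmetric pattern.
#'
#' @param D Embedding dimension (`>= order + 1`).
#' @param order 2 or 4.
#' @param delta_t Time units per occasion.
#' @param series_loadings Length-P loadings, first fixed to 1.
#' @return Numeric matrix, series-major rows matching [embed_panel()]
#'   column order.
#' @examples
#' build_loading_matrix(D = 5, order = 2)[1, ]  # (1, -2, 2)
#' @export
build_loading_matrix <- function(D, order, delta_t = 1, series_loadings = 1) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4", call. = FALSE)
  q <- order + 1L
  if (D < q) {
    stop(sprintf("model not identified: D = %d < %d latent derivatives",
                 D, q), call. = FALSE)
  }
  if (!isTRUE(all.equal(series_loadings[1], 1))) {
    stop("series_loadings[1] must be 1", call. = FALSE)
  }
  offsets <- ((0:(D - 1L)) - (D - 1) / 2) * delta_t
  base <- outer(offsets, 0:order, function(o, k) o^k / factorial(k))
  do.call(rbind, lapply(series_loadings, function(l) l * base))
}

#' Structural regression matrix of the derivative equations
#'
#' Returns the strictly lower-triangular `q x q` matrix A of latent
#' regressions among the derivatives (order f, f', f'', ...). For order 2
#' the single equation is f'' on (f, f') with coefficients `eta` and
#' `zeta`. For the constrained fourth-order model the three mathematically
#' equivalent second-order equation sets share the same coefficients:
#' f'' on (f, f'), f''' on (f', f''), and f'''' on (f'', f''').
#'
#' @param order 2 or 4.
#' @param eta,zeta Regression coefficients.
#' @return `q x q` numeric matrix with rows/columns ordered by derivative.
#' @export
build_structural <- function(order, eta, zeta) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4", call. = FALSE)
  q <- order + 1L
  A <- matrix(0, q, q)
  A[3, 1] <- eta; A[3, 2] <- zeta
  if (order == 4) {
    A[4, 2] <- eta; A[4, 3] <- zeta
    A[5, 3] <- eta; A[5, 4] <- zeta
  }
  A
}

#' Template parameter vector for an LDE model
#'
#' Returns a named numeric vector in the spec's layout order with neutral
#' values (loadings 1, variances 1, everything else 0), to be filled in by
#' the caller.
#'
#' @param spec An [lde_spec()].
#' @return Named numeric vector of length `count_free_parameters(spec)`.
#' @export
theta_template <- function(spec) {
  stopifnot(inherits(spec, "lde_spec"))
  theta <- stats::setNames(numeric(length(spec$param_names)), spec$param_names)
  theta[spec$is_variance] <- 1
  theta[spec$loading_names] <- 1
  theta
}

check_theta <- function(spec, theta) {
  if (is.null(names(theta)) || !identical(sort(names(theta)),
                                          sort(spec$param_names))) {
    stop("theta must be a named vector matching spec$param_names",
         call. = FALSE)
  }
  theta[spec$param_names]
}

# Transform map for unconstrained optimization: variances on log scale,
# all other parameters untouched. Round-trips without loss.
to_unconstrained <- function(spec, theta) {
  theta <- check_theta(spec, theta)
  theta[spec$is_variance] <- log(theta[spec$is_variance])
  theta
}

from_unconstrained <- function(spec, theta_u) {
  theta_u[spec$is_variance] <- exp(theta_u[spec$is_variance])
  theta_u
}

# Assemble all model matrices from a parameter vector. The latent
# covariance is Psi = (I - A)^-1 Phi* (I - A)^-T with Phi* carrying the
# exogenous (f, f') covariance block and the structural residual variances
# on the regressed derivatives; Sigma = L Psi L' + Theta.
model_matrices <- function(spec, theta, check = FALSE) {
  theta <- check_theta(spec, theta)
  q <- spec$q
  loadings <- c(1, unname(theta[spec$loading_names]))
  L <- build_loading_matrix(spec$D, spec$order, spec$delta_t, loadings)
  A <- build_structural(spec$order, theta[["eta"]], theta[["zeta"]])
  Phi_star <- matrix(0, q, q)
  Phi_star[1, 1] <- theta[["v_f"]]
  Phi_star[2, 2] <- theta[["v_df"]]
  Phi_star[1, 2] <- Phi_star[2, 1] <- theta[["c_fdf"]]
  diag(Phi_star)[3:q] <- unname(theta[spec$resid_names])
  if (check) {
    ev <- eigen(Phi_star, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("exogenous-plus-residual latent covariance Phi* is not positive semidefinite",
           call. = FALSE)
    }
  }
  # (I - A) is unit lower triangular, so forward substitution is exact and
  # never condition-limited (a wild optimizer step can make |eta| huge)
  IA <- diag(q) - A
  Psi <- forwardsolve(IA, t(forwardsolve(IA, t(Phi_star))))
  Psi <- (Psi + t(Psi)) / 2
  u <- unname(theta[spec$unique_names])
  theta_diag <- rep(u, each = spec$D)
  Sigma <- L %*% Psi %*% t(L)
  diag(Sigma) <- diag(Sigma) + theta_diag
  Sigma <- (Sigma + t(Sigma)) / 2
  list(L = L, A = A, Phi_star = Phi_star, Psi = Psi,
       Theta_diag = theta_diag, Sigma = Sigma, lambda0 = L[, 1],
       means = stats::setNames(unname(theta[spec$mean_names]),
                               spec$person_ids))
}

#' Model-implied covariance matrix of an embedded row
#'
#' Computes `Sigma = L Psi L' + Theta`, where
#' `Psi = (I - A)^-1 Phi* (I - A)^-T` places the exogenous (f, f')
#' covariance and the structural residual variances on the latent
#' derivatives, and `Theta` is diagonal with each series' unique variance
#' repeated across its D embedded columns.
#'
#' @param spec An [lde_spec()].
#' @param theta Named parameter vector (see [theta_template()]).
#' @return Symmetric `(D*P) x (D*P)` matrix.
#' @export
implied_covariance <- function(spec, theta) {
  model_matrices(spec, theta, check = TRUE)$Sigma
}

#' Model-implied mean of an embedded row for one person
#'
#' The equilibrium mean `m_j` propagates through the unit/zeroth-derivative
#' column of the loading matrix: all D lags of series s have mean
#' `l_s * m_j`.
#'
#' @param spec An [lde_spec()].
#' @param theta Named parameter vector.
#' @param person A person id present in the spec.
#' @return Numeric vector of length `D*P`.
#' @export
implied_row_mean <- function(spec, theta, person) {
  theta <- check_theta(spec, theta)
  person <- as.character(person)
  if (!person %in% spec$person_ids) {
    stop(sprintf("unknown person '%s'", person), call. = FALSE)
  }
  mm <- model_matrices(spec, theta)
  unname(theta[[paste0("m_", person)]]) * mm$lambda0
}

#' Serialize / deserialize an LDE model specification as JSON
#'
#' @param spec An [lde_spec()].
#' @param path File path.
#' @return `write_spec_json` returns `path` invisibly; `read_spec_json`
#'   returns an `lde_spec`.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "lde_spec"))
  jsonlite::write_json(list(order = spec$order, D = spec$D, P = spec$P,
                            delta_t = spec$delta_t,
                            person_ids = spec$person_ids,
                            series_names = spec$series_names),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lde_spec(order = x$order, D = x$D, P = x$P, delta_t = x$delta_t,
           person_ids = x$person_ids, series_names = x$series_names)
}
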