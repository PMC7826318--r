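# Factor scores for the latent derivatives (regression and Bartlett
# methods) and phase-plane vector-field summaries of the estimated
# dynamics.

#' Factor scores for the latent derivatives
#'
#' Computes per-row estimates of the latent derivative vector
#' (f, f', f''[, f''', f'''']) from a fitted LDE model. Rows are first
#' centered with the fitted person equilibrium, `w~ = w - m_j * L[,1]`
#' (not the person sample mean). Then, writing L, Psi, Theta and Sigma for
#' the fitted loading, latent-covariance, unique-variance and implied
#' covariance matrices restricted to each row's observed cells:
#'
#' * regression method: `F = Psi L' Sigma^-1 w~` — weights by the latent
#'   derivative covariance, shrinking noisy rows toward zero;
#' * Bartlett method: `F = (L' Theta^-1 L)^-1 L' Theta^-1 w~` —
#'   conditionally unbiased (the weight matrix B satisfies `B L = I`), so
#'   noiseless rows are recovered exactly.
#'
#' Rows with fewer observed cells than latent derivatives are skipped with
#' a message.
#'
#' @param fit A converged `lde_fit`.
#' @param data The `tde_matrix` the model was fitted to (or compatible).
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return A data frame of class `lde_scores` with columns `row`,
#'   `person_id` and `f`, `df`, `d2f` (plus `d3f`, `d4f` for FOLDE);
#'   attribute `method`.
#' @export
factor_scores <- function(fit, data, method = c("regression", "bartlett")) {
  stopifnot(inherits(fit, "lde_fit"), inherits(data, "tde_matrix"))
  method <- match.arg(method)
  if (isFALSE(fit$converged)) {
    warning("scoring from a non-converged fit", call. = FALSE)
  }
  spec <- fit$spec
  state <- fiml_state(spec, data)
  mm <- model_matrices(spec, fit$estimates)
  q <- spec$q
  score_names <- c("f", "df", "d2f", "d3f", "d4f")[seq_len(q)]
  scores <- matrix(NA_real_, nrow(state$W), q)
  n_skipped <- 0L
  for (g in state$patterns) {
    k <- length(g$obs)
    if (k < q) {
      n_skipped <- n_skipped + length(g$rows)
      next
    }
    L_o <- mm$L[g$obs, , drop = FALSE]
    if (method == "regression") {
      S_o <- mm$Sigma[g$obs, g$obs, drop = FALSE]
      Wt <- tryCatch(mm$Psi %*% t(L_o) %*% solve(S_o), error = function(e) {
        stop(sprintf("singular implied covariance for missingness pattern with %d observed cells (columns %s)",
                     k, paste(g$obs, collapse = ",")), call. = FALSE)
      })
    } else {
      th_inv <- 1 / mm$Theta_diag[g$obs]
      LtTi <- t(L_o * th_inv)
      M <- LtTi %*% L_o
      Wt <- tryCatch(solve(M, LtTi), error = function(e) {
        stop(sprintf("singular Bartlett weighting for missingness pattern with %d observed cells (columns %s)",
                     k, paste(g$obs, collapse = ",")), call. = FALSE)
      })
    }
    centered <- state$W[g$rows, g$obs, drop = FALSE] -
      outer(mm$means[state$person_idx[g$rows]], mm$lambda0[g$obs])
    scores[g$rows, ] <- centered %*% t(Wt)
  }
  if (n_skipped > 0L) {
    message(sprintf("skipped %d row(s) with fewer than %d observed cells",
                    n_skipped, q))
  }
  keep <- !is.na(scores[, 1])
  out <- data.frame(row = which(keep),
                    person_id = as.character(data$row_person)[keep])
  out[score_names] <- as.data.frame(scores[keep, , drop = FALSE])
  structure(out, method = method, class = c("lde_scores", "data.frame"))
}

#' Phase-plane vector field from factor scores
#'
#' Bins the (f, f') plane and, in each bin with at least `min_count`
#' member rows, places an arrow equal to the mean observed flow
#' `(df/dt, d(f')/dt) = (mean f', mean f'')` of those rows. Under the
#' damped linear oscillator the analytic flow is `(f', eta*f + zeta*f')`,
#' so near the f axis (f' = 0) the vertical arrow component approximates
#' `eta * f`.
#'
#' @param scores An `lde_scores` data frame containing `f`, `df`, `d2f`.
#' @param n_bins Number of bins per axis (default 10).
#' @param min_count Minimum bin occupancy for an arrow (default 5).
#' @param f_range,df_range Optional axis limits; default the central 95%
#'   range of the scores.
#' @return A data frame of class `lde_vector_field` with columns
#'   `f_center`, `df_center`, `u` (mean f'), `v` (mean f'') and `n`.
#'   Empty scores yield an empty field.
#' @export
vector_field <- function(scores, n_bins = 10L, min_count = 5L,
                         f_range = NULL, df_range = NULL) {
  stopifnot(inherits(scores, "lde_scores") || is.data.frame(scores))
  needed <- c("f", "df", "d2f")
  if (!all(needed %in% names(scores))) {
    stop("scores must contain columns f, df and d2f", call. = FALSE)
  }
  empty <- data.frame(f_center = numeric(0), df_center = numeric(0),
                      u = numeric(0), v = numeric(0), n = integer(0))
  if (nrow(scores) == 0L) {
    return(structure(empty, class = c("lde_vector_field", "data.frame")))
  }
  if (is.null(f_range)) {
    f_range <- stats::quantile(scores$f, c(0.025, 0.975), na.rm = TRUE)
  }
  if (is.null(df_range)) {
    df_range <- stats::quantile(scores$df, c(0.025, 0.975), na.rm = TRUE)
  }
  if (diff(range(f_range)) == 0) f_range <- f_range + c(-0.5, 0.5)
  if (diff(range(df_range)) == 0) df_range <- df_range + c(-0.5, 0.5)
  f_breaks <- seq(f_range[1], f_range[2], length.out = n_bins + 1L)
  df_breaks <- seq(df_range[1], df_range[2], length.out = n_bins + 1L)
  bf <- cut(scores$f, f_breaks, include.lowest = TRUE, labels = FALSE)
  bd <- cut(scores$df, df_breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bf) & !is.na(bd)
  if (!any(ok)) {
    return(structure(empty, class = c("lde_vector_field", "data.frame")))
  }
  key <- interaction(bf[ok], bd[ok], drop = TRUE)
  agg <- do.call(rbind, lapply(split(which(ok), key), function(rows) {
    data.frame(bf = bf[rows[1]], bd = bd[rows[1]],
               u = mean(scores$df[rows]), v = mean(scores$d2f[rows]),
               n = length(rows))
  }))
  agg <- agg[agg$n >= min_count, , drop = FALSE]
  centers <- function(br) (br[-1] + br[-length(br)]) / 2
  out <- data.frame(f_center = centers(f_breaks)[agg$bf],
                    df_center = centers(df_breaks)[agg$bd],
                    u = agg$u, v = agg$v, n = agg$n)
  rownames(out) <- NULL
  structure(out, f_breaks = f_breaks, df_breaks = df_breaks,
            class = c("lde_vector_field", "data.frame"))
}

#' Plot a phase-plane vector field
#'
#' Arrows show the mean flow (f', f'') of the rows in each occupied bin of
#' the (f, f') plane.
#'
#' @param x An `lde_vector_field`.
#' @param arrow_scale Multiplier applied to arrow lengths (default
#'   auto-scaled to bin width).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lde_vector_field <- function(x, arrow_scale = NULL, ...) {
  if (nrow(x) == 0L) {
    warning("empty vector field; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  if (is.null(arrow_scale)) {
    bin_w <- min(diff(attr(x, "f_breaks"))[1], diff(attr(x, "df_breaks"))[1])
    max_len <- max(sqrt(x$u^2 + x$v^2))
    arrow_scale <- if (max_len > 0) 0.8 * bin_w / max_len else 1
  }
  graphics::plot(x$f_center, x$df_center, type = "n",
                 xlab = "f (displacement)", ylab = "f' (velocity)", ...)
  graphics::arrows(x$f_center, x$df_center,
                   x$f_center + arrow_scale * x$u,
                   x$df_center + arrow_scale * x$v,
                   length = 0.06)
  invisible(x)
}

#' Write factor scores or a vector field as CSV
#'
#' @param x An `lde_scores` or `lde_vector_field` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
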