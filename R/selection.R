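# Embedding-dimension selection: scan D, detect stabilization of the
# frequency parameter ("reversed elbow"), and convert (eta, zeta) into the
# oscillation wavelength.

#' Wavelength (period) of a damped linear oscillator
#'
#' For the underdamped oscillator f'' = eta*f + zeta*f', the period of one
#' full cycle is `lambda = 2*pi*delta_t / sqrt(-eta - zeta^2/4)`. Pass
#' `delta_t` only when `eta` and `zeta` are expressed per occasion rather
#' than per time unit; estimates from [fit_lde()] are already per time
#' unit (the loading matrix carries `delta_t`), so the default
#' `delta_t = 1` applies.
#'
#' Because eta and zeta combine under a square root, seemingly small
#' differences in either parameter can move the wavelength substantially —
#' the reason stable estimates across embedding dimensions matter.
#'
#' @param eta Frequency parameter (must satisfy `-eta - zeta^2/4 > 0`).
#' @param zeta Damping parameter.
#' @param delta_t Time units per occasion.
#' @return The wavelength in time units.
#' @examples
#' wavelength(eta = -(2 * pi / 60)^2, zeta = 0)  # exactly 60
#' @export
wavelength <- function(eta, zeta, delta_t = 1) {
  stopifnot(is.numeric(eta), is.numeric(zeta), delta_t > 0)
  disc <- -eta - zeta^2 / 4
  if (disc <= 0) {
    stop(sprintf(
      "wavelength undefined: -eta - zeta^2/4 = %.6g <= 0 (non-oscillating parameters)",
      disc), call. = FALSE)
  }
  2 * pi * delta_t / sqrt(disc)
}

#' Detect stabilization of the frequency parameter across embedding dimensions
#'
#' Implements an algorithmic stand-in for the visual "elbow" (or reversed
#' elbow) identification: the optimal embedding dimension is the one at
#' which the estimated frequency parameter eta stabilizes when plotted
#' against D.
#'
#' Two rules are provided. The default `"relative-change"` rule selects the
#' smallest D whose eta all subsequent dimensions stay within a relative
#' band of: `|eta(D') - eta(D)| / |eta(D)| < threshold` for every larger D'
#' in the scanned range (the last scanned D cannot qualify on its own, so a
#' never-stabilizing sequence returns no selection). The
#' `"max-curvature"` rule returns the interior D maximizing the absolute
#' discrete second difference of the eta sequence. Both are documented
#' interpretations of a visual criterion, not prescriptions.
#'
#' @param D Integer vector of embedding dimensions (ordered, length >= 3).
#' @param eta Numeric vector of eta estimates, same length.
#' @param rule `"relative-change"` (default) or `"max-curvature"`.
#' @param threshold Relative-change threshold (default 0.10).
#' @return The selected D, or `NA_integer_` if no dimension qualifies.
#' @examples
#' detect_elbow(5:9, c(-2.58, -0.0090, -0.0088, -0.0088, -0.0087))  # 6
#' @export
detect_elbow <- function(D, eta, rule = c("relative-change", "max-curvature"),
                         threshold = 0.10) {
  rule <- match.arg(rule)
  stopifnot(length(D) == length(eta))
  if (length(D) < 3L) stop("need at least 3 (D, eta) pairs", call. = FALSE)
  if (is.unsorted(D, strictly = TRUE)) stop("D must be strictly increasing",
                                            call. = FALSE)
  keep <- is.finite(eta)
  D <- D[keep]; eta <- eta[keep]
  if (length(D) < 3L) return(NA_integer_)
  if (rule == "relative-change") {
    n <- length(D)
    for (i in seq_len(n - 1L)) {
      rel <- abs(eta[(i + 1L):n] - eta[i]) / abs(eta[i])
      if (all(rel < threshold)) return(as.integer(D[i]))
    }
    return(NA_integer_)
  }
  # max-curvature: interior point with largest |second difference|
  d2 <- abs(diff(eta, differences = 2))
  as.integer(D[which.max(d2) + 1L])
}

#' Scan embedding dimensions and select one by eta stabilization
#'
#' Embeds the panel and fits the requested LDE model independently at each
#' embedding dimension in `D_range` (no estimate reuse across D unless
#' `warm_start = TRUE`), recording the three outcome criteria per D: the
#' frequency parameter eta, the damping parameter zeta, and the implied
#' wavelength. The stabilization rule of [detect_elbow()] is then applied
#' to the converged eta sequence.
#'
#' @param panel A `long_panel`.
#' @param order 2 (SOLDE) or 4 (FOLDE).
#' @param D_range Integer vector of embedding dimensions, e.g. `5:9`.
#' @param tau Embedding lag (default 1).
#' @param options [fit_options()] for every per-D fit.
#' @param rule,threshold Passed to [detect_elbow()].
#' @param warm_start Start each fit from the previous D's estimates
#'   (default `FALSE`: per-D fits are fully independent).
#' @return An object of class `lde_scan`: a `results` data frame with one
#'   row per D (eta, zeta, their SEs, -2 log L, convergence, wavelength),
#'   the selected `elbow_D` (or `NA`), and the rule metadata.
#' @export
scan_embedding <- function(panel, order, D_range, tau = 1L,
                           options = fit_options(),
                           rule = c("relative-change", "max-curvature"),
                           threshold = 0.10, warm_start = FALSE) {
  stopifnot(inherits(panel, "long_panel"))
  rule <- match.arg(rule)
  q <- order + 1L
  D_range <- as.integer(D_range)
  results <- data.frame(D = integer(0), eta = numeric(0), se_eta = numeric(0),
                        zeta = numeric(0), se_zeta = numeric(0),
                        minus2ll = numeric(0), converged = logical(0),
                        n_attempts = integer(0), wavelength = numeric(0))
  fits <- list()
  prev_start <- NULL
  for (D in D_range) {
    if (D < q) {
      message(sprintf("skipping D = %d: below identification bound q = %d",
                      D, q))
      next
    }
    tde <- embed_panel(panel, D = D, tau = tau)
    spec <- lde_spec(order, D = D, P = length(attr(panel, "series_names")),
                     delta_t = attr(panel, "delta_t"),
                     person_ids = unique(panel$person_id),
                     series_names = attr(panel, "series_names"))
    fit <- fit_lde(spec, tde, options,
                   start = if (warm_start) prev_start else NULL)
    if (warm_start) prev_start <- fit$estimates
    eta <- fit$estimates[["eta"]]; zeta <- fit$estimates[["zeta"]]
    disc <- -eta - zeta^2 / 4
    lam <- if (disc > 0) wavelength(eta, zeta) else NA_real_
    results <- rbind(results, data.frame(
      D = D, eta = eta, se_eta = fit$se[["eta"]],
      zeta = zeta, se_zeta = fit$se[["zeta"]],
      minus2ll = fit$minus2ll, converged = fit$converged,
      n_attempts = fit$n_attempts,
      wavelength = lam))
    fits[[as.character(D)]] <- fit
  }
  elbow_D <- if (nrow(results) >= 3L) {
    ok <- results$converged
    if (sum(ok) >= 3L) {
      detect_elbow(results$D[ok], results$eta[ok], rule = rule,
                   threshold = threshold)
    } else NA_integer_
  } else NA_integer_
  structure(list(results = results, elbow_D = elbow_D, rule = rule,
                 threshold = threshold, order = order, fits = fits),
            class = "lde_scan")
}

#' @export
print.lde_scan <- function(x, ...) {
  cat(sprintf("Embedding-dimension scan (%s)\n",
              if (x$order == 2) "SOLDE" else "FOLDE"))
  print(x$results, row.names = FALSE, digits = 5)
  if (is.na(x$elbow_D)) {
    cat(sprintf("  no stabilization detected (rule: %s, threshold %.2f)\n",
                x$rule, x$threshold))
  } else {
    cat(sprintf("  selected D = %d (rule: %s, threshold %.2f)\n",
                x$elbow_D, x$rule, x$threshold))
  }
  invisible(x)
}

#' Write a scan result as CSV
#'
#' One row per embedding dimension with eta, zeta, SEs, fit and wavelength.
#'
#' @param scan An `lde_scan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "lde_scan"))
  utils::write.csv(scan$results, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Plot a scan result
#'
#' Three stacked panels by embedding dimension: eta with naive +/- SE bars,
#' zeta with bars, and the implied wavelength. The selected dimension, if
#' any, is marked with a vertical dashed line.
#'
#' @param x An `lde_scan`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.lde_scan <- function(x, ...) {
  r <- x$results
  if (nrow(r) == 0L) {
    warning("empty scan; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 2, 1))
  on.exit(graphics::par(old))
  panels <- list(
    list(y = r$eta, se = r$se_eta, lab = expression(eta ~ "(frequency)")),
    list(y = r$zeta, se = r$se_zeta, lab = expression(zeta ~ "(damping)")),
    list(y = r$wavelength, se = NULL, lab = "wavelength (time units)"))
  for (p in panels) {
    se <- if (is.null(p$se)) rep(0, nrow(r)) else ifelse(is.na(p$se), 0, p$se)
    ylim <- range(c(p$y - se, p$y + se), na.rm = TRUE)
    graphics::plot(r$D, p$y, type = "b", pch = 19, xlab = "embedding dimension D",
                   ylab = p$lab, ylim = ylim)
    pos <- which(se > 0)
    if (!is.null(p$se) && length(pos) > 0L) {
      graphics::arrows(r$D[pos], (p$y - se)[pos], r$D[pos], (p$y + se)[pos],
                       angle = 90, code = 3, length = 0.04)
    }
    if (!is.na(x$elbow_D)) graphics::abline(v = x$elbow_D, lty = 2)
  }
  invisible(x)
}
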