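# Time delay embedding: restructure each person's series into overlapping
# length-D windows and column-bind the per-series blocks.

#' Time delay embed a single series
#'
#' Cuts an ordered series into overlapping segments of length `D` with lag
#' `tau` between adjacent columns and row-binds them: row i is
#' `(x[i], x[i+tau], ..., x[i+(D-1)tau])`. Rows containing missing cells
#' are retained; full-information ML handles them downstream.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param D Embedding dimension (number of columns), `>= 1`.
#' @param tau Lag between adjacent embedded columns in occasions, `>= 1`.
#'   The field's standing recommendation is `tau = 1`.
#' @return A `length(x) - (D-1)*tau` by `D` numeric matrix; zero rows (with
#'   a warning) if the series is too short.
#' @examples
#' embed_series(1:6, D = 5)
#' @export
embed_series <- function(x, D, tau = 1L) {
  stopifnot(is.numeric(x), length(D) == 1L, D >= 1L,
            length(tau) == 1L, tau >= 1L)
  D <- as.integer(D); tau <- as.integer(tau)
  n_rows <- length(x) - (D - 1L) * tau
  if (n_rows <= 0L) {
    warning(sprintf("series of length %d too short for D = %d, tau = %d: 0 rows",
                    length(x), D, tau), call. = FALSE)
    return(matrix(numeric(0), nrow = 0L, ncol = D))
  }
  idx <- outer(seq_len(n_rows), (0:(D - 1L)) * tau, "+")
  matrix(x[idx], nrow = n_rows, ncol = D)
}

#' Time delay embed a multivariate panel
#'
#' Embeds each person's series independently (no window ever spans two
#' persons), column-binds the per-series blocks in series-major order (all
#' `D` lags of series 1, then series 2, ...), and row-binds persons. Within
#' a person, windows are formed on the integer occasion grid from the first
#' to the last observed occasion; skipped occasions enter the windows as
#' missing cells rather than silently compressing time.
#'
#' @param panel A `long_panel` (see [as_long_panel()]).
#' @param D Embedding dimension.
#' @param tau Lag between embedded columns in occasions (default 1).
#' @param drop_empty Drop rows whose cells are all missing (default
#'   `FALSE`; such rows contribute nothing to the likelihood either way).
#' @return A `tde_matrix`: list with `values` (rows x D*P matrix),
#'   `row_person`, `D`, `tau`, `delta_t`, `series_names`. Column order
#'   follows the series-major convention with names
#'   `<series>_lag0 ... <series>_lag{D-1}`.
#' @examples
#' panel <- simulate_panel(sim_config(n_persons = 2, n_occasions = 12))
#' tde <- embed_panel(panel, D = 5)
#' dim(tde$values)
#' @export
embed_panel <- function(panel, D, tau = 1L, drop_empty = FALSE) {
  stopifnot(inherits(panel, "long_panel"), D >= 1L, tau >= 1L)
  D <- as.integer(D); tau <- as.integer(tau)
  series_names <- attr(panel, "series_names")
  delta_t <- attr(panel, "delta_t")
  persons <- unique(panel$person_id)
  blocks <- vector("list", length(persons))
  row_person <- vector("list", length(persons))
  for (i in seq_along(persons)) {
    sub <- panel[panel$person_id == persons[i], , drop = FALSE]
    occ <- sub$occasion
    if (anyDuplicated(occ)) {
      stop(sprintf("person %s has duplicated occasions", persons[i]),
           call. = FALSE)
    }
    grid <- seq(min(occ), max(occ))
    pos <- match(grid, occ)  # NA where an occasion was skipped entirely
    per_series <- lapply(series_names, function(s) {
      x <- sub[[s]][pos]
      suppressWarnings(embed_series(x, D, tau))
    })
    n_rows <- nrow(per_series[[1]])
    blocks[[i]] <- do.call(cbind, per_series)
    row_person[[i]] <- rep(persons[i], n_rows)
  }
  values <- do.call(rbind, blocks)
  row_person <- do.call(c, row_person)
  colnames(values) <- unlist(lapply(series_names, function(s) {
    paste0(s, "_lag", 0:(D - 1L))
  }))
  if (drop_empty && nrow(values) > 0L) {
    keep <- rowSums(!is.na(values)) > 0L
    values <- values[keep, , drop = FALSE]
    row_person <- row_person[keep]
  }
  structure(list(values = values, row_person = row_person, D = D, tau = tau,
                 delta_t = delta_t, series_names = series_names),
            class = "tde_matrix")
}

#' @export
print.tde_matrix <- function(x, ...) {
  cat(sprintf("Time delay-embedded matrix: %d rows x %d columns (D = %d, tau = %d, P = %d)\n",
              nrow(x$values), ncol(x$values), x$D, x$tau,
              length(x$series_names)))
  cat(sprintf("  %d persons; %.1f%% missing cells\n",
              length(unique(x$row_person)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Nyquist sampling-limit check for an embedding window
#'
#' The total time elapsed between the first and last embedded columns,
#' `(D-1) * tau * delta_t`, must be strictly shorter than the wavelength of
#' the oscillation for the dynamics to be identifiable. The check is
#' advisory (the wavelength is typically only known after fitting), so the
#' result is returned rather than raised.
#'
#' @param D Embedding dimension.
#' @param tau Lag between embedded columns (occasions).
#' @param delta_t Time units per occasion.
#' @param wavelength Oscillation wavelength in time units, `> 0`.
#' @return A list with `pass` (logical), `ratio` (window / wavelength),
#'   `window` and `wavelength`.
#' @examples
#' nyquist_check(D = 6, tau = 1, delta_t = 1, wavelength = 64.8)
#' @export
nyquist_check <- function(D, tau = 1L, delta_t = 1, wavelength) {
  stopifnot(D >= 1, tau >= 1, delta_t > 0, is.numeric(wavelength),
            wavelength > 0)
  window <- (D - 1) * tau * delta_t
  structure(list(pass = window < wavelength,
                 ratio = window / wavelength,
                 window = window,
                 wavelength = wavelength),
            class = "nyquist_check")
}

#' @export
print.nyquist_check <- function(x, ...) {
  cat(sprintf("Nyquist check: window %g vs wavelength %g -> %s (ratio %.3f)\n",
              x$window, x$wavelength, if (x$pass) "pass" else "FAIL", x$ratio))
  invisible(x)
}

#' Write / read a time delay-embedded matrix as CSV
#'
#' Columns `person_id, <series>_lag0 ... <series>_lag{D-1}`; empty cells
#' for missing values.
#'
#' @param tde A `tde_matrix`.
#' @param path File path.
#' @return `write_tde_csv` returns `path` invisibly; `read_tde_csv` returns
#'   a `tde_matrix`.
#' @export
write_tde_csv <- function(tde, path) {
  stopifnot(inherits(tde, "tde_matrix"))
  out <- data.frame(person_id = tde$row_person, tde$values,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tde_csv
#' @param tau,delta_t Embedding metadata (not stored in the CSV).
#' @export
read_tde_csv <- function(path, tau = 1L, delta_t = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"person_id" %in% names(raw)) {
    stop(sprintf("'%s' is not a TDE CSV: missing person_id column", path),
         call. = FALSE)
  }
  lag_cols <- grep("_lag[0-9]+$", names(raw), value = TRUE)
  if (length(lag_cols) == 0L) {
    stop(sprintf("'%s' has no <series>_lag<k> columns", path), call. = FALSE)
  }
  series_names <- unique(sub("_lag[0-9]+$", "", lag_cols))
  D <- length(lag_cols) / length(series_names)
  values <- as.matrix(raw[lag_cols])
  storage.mode(values) <- "double"
  structure(list(values = values, row_person = raw$person_id,
                 D = as.integer(D), tau = as.integer(tau), delta_t = delta_t,
                 series_names = series_names),
            class = "tde_matrix")
}
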