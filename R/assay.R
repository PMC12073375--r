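# Gravimetric absorption capacity and molar-mass-distribution averages.

#' Absorption capacity of a hydrated sample
#'
#' Percent weight gain of a dry sample after hydration:
#' `AC(%) = (W_h - W_d) / W_d * 100`. A hydrated weight below the dry
#' weight yields a negative capacity (mass loss), which is allowed but
#' flagged with a warning.
#'
#' @param W_h Hydrated (swollen) weight in grams (>= 0); vectorized.
#' @param W_d Dry weight in grams (> 0).
#' @return Absorption capacity in percent.
#' @examples
#' absorption_capacity(1.5, 1.0)  # 50
#' absorption_capacity(41, 1)     # 4000: the sample holds 40x its dry weight
#' @export
absorption_capacity <- function(W_h, W_d) {
  if (!is.numeric(W_d) || any(!is.finite(W_d)) || any(W_d <= 0))
    fm_stop_validation("'W_d' must be > 0")
  if (!is.numeric(W_h) || any(!is.finite(W_h)) || any(W_h < 0))
    fm_stop_validation("'W_h' must be >= 0")
  ac <- (W_h - W_d) / W_d * 100
  if (any(ac < 0))
    warning("hydrated weight below dry weight: negative absorption capacity (mass loss)",
            call. = FALSE)
  ac
}

#' Absorption capacity over a soak time series
#'
#' Computes the absorption capacity at each time point of a gravimetric
#' soak series and finds the equilibrium time: the first time point from
#' which the relative change in capacity between consecutive points stays
#' below `tol` through the end of the series.
#'
#' @param records Data frame with columns `time_h` (strictly increasing,
#'   >= 0), `W_h_g`, `W_d_g` and optionally `medium` (`"water"` or
#'   `"PBS"`).
#' @param tol Relative-change tolerance defining equilibrium (default 2%).
#' @return An `absorption_series`: the input with an `AC_percent` column,
#'   plus `equilibrium_time_h` (`NA` if never reached),
#'   `equilibrium_reached` and `final_AC_percent`.
#' @export
absorption_series <- function(records, tol = 0.02) {
  if (!is.data.frame(records) ||
      !all(c("time_h", "W_h_g", "W_d_g") %in% names(records)))
    fm_stop_validation("'records' needs columns time_h, W_h_g, W_d_g")
  check_scalar(tol, "tol", positive = TRUE)
  t <- records$time_h
  if (any(!is.finite(t)) || any(t < 0))
    fm_stop_validation("'time_h' must be finite and >= 0")
  if (anyDuplicated(t) || is.unsorted(t, strictly = TRUE))
    fm_stop_validation("'time_h' must be strictly increasing with no duplicates")
  if (length(unique(records$W_d_g)) > 1L)
    fm_stop_validation("a series must have a single dry weight W_d_g")
  ac <- absorption_capacity(records$W_h_g, records$W_d_g[1])
  n <- length(ac)
  eq_idx <- NA_integer_
  if (n >= 2L) {
    rel <- abs(diff(ac)) / pmax(abs(ac[-n]), .Machine$double.eps)
    ok_from <- rev(cumprod(rev(rel < tol))) == 1  # rel[i..] all below tol
    if (any(ok_from)) eq_idx <- which(ok_from)[1]
  } else eq_idx <- 1L
  out <- records
  out$AC_percent <- ac
  structure(list(
    series = out,
    tol = tol,
    equilibrium_time_h = if (is.na(eq_idx)) NA_real_ else t[eq_idx],
    equilibrium_reached = !is.na(eq_idx),
    final_AC_percent = ac[n]
  ), class = "absorption_series")
}

#' @export
print.absorption_series <- function(x, ...) {
  cat(sprintf("<absorption_series> %d time points, final AC %.1f%%\n",
              nrow(x$series), x$final_AC_percent))
  if (x$equilibrium_reached)
    cat(sprintf("  equilibrium (rel. change < %.1f%%) from t = %g h\n",
                100 * x$tol, x$equilibrium_time_h))
  else cat("  equilibrium not reached\n")
  invisible(x)
}

#' Molar-mass-distribution averages
#'
#' Number-, weight- and z-average molar masses and the polydispersity
#' index of a distribution given as masses `M_i` with abundances `N_i`:
#' `Mn = sum(N M) / sum(N)`, `Mw = sum(N M^2) / sum(N M)`,
#' `Mz = sum(N M^3) / sum(N M^2)`, `PDI = Mw / Mn`. Raw per-molecule mass
#' samples are accepted by leaving `N` at its default of 1. The averages
#' are invariant to rescaling all abundances, and always satisfy
#' `Mn <= Mw <= Mz` (power-mean inequality) with equality only for a
#' monodisperse sample.
#'
#' @param M Molar masses in g/mol (> 0).
#' @param N Abundances (>= 0, at least one > 0); recycled to `length(M)`.
#' @return An `mwd_averages` list: `Mn`, `Mw`, `Mz`, `PDI` (g/mol; PDI
#'   dimensionless).
#' @examples
#' mwd_averages(c(1e6, 2e6))  # Mn 1.5e6, Mw ~1.67e6, Mz 1.8e6
#' @export
mwd_averages <- function(M, N = 1) {
  if (!is.numeric(M) || length(M) == 0L || any(!is.finite(M)) || any(M <= 0))
    fm_stop_validation("'M' must be positive finite molar masses")
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0))
    fm_stop_validation("'N' must be non-negative abundances")
  N <- rep_len(N, length(M))
  if (sum(N) <= 0)
    fm_stop_validation("at least one abundance must be > 0")
  s0 <- sum(N); s1 <- sum(N * M); s2 <- sum(N * M^2); s3 <- sum(N * M^3)
  Mn <- s1 / s0; Mw <- s2 / s1; Mz <- s3 / s2
  structure(list(Mn = Mn, Mw = Mw, Mz = Mz, PDI = Mw / Mn),
            class = "mwd_averages")
}

#' @export
print.mwd_averages <- function(x, ...) {
  cat(sprintf("<mwd_averages> Mn %.4g, Mw %.4g, Mz %.4g g/mol; PDI %.4g\n",
              x$Mn, x$Mw, x$Mz, x$PDI))
  invisible(x)
}

#' Read assay CSV inputs
#'
#' `read_absorption_csv` expects columns `time_h`, `W_h_g`, `W_d_g` and
#' optionally `medium`; `read_mwd_csv` expects `M_g_per_mol` and
#' optionally `N`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_absorption_csv <- function(path) {
  df <- read_metrics(path)
  if (!all(c("time_h", "W_h_g", "W_d_g") %in% names(df)))
    fm_stop_validation(sprintf(
      "'%s' must have columns time_h, W_h_g, W_d_g", path))
  df
}

#' @rdname read_absorption_csv
#' @export
read_mwd_csv <- function(path) {
  df <- read_metrics(path)
  if (!"M_g_per_mol" %in% names(df))
    fm_stop_validation(sprintf("'%s' must have a column M_g_per_mol", path))
  if (is.null(df$N)) df$N <- 1
  df
}
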