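#' Promoter-activity parameters
#'
#' Bundle the five constants of the rise-and-saturate promoter activity
#' function
#' \deqn{g(t) = k_1 \frac{(t/T_1)^{h_1}}{1 + (t/T_2)^{h_2}}}{
#'       g(t) = k1 (t/T1)^h1 / (1 + (t/T2)^h2)}
#' which drives the Timer Blue signal. `k1` sets the amplitude
#' (fluorescence units per hour), `T1` the rise timescale (hours), `h1`
#' the rise exponent, `T2` the saturation timescale (hours) and `h2` the
#' saturation exponent. When `h1 < h2` the activity starts at zero, rises
#' to a single interior maximum and decays back to zero; when `h1 >= h2`
#' it grows without a finite peak (a plateau regime on any finite
#' horizon).
#'
#' @param k1 Amplitude, `>= 0`.
#' @param T1 Rise timescale in hours, `> 0`.
#' @param h1 Rise exponent, `> 0`.
#' @param T2 Saturation timescale in hours, `> 0`.
#' @param h2 Saturation exponent, `> 0`.
#'
#' @return An object of class `promoter_params`.
#' @seealso [promoter_activity()], [peak_of_promoter()],
#'   [promoter_from_peak()]
#' @examples
#' p <- promoter_params(k1 = 1, T1 = 1, h1 = 1, T2 = 1, h2 = 2)
#' promoter_activity(1, p) # 0.5
#' @export
promoter_params <- function(k1, T1, h1, T2, h2) {
  vals <- c(k1 = k1, T1 = T1, h1 = h1, T2 = T2, h2 = h2)
  if (any(!is.finite(vals))) {
    stop("promoter parameters must be finite, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "),
         call. = FALSE)
  }
  if (k1 < 0) stop("`k1` must be >= 0", call. = FALSE)
  pos <- c(T1 = T1, h1 = h1, T2 = T2, h2 = h2)
  if (any(pos <= 0)) {
    stop("promoter parameters must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "promoter_params")
}

#' @export
print.promoter_params <- function(x, ...) {
  cat("<promoter_params>\n")
  cat(sprintf("  g(t) = %.4g * (t/%.4g)^%.4g / (1 + (t/%.4g)^%.4g)\n",
              x$k1, x$T1, x$h1, x$T2, x$h2))
  invisible(x)
}

#' @export
as.list.promoter_params <- function(x, ...) unclass(x)

#' Evaluate promoter activity g(t)
#'
#' Evaluates the parametric promoter activity at time `t` (hours).
#' Computed on the log scale, `exp(h1 log(t/T1) - log1p((t/T2)^h2))`,
#' so large exponents do not overflow; `g(0)` is defined as 0 by
#' continuity for `h1 > 0`.
#'
#' @param t Time(s) in hours, `>= 0`. Vectorized.
#' @param params A [promoter_params()] object.
#' @return Numeric vector of activities (same length as `t`),
#'   nonnegative.
#' @export
promoter_activity <- function(t, params) {
  stopifnot(inherits(params, "promoter_params"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    lt <- log(t[pos])
    z <- params$h2 * (lt - log(params$T2))
    # stable log1p(exp(z))
    soft <- ifelse(z > 30, z + log1p(exp(-z)), log1p(exp(z)))
    out[pos] <- params$k1 *
      exp(params$h1 * (lt - log(params$T1)) - soft)
  }
  out
}

#' Locate the peak of promoter activity
#'
#' Finds the argmax and max of g(t) on `[0, horizon]` by a coarse grid
#' scan refined with local optimization (final accuracy better than
#' 0.01 h). In plateau regimes (`h1 >= h2`, or any g still rising at the
#' horizon) the boundary value is returned with `plateau = TRUE`.
#'
#' @param params A [promoter_params()] object.
#' @param horizon Search horizon in hours (default 72, the span of a
#'   typical stimulation timecourse).
#' @return A tibble with columns `t_peak`, `g_peak`, `plateau`.
#' @export
peak_of_promoter <- function(params, horizon = 72) {
  stopifnot(inherits(params, "promoter_params"))
  if (!is.finite(horizon) || horizon <= 0) {
    stop("`horizon` must be a positive number", call. = FALSE)
  }
  grid <- seq(0, horizon, length.out = 4097)
  gv <- promoter_activity(grid, params)
  i <- which.max(gv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(function(tt) promoter_activity(tt, params),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-6)
    t_peak <- opt$maximum
    g_peak <- opt$objective
  } else {
    t_peak <- grid[i]
    g_peak <- gv[i]
  }
  # degenerate amplitude: flat zero curve
  if (g_peak <= 0) {
    return(tibble::tibble(t_peak = 0, g_peak = 0, plateau = TRUE))
  }
  # still (non-strictly) rising at the horizon => boundary, flag plateau
  plateau <- i >= length(grid) ||
    promoter_activity(horizon, params) >= (1 - 1e-9) * g_peak
  if (plateau) {
    t_peak <- horizon
    g_peak <- promoter_activity(horizon, params)
  }
  tibble::tibble(t_peak = t_peak, g_peak = g_peak, plateau = plateau)
}

#' Construct promoter parameters from peak time and height
#'
#' Convenience parameterization used by the synthetic presets: given the
#' desired interior peak time and height and the two exponents
#' (`h1 < h2`), solves for `T2` and `k1` in closed form. At the peak,
#' `(t/T2)^h2 = h1/(h2-h1)`, so `T2 = t_peak / u^(1/h2)` with
#' `u = h1/(h2-h1)`.
#'
#' @param t_peak Peak time, hours.
#' @param g_peak Peak activity (fluorescence units per hour).
#' @param h1,h2 Rise and saturation exponents, `0 < h1 < h2`.
#' @param T1 Rise timescale (only rescales `k1`; default 10 h).
#' @return A [promoter_params()] object whose activity peaks at
#'   `t_peak` with value `g_peak`.
#' @export
promoter_from_peak <- function(t_peak, g_peak, h1, h2, T1 = 10) {
  if (!(h1 > 0 && h2 > h1)) {
    stop("need 0 < h1 < h2 for an interior peak", call. = FALSE)
  }
  u <- h1 / (h2 - h1)
  T2 <- t_peak / u^(1 / h2)
  shape <- (t_peak / T1)^h1 / (1 + (t_peak / T2)^h2)
  promoter_params(k1 = g_peak / shape, T1 = T1, h1 = h1, T2 = T2, h2 = h2)
}
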