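# Forward solvers for the Timer signal ODEs.
#
# The one-state model dx/dt = g(t) - gamma x is linear, so the exact
# solution is the exponentially weighted convolution
#   x(t) = x0 e^{-gamma t} + int_0^t g(s) e^{-gamma (t - s)} ds.
# The default solver propagates this exactly between grid points with
# adaptive quadrature (rel.tol 1e-10) on each interval; an adaptive
# lsoda path is kept as a fallback for drives that defeat quadrature.

.as_drive <- function(drive) {
  if (inherits(drive, "promoter_params")) {
    function(t) promoter_activity(t, drive)
  } else if (is.function(drive)) {
    drive
  } else if (is.numeric(drive) && length(drive) == 1L && is.finite(drive)) {
    function(t) rep_len(drive, length(t))
  } else {
    stop("`drive` must be promoter_params, a function of time, ",
         "or a single constant rate", call. = FALSE)
  }
}

.check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times))) {
    stop("`times` must be finite numeric", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  times
}

# exact step: value at b given value at a, for rate `loss`
.conv_step <- function(g, loss, x_a, a, b, rel.tol = 1e-10) {
  if (b == a) return(x_a)
  add <- stats::integrate(function(s) g(s) * exp(-loss * (b - s)),
                          lower = a, upper = b,
                          rel.tol = rel.tol, abs.tol = 1e-13,
                          subdivisions = 400L)$value
  x_a * exp(-loss * (b - a)) + add
}

#' Simulate the Timer Blue signal
#'
#' Solves `dx/dt = g(t) - gamma x` on a time grid. The `"convolution"`
#' method propagates the exact solution
#' `x(t) = x0 exp(-gamma t) + int_0^t g(s) exp(-gamma (t-s)) ds`
#' interval by interval with adaptive quadrature; `"lsoda"` uses an
#' adaptive ODE solver (rtol 1e-10).
#'
#' @param drive The promoter drive: a [promoter_params()] object, a
#'   function of time (hours) returning a nonnegative rate, or a single
#'   constant rate.
#' @param decay A [timer_decay()] object (or bare positive rate).
#' @param x0 Initial Blue signal, `>= 0`.
#' @param times Strictly increasing nonnegative grid, hours.
#' @param method `"convolution"` (exact; default) or `"lsoda"`.
#' @return A tibble (`time_h`, `blue`), one row per grid point.
#' @examples
#' dec <- timer_decay(1)
#' simulate_blue(1, dec, x0 = 0, times = c(1, 2, 5)) # (1 - e^-t)
#' @export
simulate_blue <- function(drive, decay, x0 = 0, times,
                          method = c("convolution", "lsoda")) {
  method <- match.arg(method)
  g <- .as_drive(drive)
  gamma <- if (inherits(decay, "timer_decay")) decay$gamma else
    timer_decay(decay)$gamma
  .check_times(times)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 < 0) {
    stop("`x0` must be a single nonnegative number", call. = FALSE)
  }

  if (method == "convolution") {
    grid <- if (times[1] > 0) c(0, times) else times
    x <- numeric(length(grid))
    x[1] <- x0
    for (i in seq_len(length(grid) - 1L)) {
      x[i + 1L] <- .conv_step(g, gamma, x[i], grid[i], grid[i + 1L])
    }
    if (times[1] > 0) x <- x[-1L]
    tibble::tibble(time_h = times, blue = x)
  } else {
    grid <- if (times[1] > 0) c(0, times) else times
    sol <- deSolve::ode(
      y = c(x = x0), times = grid,
      func = function(t, y, p) list(g(t) - gamma * y),
      rtol = 1e-10, atol = 1e-12, method = "lsoda"
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed to converge; istate = ",
           attr(sol, "istate")[1], call. = FALSE)
    }
    x <- sol[, "x"]
    if (times[1] > 0) x <- x[-1L]
    tibble::tibble(time_h = times, blue = as.numeric(x))
  }
}

# two-state kernel: response of (B, R) to a unit impulse of production,
# tau hours later. B' = g - kb B ; R' = kb B - dr R.
.red_kernel <- function(tau, kb, dr) {
  if (abs(kb - dr) < 1e-10 * max(kb, 1)) {
    kb * tau * exp(-kb * tau)
  } else {
    kb / (kb - dr) * (exp(-dr * tau) - exp(-kb * tau))
  }
}

#' Solve the two-state (Blue, Red) Timer system
#'
#' The generator's maturation model: Blue is produced at rate `g(t)`,
#' converts to Red at rate `k_blue`, and Red is lost at rate
#' `delta_red`:
#' `dB/dt = g(t) - k_blue B`, `dR/dt = k_blue B - delta_red R`.
#' Solved exactly by convolution with the matrix-exponential kernels.
#'
#' @param drive As in [simulate_blue()].
#' @param k_blue Blue-to-Red maturation rate per hour (default
#'   `log(2)/4.1`, the Blue protein's ~4.1 h half-life).
#' @param delta_red Red loss rate per hour (default `log(2)/120`).
#' @param times Strictly increasing nonnegative grid, hours.
#' @param B0,R0 Initial signals.
#' @return A tibble (`time_h`, `blue`, `red`).
#' @export
solve_timer_states <- function(drive, k_blue = log(2) / 4.1,
                               delta_red = log(2) / 120, times,
                               B0 = 0, R0 = 0) {
  g <- .as_drive(drive)
  .check_times(times)
  stopifnot(k_blue > 0, delta_red >= 0)
  grid <- if (times[1] > 0) c(0, times) else times
  nb <- length(grid)
  B <- numeric(nb); R <- numeric(nb)
  B[1] <- B0; R[1] <- R0
  for (i in seq_len(nb - 1L)) {
    a <- grid[i]; b <- grid[i + 1L]; d <- b - a
    R[i + 1L] <- R[i] * exp(-delta_red * d) +
      B[i] * .red_kernel(d, k_blue, delta_red) +
      stats::integrate(function(s) g(s) * .red_kernel(b - s, k_blue,
                                                      delta_red),
                       a, b, rel.tol = 1e-10, abs.tol = 1e-13,
                       subdivisions = 400L)$value
    B[i + 1L] <- .conv_step(g, k_blue, B[i], a, b)
  }
  if (times[1] > 0) { B <- B[-1L]; R <- R[-1L] }
  tibble::tibble(time_h = times, blue = B, red = R)
}
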