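# Independent oracles used across the suite.

# Brute-force explicit-Euler integration of dx/dt = g(t) - gamma x.
# The recurrence x_{n+1} = x_n (1 - gamma dt) + g(t_n) dt is evaluated
# with a compiled recursive filter so tiny steps stay affordable.
euler_blue <- function(drive, gamma, x0 = 0, t_end, dt = 1e-4) {
  g <- if (inherits(drive, "promoter_params")) {
    function(t) promoter_activity(t, drive)
  } else if (is.function(drive)) drive else function(t) {
    rep_len(drive, length(t))
  }
  tg <- seq(0, t_end, by = dt)
  inc <- g(tg[-length(tg)]) * dt
  x <- stats::filter(inc, 1 - gamma * dt, method = "recursive",
                     init = x0)
  as.numeric(x[length(x)])
}

# Grid-scan argmax of promoter activity (step 1e-3 h).
scan_peak <- function(params, horizon = 72, step = 1e-3) {
  grid <- seq(0, horizon, by = step)
  gv <- promoter_activity(grid, params)
  i <- which.max(gv)
  list(t_peak = grid[i], g_peak = gv[i])
}

# Log-uniform draw of promoter parameters inside a box.
draw_params <- function(lower, upper) {
  u <- stats::runif(5)
  v <- exp(log(lower) + u * (log(upper) - log(lower)))
  promoter_params(v[1], v[2], v[3], v[4], v[5])
}

# Kinetically plausible sub-box used by the recovery suites: curve mass
# inside the 0-72 h observation window, Hill-like exponents, h2 > h1
# (interior-peak regime).
draw_recovery_params <- function() {
  h1 <- exp(stats::runif(1, log(0.5), log(3)))
  promoter_params(
    k1 = exp(stats::runif(1, log(1), log(100))),
    T1 = exp(stats::runif(1, log(2), log(40))),
    h1 = h1,
    T2 = exp(stats::runif(1, log(5), log(60))),
    h2 = exp(stats::runif(1, log(h1 + 0.5), log(6))))
}

# A minimal toy event table for summary statistics tests.
toy_events <- function(intensities, channel = "blue", time_h = 24,
                       condition = "a") {
  out <- tibble::tibble(
    event_id = sprintf("e%03d", seq_along(intensities)),
    time_h = time_h, condition = condition)
  out[[channel]] <- intensities
  out
}
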