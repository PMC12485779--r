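# Forward model: promoter activity, peak location, Blue ODE solvers.

test_that("promoter activity matches its closed form and scales linearly", {
  p <- promoter_params(k1 = 1, T1 = 1, h1 = 1, T2 = 1, h2 = 2)
  expect_identical(promoter_activity(0, p), 0)
  expect_equal(promoter_activity(1, p), 0.5) # t/(1+t^2) at t = 1
  tt <- c(0.1, 1, 7, 30, 72)
  expect_equal(promoter_activity(tt, p), tt / (1 + tt^2))

  p2 <- promoter_params(k1 = 2, T1 = 1, h1 = 1, T2 = 1, h2 = 2)
  expect_equal(promoter_activity(tt, p2), 2 * promoter_activity(tt, p))

  # overflow-safe far beyond the saturation timescale
  ph <- promoter_params(k1 = 1, T1 = 1, h1 = 9, T2 = 2, h2 = 10)
  expect_true(is.finite(promoter_activity(1e4, ph)))

  expect_error(promoter_activity(-1, p), ">= 0")
  expect_error(promoter_params(1, NaN, 1, 1, 2), "finite")
  expect_error(promoter_params(1, -1, 1, 1, 2), "positive")
})

test_that("peak location is found to 0.01 h and is amplitude-invariant", {
  p <- promoter_params(1, 1, 1, 1, 2)
  pk <- peak_of_promoter(p)
  expect_equal(pk$t_peak, 1, tolerance = 0.01)
  expect_equal(pk$g_peak, 0.5, tolerance = 1e-6)
  expect_false(pk$plateau)

  pk3 <- peak_of_promoter(promoter_params(3, 1, 1, 1, 2))
  expect_equal(pk3$t_peak, pk$t_peak, tolerance = 1e-4)
  expect_equal(pk3$g_peak, 3 * pk$g_peak, tolerance = 1e-9)

  # h1 = h2: activity is monotone, boundary value with plateau flag
  pp <- promoter_params(1, 2, 2, 3, 2)
  pkp <- peak_of_promoter(pp, horizon = 72)
  expect_true(pkp$plateau)
  expect_equal(pkp$t_peak, 72)
  expect_equal(pkp$g_peak, promoter_activity(72, pp))
})

test_that("peak agrees with a 1e-3 h grid scan across random shapes", {
  withr::local_seed(42)
  for (i in 1:8) {
    p <- draw_recovery_params()
    pk <- peak_of_promoter(p)
    ref <- scan_peak(p)
    if (!pk$plateau) {
      expect_lt(abs(pk$t_peak - ref$t_peak), 1e-3 + 1e-9)
    }
    expect_equal(pk$g_peak, ref$g_peak, tolerance = 1e-6)
  }
})

test_that("Blue ODE has the exact null and constant-drive solutions", {
  dec <- timer_decay(0.8)
  tt <- c(1, 3.5, 10, 24)
  z <- simulate_blue(0, dec, x0 = 0, times = tt)
  expect_equal(z$blue, rep(0, 4))

  # constant drive g0: x(t) = (g0/gamma)(1 - e^(-gamma t))
  g0 <- 0.8 # g0 = gamma so x(Inf) = 1
  x <- simulate_blue(g0, dec, x0 = 0, times = tt)
  expect_equal(x$blue, (g0 / 0.8) * (1 - exp(-0.8 * tt)),
               tolerance = 1e-8)
  expect_lt(abs(simulate_blue(g0, dec, 0, 200)$blue - 1), 1e-8)
})

test_that("convolution solver matches the explicit-Euler oracle", {
  p <- promoter_params(k1 = 1, T1 = 10, h1 = 2, T2 = 20, h2 = 4)
  gamma <- 0.697
  x24 <- simulate_blue(p, timer_decay(gamma), 0, 24)$blue
  ref <- euler_blue(p, gamma, 0, 24, dt = 1e-4)
  expect_equal(x24, ref, tolerance = 1e-4)

  # and the adaptive lsoda path agrees with the convolution path
  tt <- c(5, 12, 24, 48, 72)
  a <- simulate_blue(p, timer_decay(gamma), 0, tt)
  b <- simulate_blue(p, timer_decay(gamma), 0, tt, method = "lsoda")
  expect_equal(a$blue, b$blue, tolerance = 1e-8)
})

test_that("the ODE is linear: superposition and monotone response", {
  dec <- timer_decay(0.3)
  tt <- c(2, 8, 20, 50)
  g1 <- promoter_params(2, 5, 1.5, 15, 4)
  g2 <- promoter_params(1, 12, 2, 30, 5)
  both <- function(t) promoter_activity(t, g1) + promoter_activity(t, g2)
  xs <- simulate_blue(both, dec, 0, tt)$blue
  x1 <- simulate_blue(g1, dec, 0, tt)$blue
  x2 <- simulate_blue(g2, dec, 0, tt)$blue
  expect_equal(xs, x1 + x2, tolerance = 1e-8)

  # pointwise-larger drive gives a pointwise-larger trajectory
  bigger <- function(t) both(t) + 0.1
  expect_true(all(simulate_blue(bigger, dec, 0, tt)$blue > xs))

  expect_error(simulate_blue(g1, dec, 0, c(5, 2)), "increasing")
  expect_error(simulate_blue(g1, dec, -1, tt), "nonnegative")
})

test_that("half-life identities hold and step-off decay halves the signal", {
  expect_equal(decay_half_life(timer_decay(log(2) / 4.1)), 4.1,
               tolerance = 1e-12)
  expect_equal(decay_half_life(timer_decay(log(2))), 1)
  d <- timer_decay(0.697)
  expect_equal(d$gamma * d$half_life_blue, log(2), tolerance = 1e-12)
  expect_error(timer_decay(0), "positive")

  # drive switches off at t0: x(t0 + ln2/gamma) / x(t0) = 1/2
  gamma <- 0.55
  t0 <- 10
  g <- function(t) ifelse(t < t0, 3, 0)
  tt <- c(t0, t0 + log(2) / gamma)
  x <- simulate_blue(g, timer_decay(gamma), 0, tt)$blue
  expect_equal(x[2] / x[1], 0.5, tolerance = 1e-6)
})
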