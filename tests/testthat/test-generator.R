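# Synthetic single-cell Timer event generator.

quiet_cond <- function(...) {
  condition_spec("quiet", promoter = promoter_from_peak(12, 30, 2, 5),
                 lag_mean = 0, lag_sd = 0, t_first_div = Inf, ...)
}

test_that("Blue + Red conserves the cumulative drive when Red is stable", {
  cond <- quiet_cond()
  cfg <- generator_config(cond, times = c(24, 48), n_cells = 2,
                          noise_cv = 0, autofluor = 0, delta_red = 0,
                          seed = 4)
  ev <- simulate_experiment(cfg)
  for (tt in c(24, 48)) {
    G <- stats::integrate(function(s) promoter_activity(s, cond$promoter),
                          0, tt, rel.tol = 1e-10)$value
    tot <- ev$blue[ev$time_h == tt] + ev$red[ev$time_h == tt]
    expect_equal(tot, rep(G, 2), tolerance = 1e-6)
  }
})

test_that("a silent promoter yields only the autofluorescence floor", {
  cond <- condition_spec("null", promoter = promoter_params(0, 1, 1, 1, 2),
                         lag_mean = 0, lag_sd = 0, t_first_div = Inf)
  cfg <- generator_config(cond, times = c(0, 24), n_cells = 5,
                          noise_cv = 0, seed = 9)
  ev <- simulate_experiment(cfg)
  expect_equal(ev$blue, rep(cfg$autofluor[["blue"]], 10))
  expect_equal(ev$red, rep(cfg$autofluor[["red"]], 10))
})

test_that("CFSE halves per division and divisions follow the schedule", {
  cond <- condition_spec("div", promoter = promoter_from_peak(12, 30, 2, 5),
                         lag_mean = 0, lag_sd = 0,
                         t_first_div = 30, div_cycle_h = 10,
                         div_jitter_sd = 0)
  cfg <- generator_config(cond, times = c(24, 48, 72), n_cells = 4,
                          noise_cv = 0, autofluor = 0, seed = 2)
  ev <- simulate_experiment(cfg)
  # 24 h: no divisions; 48 h: divisions at 30 and 40 h; 72 h: at 30,40,50,60,70
  expect_equal(unique(ev$division_count[ev$time_h == 24]), 0L)
  expect_equal(unique(ev$division_count[ev$time_h == 48]), 2L)
  expect_equal(unique(ev$division_count[ev$time_h == 72]), 5L)
  expect_equal(ev$cfse, cfg$cfse_init / 2^ev$division_count)
})

test_that("noiseless medians collapse onto the two-state ODE solution", {
  cond <- quiet_cond()
  cfg <- generator_config(cond, times = c(0, 5, 12, 24, 48, 72),
                          n_cells = 25, noise_cv = 0, autofluor = 0,
                          seed = 3)
  ev <- simulate_experiment(cfg)
  med <- ev |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(blue = stats::median(blue),
                     red = stats::median(red))
  ref <- solve_timer_states(cond$promoter, k_blue = cfg$k_blue,
                            delta_red = cfg$delta_red,
                            times = c(5, 12, 24, 48, 72))
  expect_equal(med$blue[med$time_h > 0], ref$blue, tolerance = 1e-6)
  expect_equal(med$red[med$time_h > 0], ref$red, tolerance = 1e-6)
})

test_that("lognormal noise preserves the geometric mean of the signal", {
  cond <- quiet_cond()
  cfg <- generator_config(cond, times = c(12, 24, 48), n_cells = 5000,
                          noise_cv = 0.2, autofluor = 0, seed = 13)
  ev <- simulate_experiment(cfg)
  ref <- solve_timer_states(cond$promoter, k_blue = cfg$k_blue,
                            delta_red = cfg$delta_red,
                            times = c(12, 24, 48))
  sdlog <- sqrt(log(1 + 0.2^2))
  for (i in seq_len(3)) {
    lb <- log(ev$blue[ev$time_h == ref$time_h[i]])
    se <- sdlog / sqrt(length(lb))
    expect_lt(abs(mean(lb) - log(ref$blue[i])), 3 * se)
  }
})

test_that("the same seed reproduces the event table bit for bit", {
  cfg <- generator_config(condition_presets("itk_wt_N4"),
                          n_cells = 40, seed = 77)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1, e2)
  truth <- generator_truth(e1)
  expect_identical(truth$rng[1], "Mersenne-Twister")
  expect_identical(nrow(truth$cells), nrow(e1))
  e3 <- simulate_experiment(generator_config(
    condition_presets("itk_wt_N4"), n_cells = 40, seed = 78))
  expect_false(identical(e1$blue, e3$blue))
})

test_that("amplitude ordering of drives is preserved in every Blue summary", {
  strong <- quiet_cond()
  weak <- condition_spec(
    "weak", promoter = promoter_from_peak(12, 15, 2, 5),
    lag_mean = 0, lag_sd = 0, t_first_div = Inf)
  cfg <- generator_config(list(strong, weak),
                          times = c(5, 12, 24, 48, 72), n_cells = 10,
                          noise_cv = 0, autofluor = 0, seed = 6)
  ev <- simulate_experiment(cfg)
  med <- ev |>
    dplyr::group_by(condition, time_h) |>
    dplyr::summarise(blue = stats::median(blue), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = blue)
  expect_true(all(med$quiet > med$weak))
})

test_that("knockout-like drive raises the Blue 48h/24h fold change", {
  cfg <- generator_config(condition_presets(c("itk_wt_N4", "itk_ko_N4")),
                          times = c(24, 48), n_cells = 300,
                          noise_cv = 0, seed = 19)
  ev <- simulate_experiment(cfg)
  s <- ev |>
    dplyr::group_by(condition, genotype, time_h) |>
    dplyr::summarise(mfi_positive = stats::median(blue),
                     .groups = "drop") |>
    dplyr::mutate(channel = "blue")
  fc <- fold_change_ratio(s, value_cols = "mfi_positive")
  ko <- fc$ratio_mfi_positive[fc$genotype == "Itk_ko"]
  wt <- fc$ratio_mfi_positive[fc$genotype == "Itk_wt"]
  expect_gt(ko, wt)
})

test_that("condition presets serialize round-trip exactly", {
  pres <- condition_presets(c("itk_wt_N4", "itk_ko_T4",
                              "wt_N4_prn694_24h"))
  path <- withr::local_tempfile(fileext = ".json")
  write_presets(pres, path)
  back <- read_presets(path)
  expect_identical(lapply(back, unclass), lapply(pres, unclass))
})

test_that("simulate_cell returns a single consistent event record", {
  cfg <- generator_config(condition_presets("itk_wt_N4"), n_cells = 1,
                          noise_cv = 0, autofluor = 0, seed = 5)
  cell <- withr::with_seed(5, simulate_cell(cfg, "itk_wt_N4", 24))
  expect_identical(nrow(cell), 1L)
  expect_true(all(c("blue", "red", "cfse", "cd69") %in% names(cell)))
  expect_gte(cell$blue, 0)
})
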