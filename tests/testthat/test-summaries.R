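# Flow-cytometry summary statistics: gating, MFI, normalization,
# ratio statistics, division cycles, pseudo-time bins.

test_that("percent positive uses a strict gate and partitions exactly", {
  ev <- toy_events(c(1, 2, 3, 4))
  g <- gate_spec("blue", 2.5)
  expect_equal(percent_positive(ev, g)$pct_positive, 50)
  expect_equal(percent_positive(ev, gate_spec("blue", 0.5))$pct_positive,
               100)
  # boundary events are negative: threshold at the max gives 0%
  ev3 <- toy_events(c(1, 2, 3))
  expect_equal(percent_positive(ev3, gate_spec("blue", 3))$pct_positive,
               0)
  # positive + negative = 100 exactly, per group
  withr::local_seed(1)
  evr <- toy_events(stats::runif(100, 0, 10))
  pos <- percent_positive(evr, g)$pct_positive
  neg <- 100 * mean(evr$blue <= g$threshold)
  expect_identical(pos + neg, 100)
})

test_that("MFI is the median of gated-positive events", {
  g <- gate_spec("blue", 5)
  expect_equal(mfi_positive(toy_events(c(10, 20, 90, 1)), g)$mfi_positive,
               20)
  expect_equal(mfi_positive(toy_events(c(10, 20, 2)), g)$mfi_positive, 15)
  res <- mfi_positive(toy_events(c(1, 2, 3)), g)
  expect_true(is.na(res$mfi_positive))
  expect_identical(res$n_positive, 0L)
})

test_that("normalization maps the max to 100 and is idempotent and scale-invariant", {
  s <- tibble::tibble(channel = "blue", time_h = c(5, 12, 24, 48),
                      mfi_positive = c(2, 4, 8, 6))
  n1 <- normalize_to_experiment_max(s)
  expect_equal(n1$mfi_normalized, c(25, 50, 100, 75))
  expect_equal(normalize_to_experiment_max(n1)$mfi_normalized,
               n1$mfi_normalized)
  s10 <- dplyr::mutate(s, mfi_positive = mfi_positive * 10)
  expect_equal(normalize_to_experiment_max(s10)$mfi_normalized,
               n1$mfi_normalized)

  one <- normalize_to_experiment_max(s[3, ])
  expect_equal(one$mfi_normalized, 100)
  eq <- normalize_to_experiment_max(dplyr::mutate(s, mfi_positive = 7))
  expect_equal(eq$mfi_normalized, rep(100, 4))
  zero <- normalize_to_experiment_max(dplyr::mutate(s, mfi_positive = 0))
  expect_true(all(is.na(zero$mfi_normalized)))
})

test_that("fold-change ratios follow the 48h/24h definition", {
  s <- tibble::tibble(condition = "a", channel = "blue",
                      time_h = c(24, 48), mfi_positive = c(10, 5),
                      pct_positive = c(40, 40))
  fc <- fold_change_ratio(s)
  expect_equal(fc$ratio_mfi_positive, 0.5)
  expect_equal(fc$ratio_pct_positive, 1.0) # equal values ratio to 1
  s$mfi_positive <- c(8, 12)
  expect_equal(fold_change_ratio(s)$ratio_mfi_positive, 1.5)
  # same-time ratio is identically 1
  expect_equal(fold_change_ratio(s, 24, 24)$ratio_mfi_positive, 1)
  # zero or missing denominators propagate as NA
  s$mfi_positive <- c(0, 5)
  expect_true(is.na(fold_change_ratio(s)$ratio_mfi_positive))
})

test_that("genotype ratio curves match strata and flag missing ones", {
  s <- tidyr::expand_grid(genotype = c("Itk_wt", "Itk_ko"),
                          time_h = c(5, 24, 72), channel = "blue")
  s$mfi_positive <- c(3, 6, 9, 3, 6, 9)
  r <- genotype_ratio_curve(s)
  expect_equal(r$ratio, rep(1, 3))
  s$mfi_positive[s$genotype == "Itk_ko"] <- c(6, 12, 18)
  expect_equal(genotype_ratio_curve(s)$ratio, rep(2, 3))
  # wild-type missing at 72 h: NA there, intact elsewhere
  s2 <- s[!(s$genotype == "Itk_wt" & s$time_h == 72), ]
  r2 <- genotype_ratio_curve(s2)
  expect_equal(r2$ratio[r2$time_h != 72], c(2, 2))
  expect_true(is.na(r2$ratio[r2$time_h == 72]))
})

test_that("nested gate fractions follow their definition", {
  ev <- tibble::tibble(
    event_id = sprintf("e%02d", 1:12), time_h = 48,
    cd69 = c(rep(10, 10), 0, 0),
    blue = c(rep(5, 8), 0, 0, 5, 5))
  outer <- gate_spec("cd69", 1)
  inner <- gate_spec("blue", 1)
  expect_equal(
    positive_fraction_within_gate(ev, outer, inner)$pct_inner_of_outer,
    80) # 8 Blue+ of 10 CD69+
  expect_equal(
    positive_fraction_within_gate(ev, outer, outer)$pct_inner_of_outer,
    100)
  none <- gate_spec("blue", 100)
  expect_equal(
    positive_fraction_within_gate(ev, outer, none)$pct_inner_of_outer, 0)
  empty <- gate_spec("cd69", 1e6)
  expect_true(is.na(
    positive_fraction_within_gate(ev, empty, inner)$pct_inner_of_outer))
})

test_that("CFSE halving assigns division counts exactly when noiseless", {
  init <- 5000
  ev <- tibble::tibble(
    event_id = sprintf("e%02d", 1:8),
    time_h = c(0, 0, rep(48, 6)),
    cfse = init / 2^c(0, 0, 0, 1, 1, 2, 3, 4),
    blue = 1)
  out <- assign_divisions(ev)
  expect_identical(out$division_count,
                   c(0L, 0L, 0L, 1L, 1L, 2L, 3L, 4L))
})

test_that("division-cycle summaries normalize within the queried time", {
  ev <- tibble::tibble(
    event_id = sprintf("e%03d", 1:60), time_h = 48,
    division_count = rep(0:2, each = 20),
    blue = rep(c(80, 40, 20), each = 20))
  d <- division_cycle_summary(ev, min_n = 20)
  expect_equal(d$mfi_normalized, c(100, 50, 25))
  expect_false(any(d$low_n))
  d5 <- division_cycle_summary(ev[c(1:20, 21:24), ], min_n = 20)
  expect_true(d5$low_n[d5$division_count == 1])
  # a single cohort holding the max normalizes to 100
  expect_equal(division_cycle_summary(ev[1:20, ])$mfi_normalized, 100)
})

test_that("pseudo-time bins partition events and preserve monotone markers", {
  withr::local_seed(8)
  blue <- stats::runif(300, 0, 150)
  ev <- tibble::tibble(event_id = sprintf("e%03d", 1:300), time_h = 24,
                       blue = blue, cd69 = 3 * blue + 1) # marker ~ Blue
  edges <- c(0, 10, 100)
  pt <- pseudo_time_bins(ev, bin_edges = edges,
                         target_channels = "cd69")
  expect_equal(sum(pt$n_events), 300) # bins partition the events
  expect_true(all(diff(pt$mfi) > 0))  # monotone construction
  expect_equal(max(pt$mfi_normalized, na.rm = TRUE), 100)
  # an empty bin is flagged missing in place, ordering preserved
  ev2 <- dplyr::filter(ev, blue < 10 | blue >= 100)
  pt2 <- pseudo_time_bins(ev2, bin_edges = edges,
                          target_channels = "cd69")
  expect_identical(pt2$n_events[2], 0L)
  expect_true(is.na(pt2$mfi[2]))
  expect_error(pseudo_time_bins(ev, bin_edges = 5,
                                target_channels = "cd69"), "edges")
})

test_that("summaries are permutation- and scale-invariant", {
  withr::local_seed(21)
  for (i in 1:5) {
    n <- 120
    ev <- tibble::tibble(
      event_id = sprintf("e%03d", 1:n),
      time_h = sample(c(5, 24, 48), n, replace = TRUE),
      condition = sample(c("a", "b"), n, replace = TRUE),
      blue = stats::rlnorm(n, 2, 1))
    g <- gate_spec("blue", stats::median(ev$blue))
    perm <- ev[sample(n), ]
    by <- c("condition", "time_h")
    expect_equal(dplyr::arrange(percent_positive(perm, g, by),
                                condition, time_h),
                 dplyr::arrange(percent_positive(ev, g, by),
                                condition, time_h))
    expect_equal(dplyr::arrange(mfi_positive(perm, g, by),
                                condition, time_h),
                 dplyr::arrange(mfi_positive(ev, g, by),
                                condition, time_h))
    # scaling all intensities (and the gate) leaves normalized MFI fixed
    s <- summarize_events(ev, g, by = by)
    ev_c <- dplyr::mutate(ev, blue = blue * 7)
    s_c <- summarize_events(ev_c, gate_spec("blue", g$threshold * 7),
                            by = by)
    expect_equal(s_c$mfi_normalized, s$mfi_normalized)
    expect_equal(s_c$pct_positive, s$pct_positive)
  }
})
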