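# Synthetic single-cell Timer event generator.
#
# Per-cell mechanism: after a random onset lag L, the cell's promoter
# drives Blue production at g(t - L); Blue matures into Red at rate
# k_blue and Red is lost slowly at delta_red:
#   dB/dt = g(t - L) - k_blue B,   dR/dt = k_blue B - delta_red R.
# At each division, timer states and CFSE halve (protein partitioning
# between daughters); synthesis continues through g. Because both
# states halve by the same scalar, the solution with divisions at
# d_1 < ... < d_m is the exact convolution
#   B(t) = int g(s - L) 2^(-N(s,t)) exp(-k_blue (t - s)) ds
# (and the analogous two-exponential kernel for Red), where N(s,t)
# counts divisions in (s, t]. The integrals are evaluated per segment
# between breakpoints (lag, inhibitor switch, divisions) with composite
# Gauss-Legendre quadrature, vectorized across cells.
#
# Activation markers are a deliberately simple, non-mechanistic
# stand-in: linear-threshold readouts of three latent pathway-activity
# profiles (NFAT-like, NFkB-like, AP-1-like) scaled per condition.
# Measurement noise is multiplicative lognormal (meanlog 0, so medians
# are preserved) on top of an additive autofluorescence floor.

.gl_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gl <- pracma::gaussLegendre(10, 0, 1)
      cache <<- list(x = gl$x, w = gl$w)
    }
    cache
  }
})

.timer_channels <- c("blue", "red", "cfse")
.marker_channels <- c("cd69", "cd25", "irf4")
.pathways <- c("NFAT", "NFkB", "AP1")

.default_floor <- function() {
  c(blue = 1, red = 3, cfse = 50, cd69 = 10, cd25 = 8, irf4 = 6)
}

.default_pathway_profiles <- function() {
  list(NFAT = promoter_from_peak(12, 1, 2, 4),
       NFkB = promoter_from_peak(8, 1, 2, 4),
       AP1  = promoter_from_peak(6, 1, 1.5, 4))
}

.default_marker_models <- function() {
  list(
    cd69 = list(weights = c(AP1 = 1200, NFkB = 300),
                thresholds = c(AP1 = 0.05, NFkB = 0.10)),
    cd25 = list(weights = c(NFAT = 600, NFkB = 400),
                thresholds = c(NFAT = 0.10, NFkB = 0.10)),
    irf4 = list(weights = c(NFAT = 500, NFkB = 300),
                thresholds = c(NFAT = 0.15, NFkB = 0.10)))
}

#' Define a synthetic stimulation condition
#'
#' A named bundle of kinetic parameters for one condition (genotype x
#' peptide x dose x inhibitor): the promoter activity, the per-cell
#' onset-lag distribution, the division schedule, and the pathway
#' scalings feeding the marker models. An inhibitor added mid-course is
#' modeled by switching the promoter and pathway scalings at
#' `switch_time` hours.
#'
#' @param name Condition label used in event tables.
#' @param genotype `"Itk_wt"` or `"Itk_ko"`.
#' @param peptide `"N4"` or `"T4"`.
#' @param dose_nM Peptide dose, nM (> 0).
#' @param inhibitor One of `"none"`, `"CsA"`, `"IKK16"`, `"PD325901"`,
#'   `"PRN694"`.
#' @param inhibitor_add_time_h 0 or 24 (delayed-addition design).
#' @param promoter A [promoter_params()] object.
#' @param g_scale_after Multiplier applied to g(t) from `switch_time`
#'   on (default 1 = no switch).
#' @param switch_time Hour at which scalings switch (default `Inf`).
#' @param pathway_scales,pathway_scales_after Named vectors over
#'   `NFAT`, `NFkB`, `AP1` (after-switch defaults to before).
#' @param pathway_shift_h Per-pathway onset delay, hours.
#' @param lag_mean,lag_sd Per-cell onset lag distribution, hours
#'   (normal, truncated at 0).
#' @param t_first_div Mean time to first division, hours (`Inf`
#'   disables division).
#' @param div_cycle_h Cycle length of later divisions, hours.
#' @param div_jitter_sd Per-cell jitter of the first-division time.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name, genotype = "Itk_wt", peptide = "N4",
                           dose_nM = 1,
                           inhibitor = "none",
                           inhibitor_add_time_h = 0,
                           promoter,
                           g_scale_after = 1, switch_time = Inf,
                           pathway_scales = c(NFAT = 1, NFkB = 1, AP1 = 1),
                           pathway_scales_after = NULL,
                           pathway_shift_h = c(NFAT = 0, NFkB = 0, AP1 = 0),
                           lag_mean = 1, lag_sd = 0.5,
                           t_first_div = Inf, div_cycle_h = 10,
                           div_jitter_sd = 0) {
  stopifnot(inherits(promoter, "promoter_params"),
            genotype %in% c("Itk_wt", "Itk_ko"),
            peptide %in% c("N4", "T4"),
            inhibitor %in% c("none", "CsA", "IKK16", "PD325901", "PRN694"),
            inhibitor_add_time_h %in% c(0, 24),
            dose_nM > 0, lag_mean >= 0, lag_sd >= 0,
            div_cycle_h > 0, div_jitter_sd >= 0, g_scale_after >= 0)
  if (is.null(pathway_scales_after)) pathway_scales_after <- pathway_scales
  for (v in list(pathway_scales, pathway_scales_after, pathway_shift_h)) {
    stopifnot(all(.pathways %in% names(v)), all(is.finite(v)))
  }
  structure(list(
    name = name, genotype = genotype, peptide = peptide,
    dose_nM = dose_nM, inhibitor = inhibitor,
    inhibitor_add_time_h = inhibitor_add_time_h,
    promoter = promoter, g_scale_after = g_scale_after,
    switch_time = switch_time,
    pathway_scales = pathway_scales[.pathways],
    pathway_scales_after = pathway_scales_after[.pathways],
    pathway_shift_h = pathway_shift_h[.pathways],
    lag_mean = lag_mean, lag_sd = lag_sd,
    t_first_div = t_first_div, div_cycle_h = div_cycle_h,
    div_jitter_sd = div_jitter_sd), class = "condition_spec")
}

#' Named condition presets
#'
#' Parameter bundles encoding the qualitative contrasts of ITK-dependent
#' Timer kinetics, fixed by construction (not fit to any data):
#'
#' * `itk_wt_N4`: strong-agonist wild type; fast onset, promoter peak
#'   at 12 h, declining drive; divisions from ~30 h.
#' * `itk_ko_N4`: same peak time, peak height exactly 30% lower, and a
#'   much slower post-peak decline (sustained drive).
#' * `itk_wt_T4`: weak agonist; promoter peak at 4 h, lower amplitude,
#'   delayed onset.
#' * `itk_ko_T4`: rapid initial rise to a plateau sustained to ~60 h,
#'   then sharp decline.
#' * `wt_N4_ikk16`: NF-kB inhibition; knockout-like sustained drive.
#' * `wt_N4_csa`: NFAT inhibition; reduced/delayed NFAT arm, faster
#'   AP-1 arm markers.
#' * `wt_N4_pd325901`: MEK inhibition; AP-1 arm suppressed.
#' * `wt_N4_prn694_0h` / `wt_N4_prn694_24h`: ITK inhibitor at time 0
#'   (knockout-like throughout) or added at 24 h (wild-type kinetics
#'   switching to reduced drive at 24 h).
#'
#' @param names Preset name(s); see Details. Default: the four
#'   genotype x peptide presets.
#' @return A list of [condition_spec()] objects.
#' @export
condition_presets <- function(names = c("itk_wt_N4", "itk_ko_N4",
                                        "itk_wt_T4", "itk_ko_T4")) {
  build <- function(nm) {
    switch(nm,
      itk_wt_N4 = condition_spec(
        "itk_wt_N4", "Itk_wt", "N4",
        promoter = promoter_from_peak(12, 30, h1 = 2, h2 = 5),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 30, div_cycle_h = 10, div_jitter_sd = 2),
      itk_ko_N4 = condition_spec(
        "itk_ko_N4", "Itk_ko", "N4",
        promoter = promoter_from_peak(12, 21, h1 = 3, h2 = 3.8),
        pathway_scales = c(NFAT = 0.6, NFkB = 0.8, AP1 = 0.9),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 36, div_cycle_h = 12, div_jitter_sd = 2),
      itk_wt_T4 = condition_spec(
        "itk_wt_T4", "Itk_wt", "T4",
        promoter = promoter_from_peak(4, 15, h1 = 2, h2 = 5),
        pathway_scales = c(NFAT = 0.7, NFkB = 0.7, AP1 = 0.7),
        lag_mean = 2, lag_sd = 1,
        t_first_div = 34, div_cycle_h = 11, div_jitter_sd = 2),
      itk_ko_T4 = condition_spec(
        "itk_ko_T4", "Itk_ko", "T4",
        promoter = promoter_params(k1 = 5, T1 = 10, h1 = 0.6,
                                   T2 = 60, h2 = 8),
        pathway_scales = c(NFAT = 0.4, NFkB = 0.6, AP1 = 0.8),
        lag_mean = 3, lag_sd = 1.5,
        t_first_div = 40, div_cycle_h = 12, div_jitter_sd = 2),
      wt_N4_ikk16 = condition_spec(
        "wt_N4_ikk16", "Itk_wt", "N4", inhibitor = "IKK16",
        promoter = promoter_from_peak(12, 27, h1 = 2.5, h2 = 3.2),
        pathway_scales = c(NFAT = 1, NFkB = 0.2, AP1 = 1),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 30, div_cycle_h = 10, div_jitter_sd = 2),
      wt_N4_csa = condition_spec(
        "wt_N4_csa", "Itk_wt", "N4", inhibitor = "CsA",
        promoter = promoter_from_peak(14, 12, h1 = 2, h2 = 4.5),
        pathway_scales = c(NFAT = 0.2, NFkB = 1, AP1 = 1.3),
        pathway_shift_h = c(NFAT = 8, NFkB = 0, AP1 = 0),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 32, div_cycle_h = 10, div_jitter_sd = 2),
      wt_N4_pd325901 = condition_spec(
        "wt_N4_pd325901", "Itk_wt", "N4", inhibitor = "PD325901",
        promoter = promoter_from_peak(12, 24, h1 = 2, h2 = 5),
        pathway_scales = c(NFAT = 1, NFkB = 1, AP1 = 0.05),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 32, div_cycle_h = 10, div_jitter_sd = 2),
      wt_N4_prn694_0h = condition_spec(
        "wt_N4_prn694_0h", "Itk_wt", "N4", inhibitor = "PRN694",
        inhibitor_add_time_h = 0,
        promoter = promoter_from_peak(12, 21, h1 = 3, h2 = 3.8),
        pathway_scales = c(NFAT = 0.6, NFkB = 0.8, AP1 = 0.9),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 36, div_cycle_h = 12, div_jitter_sd = 2),
      wt_N4_prn694_24h = condition_spec(
        "wt_N4_prn694_24h", "Itk_wt", "N4", inhibitor = "PRN694",
        inhibitor_add_time_h = 24,
        promoter = promoter_from_peak(12, 30, h1 = 2, h2 = 5),
        g_scale_after = 0.25, switch_time = 24,
        pathway_scales = c(NFAT = 1, NFkB = 1, AP1 = 1),
        pathway_scales_after = c(NFAT = 0.25, NFkB = 0.5, AP1 = 0.5),
        lag_mean = 1, lag_sd = 0.5,
        t_first_div = 30, div_cycle_h = 10, div_jitter_sd = 2),
      stop("unknown preset: ", nm, call. = FALSE))
  }
  out <- lapply(names, build)
  names(out) <- names
  out
}

#' Generator configuration
#'
#' Everything needed to simulate a multi-condition, multi-timepoint
#' Timer experiment reproducibly.
#'
#' @param conditions List of [condition_spec()] objects (default: the
#'   four genotype x peptide presets).
#' @param times Sampling times, hours (default `c(0, 5, 12, 24, 48, 72)`).
#' @param n_cells Events per condition per time point (default 1000).
#' @param k_blue Blue-to-Red maturation rate, per hour (default
#'   `log(2)/4.1`: the Blue form's ~4.1 h half-life).
#' @param delta_red Red loss rate, per hour (default `log(2)/120`, a
#'   slow 120 h half-life).
#' @param noise_cv Multiplicative lognormal noise CV; a scalar or a
#'   named per-channel vector (default 0.2).
#' @param autofluor Additive autofluorescence floor per channel; named
#'   vector, defaults to ~1% of a typical positive signal per channel.
#'   Use 0 to disable.
#' @param cfse_init Undivided CFSE intensity (default 5000).
#' @param dilution Halve timer and CFSE intensities at each division
#'   (default `TRUE`).
#' @param pathway_profiles Named list of unit-peak [promoter_params()]
#'   latent pathway-activity profiles (`NFAT`, `NFkB`, `AP1`).
#' @param marker_models Named list of linear-threshold marker models
#'   (`weights`, `thresholds` per pathway).
#' @param seed Integer seed; fixes the full event table bit-for-bit
#'   (base R Mersenne-Twister, recorded in the truth sidecar).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(conditions = condition_presets(),
                             times = c(0, 5, 12, 24, 48, 72),
                             n_cells = 1000,
                             k_blue = log(2) / 4.1,
                             delta_red = log(2) / 120,
                             noise_cv = 0.2,
                             autofluor = .default_floor(),
                             cfse_init = 5000,
                             dilution = TRUE,
                             pathway_profiles = .default_pathway_profiles(),
                             marker_models = .default_marker_models(),
                             seed = 1L) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, logical(1), "condition_spec")),
            all(times >= 0), !is.unsorted(times, strictly = TRUE),
            n_cells >= 0, k_blue > 0, delta_red >= 0,
            all(noise_cv >= 0), all(autofluor >= 0), cfse_init > 0)
  channels <- c(.timer_channels, names(marker_models))
  cv <- if (length(noise_cv) == 1L && is.null(names(noise_cv))) {
    stats::setNames(rep(noise_cv, length(channels)), channels)
  } else {
    stopifnot(all(channels %in% names(noise_cv)))
    noise_cv[channels]
  }
  floor <- if (length(autofluor) == 1L && is.null(names(autofluor))) {
    stats::setNames(rep(autofluor, length(channels)), channels)
  } else {
    fl <- .default_floor()[channels]
    fl[intersect(names(autofluor), channels)] <-
      autofluor[intersect(names(autofluor), channels)]
    fl
  }
  names(conditions) <- vapply(conditions, `[[`, character(1), "name")
  structure(list(conditions = conditions, times = times,
                 n_cells = as.integer(n_cells), k_blue = k_blue,
                 delta_red = delta_red, noise_cv = cv,
                 autofluor = floor, cfse_init = cfse_init,
                 dilution = isTRUE(dilution),
                 pathway_profiles = pathway_profiles,
                 marker_models = marker_models,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic (B, R) for a group of cells sharing t_sample, division
# count m and switch structure; lag and t_first vary per cell.
.two_state_cells <- function(cond, k_blue, delta_red, lag, t_first, m,
                             t_sample) {
  n <- length(lag)
  if (t_sample <= 0 || n == 0L) {
    return(list(B = numeric(n), R = numeric(n)))
  }
  g0 <- cond$promoter
  sw <- cond$switch_time
  has_sw <- is.finite(sw) && sw < t_sample && cond$g_scale_after != 1
  lag <- pmin(lag, t_sample)
  cols <- list(lag)
  if (has_sw) cols <- c(cols, list(rep(sw, n)))
  if (m > 0L) {
    for (j in seq_len(m)) {
      cols <- c(cols, list(pmin(t_first + (j - 1) * cond$div_cycle_h,
                                t_sample)))
    }
  }
  cols <- c(cols, list(rep(t_sample, n)))
  bp <- do.call(cbind, cols)
  for (j in seq(2L, ncol(bp))) bp[, j] <- pmax(bp[, j], bp[, j - 1L])

  gl <- .gl_nodes()
  n_panels <- 4L
  B <- numeric(n); R <- numeric(n)
  n_seg <- ncol(bp) - 1L
  for (k in seq_len(n_seg)) {
    a <- bp[, k]; b <- bp[, k + 1L]
    len <- b - a
    if (all(len <= 0)) next
    scale_k <- if (has_sw && k >= 2L) cond$g_scale_after else 1
    expo <- m - max(0L, k - (1L + has_sw)) # divisions after this segment
    halve <- 2^(-expo)
    for (p in seq_len(n_panels)) {
      pa <- a + (p - 1) * len / n_panels
      plen <- len / n_panels
      for (q in seq_along(gl$x)) {
        s <- pa + gl$x[q] * plen
        gv <- promoter_activity(pmax(s - lag, 0), g0)
        wq <- gl$w[q] * plen * scale_k * halve
        tau <- t_sample - s
        B <- B + wq * gv * exp(-k_blue * tau)
        R <- R + wq * gv * .red_kernel(tau, k_blue, delta_red)
      }
    }
  }
  list(B = B, R = R)
}

# latent pathway activity at the sample time for each cell (vector lag)
.marker_values <- function(config, cond, lag, t_sample) {
  profs <- config$pathway_profiles
  after <- is.finite(cond$switch_time) && t_sample >= cond$switch_time
  scales <- if (after) cond$pathway_scales_after else cond$pathway_scales
  p_act <- lapply(.pathways, function(pw) {
    tt <- pmax(t_sample - cond$pathway_shift_h[[pw]] - lag, 0)
    scales[[pw]] * promoter_activity(tt, profs[[pw]])
  })
  names(p_act) <- .pathways
  out <- lapply(config$marker_models, function(mm) {
    v <- numeric(length(lag))
    for (pw in names(mm$weights)) {
      v <- v + mm$weights[[pw]] *
        pmax(p_act[[pw]] - mm$thresholds[[pw]], 0)
    }
    v
  })
  out
}

#' Simulate one synthetic cell
#'
#' Draws a single event record for a condition at one sample time,
#' using the current RNG state (seed upstream for reproducibility).
#' See [simulate_experiment()] for the batch path.
#'
#' @param config A [generator_config()].
#' @param condition A [condition_spec()] (or the name of one of
#'   `config$conditions`).
#' @param t_sample Sample time, hours.
#' @return A one-row event tibble.
#' @export
simulate_cell <- function(config, condition, t_sample) {
  stopifnot(inherits(config, "generator_config"), t_sample >= 0)
  if (is.character(condition)) condition <- config$conditions[[condition]]
  stopifnot(inherits(condition, "condition_spec"))
  .simulate_stratum(config, condition, t_sample, n = 1L,
                    event_offset = 0L)$events
}

# n cells for one condition x time stratum; returns events + truth
.simulate_stratum <- function(config, cond, t_sample, n,
                              event_offset = 0L) {
  lag <- pmax(stats::rnorm(n, cond$lag_mean, cond$lag_sd), 0)
  if (config$dilution && is.finite(cond$t_first_div)) {
    tf <- pmax(stats::rnorm(n, cond$t_first_div, cond$div_jitter_sd), 5)
    m <- ifelse(t_sample >= tf,
                pmax(floor((t_sample - tf) / cond$div_cycle_h), 0) + 1, 0)
    m <- as.integer(m)
  } else {
    tf <- rep(Inf, n)
    m <- integer(n)
  }

  B <- numeric(n); R <- numeric(n)
  for (mm in unique(m)) {
    idx <- which(m == mm)
    sig <- .two_state_cells(cond, config$k_blue, config$delta_red,
                            lag[idx], tf[idx], mm, t_sample)
    B[idx] <- sig$B; R[idx] <- sig$R
  }
  cfse <- config$cfse_init / 2^m
  markers <- .marker_values(config, cond, lag, t_sample)

  truth <- tibble::tibble(lag = lag, t_first_div = tf,
                          division_count = m,
                          blue_true = B, red_true = R)

  chans <- c(list(blue = B, red = R, cfse = cfse), markers)
  for (ch in names(chans)) {
    cv <- config$noise_cv[[ch]]
    x <- chans[[ch]] + config$autofluor[[ch]]
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      x <- x * exp(stats::rnorm(n, 0, sdlog))
    }
    chans[[ch]] <- x
  }

  events <- tibble::tibble(
    event_id = sprintf("%s_t%g_%06d", cond$name, t_sample,
                       event_offset + seq_len(n)),
    condition = cond$name,
    time_h = t_sample,
    genotype = cond$genotype,
    peptide = cond$peptide,
    dose_nM = cond$dose_nM,
    inhibitor = cond$inhibitor,
    inhibitor_add_time_h = cond$inhibitor_add_time_h,
    division_count = m)
  for (ch in names(chans)) events[[ch]] <- chans[[ch]]
  list(events = events, truth = truth)
}

#' Simulate a full Timer experiment
#'
#' Generates an event table over all conditions and time points in the
#' configuration, with a truth sidecar (per-cell lags, division counts,
#' noiseless timer signals, the generating promoter parameters and the
#' RNG algorithm) attached as the `"truth"` attribute. The same seed
#' always yields a bit-identical table.
#'
#' @param config A [generator_config()].
#' @return An event tibble (one row per cell); see
#'   [generator_truth()] for the sidecar.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_cells == 0L) {
    stop("`n_cells` is 0: every stratum would be empty", call. = FALSE)
  }
  res <- withr::with_seed(config$seed, {
    purrr::map(config$conditions, function(cond) {
      purrr::map(config$times, function(t_sample) {
        .simulate_stratum(config, cond, t_sample, config$n_cells)
      })
    })
  })
  events <- purrr::map(res, function(cc)
    purrr::map(cc, "events") |> dplyr::bind_rows()) |>
    dplyr::bind_rows()
  truth_cells <- purrr::map(res, function(cc)
    purrr::map(cc, "truth") |> dplyr::bind_rows()) |>
    dplyr::bind_rows()
  truth_cells <- dplyr::bind_cols(
    events[, c("event_id", "condition", "time_h")], truth_cells)
  attr(events, "truth") <- list(
    cells = truth_cells,
    promoter = purrr::map(config$conditions, "promoter"),
    config = config,
    rng = RNGkind())
  events
}

#' Truth sidecar of a simulated experiment
#'
#' @param events The tibble returned by [simulate_experiment()].
#' @return A list: `cells` (per-cell lags, division counts, noiseless
#'   signals), `promoter` (generating parameters per condition),
#'   `config`, `rng`.
#' @export
generator_truth <- function(events) {
  truth <- attr(events, "truth")
  if (is.null(truth)) {
    stop("no truth sidecar attached; was this table made by ",
         "simulate_experiment()?", call. = FALSE)
  }
  truth
}

#' Serialize condition presets
#'
#' Presets round-trip exactly through JSON (full double precision).
#'
#' @param conditions List of [condition_spec()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presets <- function(conditions, path) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  ser <- purrr::map(conditions, function(cc) {
    out <- unclass(cc)
    out$promoter <- unclass(out$promoter)
    # named vectors must become objects, not arrays, to keep names
    for (f in c("pathway_scales", "pathway_scales_after",
                "pathway_shift_h")) {
      out[[f]] <- as.list(out[[f]])
    }
    out
  })
  names(ser) <- vapply(conditions, `[[`, character(1), "name")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # whole-number doubles come back as integers, and Inf as the string
  # "Inf" (JSON has neither type); coerce every kinetic field to double
  num <- function(x) if (is.null(x)) Inf else as.numeric(x)
  purrr::map(raw, function(cc) {
    condition_spec(
      name = cc$name, genotype = cc$genotype, peptide = cc$peptide,
      dose_nM = num(cc$dose_nM), inhibitor = cc$inhibitor,
      inhibitor_add_time_h = num(cc$inhibitor_add_time_h),
      promoter = do.call(promoter_params,
                         lapply(as.list(cc$promoter), as.numeric)),
      g_scale_after = num(cc$g_scale_after),
      switch_time = num(cc$switch_time),
      pathway_scales = vapply(cc$pathway_scales, as.numeric, 0),
      pathway_scales_after = vapply(cc$pathway_scales_after,
                                    as.numeric, 0),
      pathway_shift_h = vapply(cc$pathway_shift_h, as.numeric, 0),
      lag_mean = num(cc$lag_mean), lag_sd = num(cc$lag_sd),
      t_first_div = num(cc$t_first_div),
      div_cycle_h = num(cc$div_cycle_h),
      div_jitter_sd = num(cc$div_jitter_sd))
  })
}
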