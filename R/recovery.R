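# Pipeline self-test: generate -> summarize -> normalize -> fit ->
# compare against the generating truth.

#' End-to-end parameter recovery report
#'
#' Runs the whole pipeline on a synthetic experiment with known
#' promoter parameters: simulates events, takes the per-timepoint Blue
#' median per condition, normalizes to the experiment max
#' (percent-of-max across all conditions, so relative amplitudes are
#' preserved), fits the promoter model to each condition's timecourse,
#' and reports how well the inferred activity curves recover the truth.
#'
#' Because normalization rescales the observations by a common factor
#' `100 / max_raw`, the inferred activity is rescaled by `max_raw / 100`
#' before comparison, putting it back in the generator's units.
#'
#' @param config A [generator_config()] with known promoter parameters.
#' @param gamma Decay rate used by the inference model (default the
#'   generator's own `k_blue`, which makes the one-state model exact
#'   for the Blue channel).
#' @param pairs Optional list of `c(reference, alternative)` condition
#'   name pairs for peak-reduction comparisons.
#' @param n_starts,fit_seed Passed to [fit_promoter()].
#' @param horizon Comparison horizon, hours (default 72).
#' @return A `recovery_report` list: `per_condition` tibble (RMSE of
#'   the inferred g as percent of the true peak, peak-time error,
#'   plateau flags), `pairs` tibble (true and recovered percent peak
#'   reduction), `fits` (the `promoter_fit` objects), `summaries`.
#' @export
end_to_end_recovery <- function(config, gamma = config$k_blue,
                                pairs = NULL, n_starts = 20,
                                fit_seed = 1L, horizon = 72) {
  stopifnot(inherits(config, "generator_config"))
  events <- simulate_experiment(config)
  truth <- generator_truth(events)

  med <- events |>
    dplyr::group_by(.data$condition, .data$time_h) |>
    dplyr::summarise(mfi = stats::median(.data$blue), .groups = "drop")
  max_raw <- max(med$mfi)
  if (max_raw <= 0) stop("all Blue medians are zero", call. = FALSE)
  med$mfi_normalized <- 100 * med$mfi / max_raw

  conds <- names(config$conditions)
  decay <- timer_decay(gamma)
  fits <- purrr::map(conds, function(cn) {
    obs <- med |>
      dplyr::filter(.data$condition == cn, .data$time_h > 0) |>
      dplyr::transmute(time_h = .data$time_h,
                       value = .data$mfi_normalized)
    fit_promoter(obs, decay = decay, n_starts = n_starts,
                 seed = fit_seed)
  })
  names(fits) <- conds

  grid <- seq(0, horizon, by = 0.5)
  rescale <- max_raw / 100
  per_condition <- purrr::map(conds, function(cn) {
    p_true <- truth$promoter[[cn]]
    g_true <- promoter_activity(grid, p_true)
    pk_true <- peak_of_promoter(p_true, horizon)
    g_hat <- promoter_activity(grid, fits[[cn]]$params) * rescale
    pk_hat <- peak_of_promoter(fits[[cn]]$params, horizon)
    tibble::tibble(
      condition = cn,
      rmse_pct_peak = 100 * sqrt(mean((g_hat - g_true)^2)) /
        pk_true$g_peak,
      t_peak_true = pk_true$t_peak, t_peak_fit = pk_hat$t_peak,
      t_peak_err_h = pk_hat$t_peak - pk_true$t_peak,
      plateau_true = pk_true$plateau, plateau_fit = pk_hat$plateau,
      degenerate = fits[[cn]]$degenerate)
  }) |> dplyr::bind_rows()

  pair_tbl <- NULL
  if (!is.null(pairs)) {
    pair_tbl <- purrr::map(pairs, function(pr) {
      cmp_true <- compare_peaks(truth$promoter[[pr[1]]],
                                truth$promoter[[pr[2]]], horizon)
      cmp_fit <- compare_peaks(fits[[pr[1]]], fits[[pr[2]]], horizon)
      tibble::tibble(
        reference = pr[1], alternative = pr[2],
        percent_reduction_true = cmp_true$percent_reduction,
        percent_reduction_fit = cmp_fit$percent_reduction,
        percent_reduction_err = cmp_fit$percent_reduction -
          cmp_true$percent_reduction)
    }) |> dplyr::bind_rows()
  }

  structure(list(per_condition = per_condition, pairs = pair_tbl,
                 fits = fits, summaries = med, max_raw = max_raw,
                 gamma = decay$gamma),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> gamma =", format(x$gamma, digits = 4), "/h\n")
  print(x$per_condition)
  if (!is.null(x$pairs)) {
    cat("peak comparisons:\n")
    print(x$pairs)
  }
  invisible(x)
}
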