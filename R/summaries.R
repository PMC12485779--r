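# Flow-cytometry summary statistics for Timer event tables.
#
# Event tables are plain tibbles, one row per cell, with fluorescence
# channels as columns (e.g. blue, red, cfse, cd69) and annotation
# columns (time_h, genotype, peptide, dose_nM, inhibitor, ...). All
# summaries are grouping-driven (`by` = character vector of annotation
# columns) and permutation-invariant in the event order.
#
# Conventions, fixed package-wide:
#  * "MFI" is the MEDIAN fluorescence of the gated-positive population.
#  * positivity is strict: intensity > threshold; boundary events are
#    negative.
#  * missing denominators (no positive events, zero max) propagate as
#    NA, never as 0 or Inf.

#' Positivity gate specification
#'
#' A per-channel threshold. Events are positive when intensity is
#' *strictly greater* than the threshold.
#'
#' @param channel Channel (column) name.
#' @param threshold Threshold intensity, `>= 0`.
#' @param derivation `"manual"` or `"percentile-of-control"` (how the
#'   threshold was obtained; informational).
#' @param control_percentile Percentile used when derived from a
#'   control population, in (50, 100).
#' @return An object of class `gate_spec`.
#' @seealso [gate_from_control()]
#' @export
gate_spec <- function(channel, threshold,
                      derivation = c("manual", "percentile-of-control"),
                      control_percentile = 99) {
  derivation <- match.arg(derivation)
  stopifnot(is.character(channel), length(channel) == 1L)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  }
  if (control_percentile <= 50 || control_percentile >= 100) {
    stop("`control_percentile` must be in (50, 100)", call. = FALSE)
  }
  structure(list(channel = channel, threshold = threshold,
                 derivation = derivation,
                 control_percentile = control_percentile),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate_spec> %s > %.4g (%s)\n", x$channel, x$threshold,
              x$derivation), sep = "")
  invisible(x)
}

#' Derive a gate from a control population
#'
#' Sets the positivity threshold for a channel at a percentile
#' (default 99th) of a control population, typically the unstimulated
#' (t = 0) events.
#'
#' @param events Event tibble.
#' @param channel Channel column name.
#' @param control A logical vector over rows of `events`, or a filter
#'   expression result, marking control events. Defaults to
#'   `events$time_h == 0`.
#' @param percentile Control percentile in (50, 100), default 99.
#' @return A [gate_spec()].
#' @export
gate_from_control <- function(events, channel, control = NULL,
                              percentile = 99) {
  .check_channel(events, channel)
  if (is.null(control)) control <- events$time_h == 0
  ctrl <- events[[channel]][control]
  if (length(ctrl) == 0L) {
    stop("no control events to derive a gate from", call. = FALSE)
  }
  gate_spec(channel,
            as.numeric(stats::quantile(ctrl, percentile / 100,
                                       names = FALSE, type = 7)),
            derivation = "percentile-of-control",
            control_percentile = percentile)
}

.check_channel <- function(events, channel) {
  stopifnot(is.data.frame(events))
  if (!channel %in% names(events)) {
    stop("channel `", channel, "` not found in event table",
         call. = FALSE)
  }
  invisible(TRUE)
}

.grouped <- function(events, by) {
  if (length(by)) {
    missing <- setdiff(by, names(events))
    if (length(missing)) {
      stop("grouping columns not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    dplyr::group_by(events, dplyr::across(dplyr::all_of(by)))
  } else {
    events
  }
}

#' Percent of gate-positive events
#'
#' `100 * #(intensity > threshold) / #events` per group. Strictly
#' greater than: events at the threshold are negative.
#'
#' @param events Event tibble.
#' @param gate A [gate_spec()].
#' @param by Character vector of grouping columns (default none).
#' @return Tibble with the grouping columns, `channel`, `n_events`,
#'   `pct_positive`.
#' @export
percent_positive <- function(events, gate, by = character()) {
  stopifnot(inherits(gate, "gate_spec"))
  .check_channel(events, gate$channel)
  ch <- gate$channel; thr <- gate$threshold
  .grouped(tibble::as_tibble(events), by) |>
    dplyr::summarise(
      channel = ch,
      n_events = dplyr::n(),
      pct_positive = 100 * mean(.data[[ch]] > thr),
      .groups = "drop")
}

#' Median fluorescence of gate-positive events (MFI)
#'
#' Median intensity among events passing the gate, per group. Groups
#' with no positive events get `NA` (flagged missing, never 0).
#'
#' @inheritParams percent_positive
#' @param stat `"median"` (default, the package-wide MFI convention) or
#'   `"mean"`.
#' @return Tibble with the grouping columns, `channel`, `n_positive`,
#'   `mfi_positive`.
#' @export
mfi_positive <- function(events, gate, by = character(),
                         stat = c("median", "mean")) {
  stopifnot(inherits(gate, "gate_spec"))
  stat <- match.arg(stat)
  .check_channel(events, gate$channel)
  ch <- gate$channel; thr <- gate$threshold
  fun <- if (stat == "median") stats::median else mean
  .grouped(tibble::as_tibble(events), by) |>
    dplyr::summarise(
      channel = ch,
      n_positive = sum(.data[[ch]] > thr),
      mfi_positive = {
        pos <- .data[[ch]][.data[[ch]] > thr]
        if (length(pos)) fun(pos) else NA_real_
      },
      .groups = "drop")
}

#' Summarize an event table per condition, time and channel
#'
#' Convenience wrapper producing, for each gated channel, the percent
#' positive and MFI-of-positive per group, then normalization to the
#' experimental max ([normalize_to_experiment_max()]).
#'
#' @param events Event tibble.
#' @param gates A list of [gate_spec()] (one per channel of interest).
#' @param by Grouping columns (default `c("condition", "time_h")` if a
#'   `condition` column exists, else `"time_h"`).
#' @param scope Columns defining the "experiment" for normalization
#'   (default none: the whole table is one experiment).
#' @return A tidy tibble of summary records: grouping columns,
#'   `channel`, `n_events`, `n_positive`, `pct_positive`,
#'   `mfi_positive`, `mfi_normalized`.
#' @export
summarize_events <- function(events, gates,
                             by = intersect(c("condition", "time_h"),
                                            names(events)),
                             scope = character()) {
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  recs <- purrr::map(gates, function(g) {
    dplyr::left_join(
      percent_positive(events, g, by),
      mfi_positive(events, g, by),
      by = c(by, "channel"))
  })
  normalize_to_experiment_max(dplyr::bind_rows(recs), scope = scope)
}

#' Normalize MFI to the experimental maximum
#'
#' Within each scope group and channel, expresses MFI as percent of the
#' maximum observed MFI (`mfi_normalized = 100 * mfi / max(mfi)`); the
#' maximal record maps to exactly 100. If the in-scope max is 0 or all
#' missing, all records are flagged missing.
#'
#' @param summaries Tibble with a `channel` column and an MFI column.
#' @param scope Character vector of columns defining the experiment
#'   (default none: whole table). Channel is always part of the scope.
#' @param value_col MFI column to normalize (default `mfi_positive`).
#' @return `summaries` with an `mfi_normalized` column (replaced if
#'   present).
#' @export
normalize_to_experiment_max <- function(summaries, scope = character(),
                                        value_col = "mfi_positive") {
  stopifnot(is.data.frame(summaries))
  if (!value_col %in% names(summaries)) {
    stop("column `", value_col, "` not found", call. = FALSE)
  }
  keys <- c(scope, intersect("channel", names(summaries)))
  summaries <- tibble::as_tibble(summaries)
  summaries$mfi_normalized <- NULL
  .grouped(summaries, keys) |>
    dplyr::mutate(mfi_normalized = {
      mx <- suppressWarnings(max(.data[[value_col]], na.rm = TRUE))
      if (!is.finite(mx) || mx <= 0) NA_real_ else
        100 * .data[[value_col]] / mx
    }) |>
    dplyr::ungroup()
}

#' Late/early fold-change ratio
#'
#' Per condition and channel, the ratio of a summary value at a late
#' time to the same value at an earlier time (the 48 h / 24 h ratio in
#' Timer timecourses). Values of 1 indicate equivalent expression at
#' the two times; values below 1, reduced late expression.
#'
#' @param summaries Summary tibble with a `time_h` column.
#' @param t_num,t_den Numerator and denominator times, hours (defaults
#'   48 and 24).
#' @param value_cols Columns to form ratios of (default
#'   `mfi_positive` and `pct_positive` where present).
#' @param by Identifier columns (default: all columns except `time_h`,
#'   the value columns and counts).
#' @return Tibble with the id columns and one `ratio_<col>` per value
#'   column; missing or zero denominators give `NA`.
#' @export
fold_change_ratio <- function(summaries, t_num = 48, t_den = 24,
                              value_cols = intersect(
                                c("mfi_positive", "pct_positive",
                                  "mfi_normalized"), names(summaries)),
                              by = NULL) {
  stopifnot(is.data.frame(summaries), "time_h" %in% names(summaries))
  if (!length(value_cols)) stop("no value columns to ratio", call. = FALSE)
  # all summary-value columns are excluded from the join keys, whether
  # or not they are being ratioed
  drop <- c("time_h", value_cols, "n_events", "n_positive",
            "pct_positive", "mfi_positive", "mfi_normalized")
  if (is.null(by)) by <- setdiff(names(summaries), drop)
  num <- dplyr::filter(summaries, .data$time_h == t_num)
  den <- dplyr::filter(summaries, .data$time_h == t_den)
  if (!nrow(num) || !nrow(den)) {
    stop("both time points must be present (", t_num, " h and ",
         t_den, " h)", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(num, dplyr::all_of(c(by, value_cols))),
    dplyr::select(den, dplyr::all_of(c(by, value_cols))),
    by = by, suffix = c("_num", "_den"))
  for (vc in value_cols) {
    d <- joined[[paste0(vc, "_den")]]
    n <- joined[[paste0(vc, "_num")]]
    joined[[paste0("ratio_", vc)]] <-
      ifelse(is.na(d) | d == 0, NA_real_, n / d)
  }
  dplyr::select(joined, dplyr::all_of(by),
                dplyr::starts_with("ratio_")) |>
    tibble::as_tibble()
}

#' Genotype ratio curve
#'
#' Per time point and channel, the ratio of a summary value in one
#' genotype over the other (knockout over wild type), matched on all
#' remaining condition columns. Ratios above 1 mean higher expression
#' in the numerator genotype at that time.
#'
#' @param summaries Summary tibble with `genotype` and `time_h`.
#' @param num_genotype,den_genotype Genotype labels for numerator and
#'   denominator (defaults `"Itk_ko"` / `"Itk_wt"`).
#' @param value_col Column to ratio (default `mfi_positive`).
#' @param by Matching columns (default: all columns except `genotype`,
#'   value and count columns). Unmatched strata get `NA`.
#' @return Tibble of matched strata with `ratio` (ordered by time).
#' @export
genotype_ratio_curve <- function(summaries, num_genotype = "Itk_ko",
                                 den_genotype = "Itk_wt",
                                 value_col = "mfi_positive",
                                 by = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("genotype", "time_h") %in% names(summaries)))
  drop <- c("genotype", value_col, "n_events", "n_positive",
            "pct_positive", "mfi_positive", "mfi_normalized")
  if (is.null(by)) by <- setdiff(names(summaries), drop)
  num <- dplyr::filter(summaries, .data$genotype == num_genotype)
  den <- dplyr::filter(summaries, .data$genotype == den_genotype)
  joined <- dplyr::full_join(
    dplyr::select(num, dplyr::all_of(by), num_value = dplyr::all_of(value_col)),
    dplyr::select(den, dplyr::all_of(by), den_value = dplyr::all_of(value_col)),
    by = by)
  joined$ratio <- ifelse(
    is.na(joined$den_value) | joined$den_value == 0 |
      is.na(joined$num_value),
    NA_real_, joined$num_value / joined$den_value)
  dplyr::arrange(joined, .data$time_h) |> tibble::as_tibble()
}

#' Percent positive within an outer gate
#'
#' Percent of events passing the inner gate among those passing the
#' outer gate (e.g. Timer-Blue-positive fraction of CD69+ cells), per
#' group. Empty outer populations give `NA`.
#'
#' @param events Event tibble.
#' @param outer_gate,inner_gate [gate_spec()] objects for the parent
#'   and child gates.
#' @param by Grouping columns.
#' @return Tibble: grouping columns, `n_outer`, `n_inner`,
#'   `pct_inner_of_outer`.
#' @export
positive_fraction_within_gate <- function(events, outer_gate, inner_gate,
                                          by = character()) {
  stopifnot(inherits(outer_gate, "gate_spec"),
            inherits(inner_gate, "gate_spec"))
  .check_channel(events, outer_gate$channel)
  .check_channel(events, inner_gate$channel)
  och <- outer_gate$channel; othr <- outer_gate$threshold
  ich <- inner_gate$channel; ithr <- inner_gate$threshold
  .grouped(tibble::as_tibble(events), by) |>
    dplyr::summarise(
      n_outer = sum(.data[[och]] > othr),
      n_inner = sum(.data[[och]] > othr & .data[[ich]] > ithr),
      .groups = "drop") |>
    dplyr::mutate(pct_inner_of_outer = ifelse(
      .data$n_outer == 0, NA_real_, 100 * .data$n_inner / .data$n_outer))
}

#' Assign division counts from CFSE intensity
#'
#' CFSE halves at each division, so division-cycle centers are
#' log2-spaced below the undivided peak. Each event is assigned the
#' nearest center in log2 space: `round(log2(anchor / intensity))`,
#' clamped at 0.
#'
#' @param events Event tibble.
#' @param cfse_channel CFSE column name (default `"cfse"`).
#' @param anchor Undivided-peak intensity; default the median CFSE of
#'   the `time_h == 0` events (the unstimulated, undivided population).
#' @param max_divisions Cap on assigned divisions (default 10).
#' @return `events` with a `division_count` column (replaced if
#'   present).
#' @export
assign_divisions <- function(events, cfse_channel = "cfse",
                             anchor = NULL, max_divisions = 10L) {
  .check_channel(events, cfse_channel)
  if (is.null(anchor)) {
    ctrl <- events[[cfse_channel]][events$time_h == 0]
    if (!length(ctrl)) {
      stop("no t = 0 events; supply `anchor` explicitly", call. = FALSE)
    }
    anchor <- stats::median(ctrl)
  }
  if (!is.finite(anchor) || anchor <= 0) {
    stop("`anchor` must be positive", call. = FALSE)
  }
  x <- events[[cfse_channel]]
  n <- round(log2(anchor / pmax(x, .Machine$double.eps)))
  events$division_count <- pmin(pmax(as.integer(n), 0L),
                                as.integer(max_divisions))
  tibble::as_tibble(events)
}

#' Per-division-cycle normalized MFI
#'
#' For events at one time point, the median intensity of a channel per
#' division cycle, normalized to the maximum median across divisions at
#' that time (percent of experimental max at the queried time).
#' Divisions with fewer than `min_n` events are flagged `low_n`.
#'
#' @param events Event tibble with a `division_count` column (from the
#'   generator truth or [assign_divisions()]).
#' @param channel Channel to summarize (default `"blue"`).
#' @param at_time Time point to analyze, hours (default 48).
#' @param by Extra grouping columns (e.g. `"condition"`); normalization
#'   is per group.
#' @param min_n Low-count flag threshold (default 20 events).
#' @return Tibble: grouping columns, `division_count`, `n_events`,
#'   `mfi`, `mfi_normalized`, `low_n`.
#' @export
division_cycle_summary <- function(events, channel = "blue",
                                   at_time = 48, by = character(),
                                   min_n = 20L) {
  .check_channel(events, channel)
  if (!"division_count" %in% names(events)) {
    stop("`events` needs a `division_count` column ",
         "(see assign_divisions())", call. = FALSE)
  }
  sub <- dplyr::filter(tibble::as_tibble(events),
                       .data$time_h == at_time)
  if (!nrow(sub)) stop("no events at time ", at_time, " h", call. = FALSE)
  out <- .grouped(sub, c(by, "division_count")) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mfi = stats::median(.data[[channel]]),
                     .groups = "drop")
  out <- .grouped(out, by) |>
    dplyr::mutate(mfi_normalized = {
      mx <- max(.data$mfi)
      if (mx <= 0) NA_real_ else 100 * .data$mfi / mx
    }) |>
    dplyr::ungroup()
  out$low_n <- out$n_events < min_n
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)),
                 .data$division_count)
}

#' Pseudo-time binning on Timer Blue levels
#'
#' Orders cells by increasing Blue intensity as a proxy for time since
#' signaling onset: events are partitioned into half-open,
#' lower-inclusive bins `[e1, e2), [e2, e3), ...` on the Blue channel
#' (the last bin is `[e_last, Inf)`), and each target channel is
#' summarized per bin (median, percent-of-max normalized median, and
#' percent positive when gates are supplied).
#'
#' @param events Event tibble.
#' @param blue_channel Blue column name (default `"blue"`).
#' @param bin_edges Increasing vector of Blue levels (>= 2 edges).
#' @param target_channels Channels to summarize per bin.
#' @param gates Optional named list of [gate_spec()] per target channel
#'   for percent-positive.
#' @param by Extra grouping columns.
#' @return Tibble: grouping columns, `bin` (ordered factor label),
#'   `bin_lower`, `channel`, `n_events`, `mfi`, `mfi_normalized`, and
#'   `pct_positive` when gates are given. Empty bins appear with `NA`
#'   summaries, ordering preserved.
#' @export
pseudo_time_bins <- function(events, blue_channel = "blue", bin_edges,
                             target_channels, gates = NULL,
                             by = character()) {
  .check_channel(events, blue_channel)
  for (ch in target_channels) .check_channel(events, ch)
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be >= 2 strictly increasing values",
         call. = FALSE)
  }
  edges <- c(bin_edges, Inf)
  labels <- paste0("[", format(edges[-length(edges)], trim = TRUE), ",",
                   format(edges[-1], trim = TRUE), ")")
  ev <- tibble::as_tibble(events)
  ev$bin <- cut(ev[[blue_channel]], breaks = edges, labels = labels,
                right = FALSE, include.lowest = FALSE)
  ev <- dplyr::filter(ev, !is.na(.data$bin)) # below the first edge: out of range
  long <- purrr::map(target_channels, function(ch) {
    s <- .grouped(ev, c(by, "bin")) |>
      dplyr::summarise(channel = ch, n_events = dplyr::n(),
                       mfi = stats::median(.data[[ch]]),
                       pct_positive = if (!is.null(gates) &&
                                          !is.null(gates[[ch]]))
                         100 * mean(.data[[ch]] > gates[[ch]]$threshold)
                       else NA_real_,
                       .groups = "drop")
    s
  }) |> dplyr::bind_rows()
  # materialize empty bins, per group x channel, preserving order
  long <- tidyr::complete(
    long, tidyr::nesting(!!!rlang::syms(c(by, "channel"))),
    bin = factor(labels, levels = labels),
    fill = list(n_events = 0L))
  long$bin <- factor(long$bin, levels = labels, ordered = TRUE)
  long$bin_lower <- bin_edges[as.integer(long$bin)]
  long <- .grouped(long, c(by, "channel")) |>
    dplyr::mutate(mfi_normalized = {
      mx <- suppressWarnings(max(.data$mfi, na.rm = TRUE))
      if (!is.finite(mx) || mx <= 0) NA_real_ else 100 * .data$mfi / mx
    }) |>
    dplyr::ungroup()
  dplyr::arrange(long, dplyr::across(dplyr::all_of(c(by, "channel"))),
                 .data$bin)
}
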