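#' Detect supra-threshold calcium events
#'
#' A Ca2+ event is a maximal run of consecutive frames with
#' `dff_pct > threshold_pct` (strict inequality, "above x%"). The onset is
#' the time of the first supra-threshold frame; the offset is one sampling
#' interval after the last, so intervals are half-open `[onset, offset)`.
#' No minimum duration, hysteresis or refractory period is applied.
#'
#' @param dff A dF/F0 tibble from [compute_dff()] (one larva or a cohort).
#' @param threshold_pct Detection threshold in percent dF/F0.
#' @return A tibble with one row per event: `larva_id`, `group`,
#'   `onset_s`, `offset_s`, `peak_time_s`, `amplitude_pct`, `duration_s`,
#'   `detect_threshold_pct`, `truncated` (event touches a recording edge).
#'   Events are ordered by larva then onset; zero rows when nothing
#'   crosses the threshold.
#' @examples
#' rec <- new_recording(c(rep(100, 20), rep(108, 8), rep(100, 20)),
#'                      "fish01", sampling_rate_hz = 1)
#' detect_events(compute_dff(rec, window_s = 40), threshold_pct = 5)
#' @export
detect_events <- function(dff, threshold_pct) {
  stopifnot(is.numeric(threshold_pct), threshold_pct > 0)
  check_recording_cols(dff, "dff_pct")
  dff |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::group_modify(function(d, key) {
      runs <- supra_runs(d$dff_pct, d$time_s, d$sampling_rate_hz[1], threshold_pct)
      if (nrow(runs) == 0) return(empty_events())
      tibble(
        group = d$group[1],
        onset_s = runs$onset_s,
        offset_s = runs$offset_s,
        peak_time_s = runs$peak_time_s,
        amplitude_pct = runs$amplitude_pct,
        duration_s = runs$offset_s - runs$onset_s,
        detect_threshold_pct = threshold_pct,
        truncated = runs$truncated_start | runs$truncated_end
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$larva_id, .data$onset_s)
}

# Maximal runs of x > threshold on a uniform time grid; offsets are one
# sampling interval past the last supra-threshold frame (half-open).
supra_runs <- function(x, time_s, fs, threshold) {
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(tibble(start_idx = integer(), end_idx = integer(),
                  onset_s = numeric(), offset_s = numeric(),
                  peak_idx = integer(), peak_time_s = numeric(),
                  amplitude_pct = numeric(),
                  truncated_start = logical(), truncated_end = logical()))
  }
  dt <- 1 / fs
  n <- length(x)
  s <- starts[keep]
  e <- ends[keep]
  peak <- purrr::map2_int(s, e, function(a, b) a + which.max(x[a:b]) - 1L)
  tibble(
    start_idx = s, end_idx = e,
    onset_s = time_s[s],
    offset_s = time_s[e] + dt,
    peak_idx = peak,
    peak_time_s = time_s[peak],
    amplitude_pct = x[peak],
    truncated_start = s == 1L,
    truncated_end = e == n
  )
}

empty_events <- function() {
  tibble(group = character(), onset_s = numeric(), offset_s = numeric(),
         peak_time_s = numeric(), amplitude_pct = numeric(),
         duration_s = numeric(), detect_threshold_pct = numeric(),
         truncated = logical())
}

#' Classify events into detection tiers
#'
#' Runs event detection at each tier threshold (default 5% and 10%
#' dF/F0). The default `"cumulative"` semantics matches "events above x%":
#' detection is re-run per tier, so a 12% transient appears in both the
#' >5% and >10% tiers and tier counts are nested. The `"band"` mode
#' instead assigns each event detected at the lowest tier to the
#' amplitude band it peaks in (e.g. \[5, 10) and \[10, Inf)), for
#' sensitivity analyses.
#'
#' @inheritParams detect_events
#' @param tiers Ascending tier thresholds in percent dF/F0.
#' @param mode `"cumulative"` (default) or `"band"`.
#' @return Event tibble as in [detect_events()] with a `tier` column
#'   (the tier's threshold, as numeric).
#' @export
classify_tiers <- function(dff, tiers = c(5, 10),
                           mode = c("cumulative", "band")) {
  mode <- match.arg(mode)
  stopifnot(length(tiers) >= 1, all(tiers > 0))
  if (is.unsorted(tiers, strictly = TRUE)) abort("`tiers` must be strictly ascending.")

  if (mode == "cumulative") {
    purrr::map_dfr(tiers, function(thr) {
      detect_events(dff, thr) |> dplyr::mutate(tier = thr, .before = "onset_s")
    })
  } else {
    ev <- detect_events(dff, tiers[1])
    band_of <- function(a) tiers[findInterval(a, tiers)]
    ev |>
      dplyr::mutate(tier = band_of(.data$amplitude_pct), .before = "onset_s")
  }
}

#' Remove seizure-like events from an event table
#'
#' The hypoactivity analysis of seizure-model recordings excludes events
#' that are both large and long: amplitude above `amp_pct` (default 50%
#' dF/F0) and duration above `dur_s` (default 20 s). The published rule
#' is the conjunction; `rule = "or"` removes events satisfying either
#' condition.
#'
#' @param events Event tibble from [detect_events()] / [classify_tiers()].
#' @param amp_pct,dur_s Exclusion thresholds.
#' @param rule `"and"` (default) or `"or"`.
#' @return The event tibble without the excluded rows.
#' @export
exclude_seizure_like <- function(events, amp_pct = 50, dur_s = 20,
                                 rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(amp_pct > 0, dur_s > 0)
  big <- events$amplitude_pct > amp_pct
  long <- events$duration_s > dur_s
  drop <- if (rule == "and") big & long else big | long
  events[!drop, , drop = FALSE]
}

#' Area under the dF/F0 curve
#'
#' Trapezoidal integral of percent dF/F0 over time (units %*s), per
#' larva. By default the whole trace is integrated; with `windows` the
#' integral is computed inside each `[start, end)` window and the
#' per-window values are averaged (the protocol used for interictal
#' activity of seizure-model larvae: two 5 min windows per animal).
#'
#' @inheritParams detect_events
#' @param windows Optional list of `c(start, end)` intervals in seconds.
#' @return Tibble with `larva_id`, `group`, `auc_pct_s`.
#' @examples
#' rec <- new_recording(rep(100, 61), "fish01", sampling_rate_hz = 1)
#' dff <- compute_dff(rec, window_s = 30)
#' dff$dff_pct <- 10  # constant 10% for 60 s
#' compute_auc(dff)   # 600 %*s
#' @export
compute_auc <- function(dff, windows = NULL) {
  check_recording_cols(dff, "dff_pct")
  if (!is.null(windows)) {
    ok <- is.list(windows) && length(windows) > 0 &&
      all(vapply(windows, function(w) length(w) == 2 && w[1] < w[2], logical(1)))
    if (!ok) abort("`windows` must be a non-empty list of c(start, end) with start < end.")
  }
  dff |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::group_modify(function(d, key) {
      auc <- if (is.null(windows)) {
        pracma::trapz(d$time_s, d$dff_pct)
      } else {
        span <- range(d$time_s)
        vals <- vapply(windows, function(w) {
          if (w[1] < span[1] || w[2] > span[2] + 1 / d$sampling_rate_hz[1]) {
            abort(sprintf("Window [%g, %g) outside recording span [%g, %g].",
                          w[1], w[2], span[1], span[2]))
          }
          sel <- d$time_s >= w[1] & d$time_s < w[2]
          if (sum(sel) < 2) return(0)
          pracma::trapz(d$time_s[sel], d$dff_pct[sel])
        }, numeric(1))
        mean(vals)
      }
      tibble(group = d$group[1], auc_pct_s = auc)
    }) |>
    dplyr::ungroup()
}

#' Per-larva activity summaries
#'
#' Aggregates tiered events into per-larva, per-tier counts, mean
#' amplitudes and mean durations, joins the AUC, and normalizes AUC to
#' the control-group mean. Larvae present in `auc` but without events at
#' a tier get a count of 0 and missing amplitude/duration (means over an
#' empty set are undefined, not zero).
#'
#' @param events Tiered event tibble from [classify_tiers()].
#' @param auc Per-larva AUC tibble from [compute_auc()].
#' @param control_group Group label used for AUC normalization.
#' @return Tibble with one row per larva x tier: `larva_id`, `group`,
#'   `tier`, `event_count`, `mean_amplitude_pct`, `mean_duration_s`,
#'   `auc_pct_s`, `auc_normalized`.
#' @export
summarize_larvae <- function(events, auc, control_group = "control") {
  stopifnot(all(c("larva_id", "group", "auc_pct_s") %in% names(auc)))
  if (!"tier" %in% names(events)) {
    events <- dplyr::mutate(events, tier = .data$detect_threshold_pct)
  }
  ctrl <- auc$auc_pct_s[auc$group == control_group]
  if (length(ctrl) == 0) abort(paste0("No larvae in control group '", control_group, "'."))
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean == 0) {
    abort("Control AUC mean is zero or non-finite; cannot normalize.")
  }

  tiers <- sort(unique(events$tier))
  if (length(tiers) == 0) tiers <- NA_real_
  roster <- tidyr::expand_grid(auc, tier = tiers)

  per <- events |>
    dplyr::group_by(.data$larva_id, .data$tier) |>
    dplyr::summarise(
      event_count = dplyr::n(),
      mean_amplitude_pct = mean(.data$amplitude_pct),
      mean_duration_s = mean(.data$duration_s),
      .groups = "drop"
    )

  roster |>
    dplyr::left_join(per, by = c("larva_id", "tier")) |>
    dplyr::mutate(
      event_count = dplyr::coalesce(.data$event_count, 0L),
      auc_normalized = .data$auc_pct_s / ctrl_mean
    ) |>
    dplyr::select("larva_id", "group", "tier", "event_count",
                  "mean_amplitude_pct", "mean_duration_s",
                  "auc_pct_s", "auc_normalized") |>
    dplyr::arrange(.data$larva_id, .data$tier)
}
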