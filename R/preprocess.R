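#' Moving-window percentile baseline
#'
#' Estimates the slowly varying baseline F0 of a raw fluorescence trace as
#' a low percentile (default the 1st) of the fluorescence values inside a
#' moving time window (default 150 s; 300 s for seizure-model recordings).
#' The window is centered on each frame and truncated at the recording
#' edges, so no data are fabricated at the boundaries; a trailing window
#' is available via `align = "trailing"`. Percentiles use the
#' linear-interpolation (type 7) definition.
#'
#' Works on a single recording or on a cohort tibble containing several
#' larvae (grouped internally by `larva_id`).
#'
#' @param recording A recording tibble from [new_recording()] /
#'   [read_recording()], or several bound together.
#' @param window_s Window width in seconds. Must cover at least two
#'   frames. If it exceeds the recording length the whole-trace
#'   percentile is used, with a warning.
#' @param percentile Percentile in (0, 100] of the in-window fluorescence
#'   taken as F0.
#' @param align `"centered"` or `"trailing"` window placement.
#' @return The input tibble with a per-frame `f0` column appended.
#' @seealso [compute_dff()]
#' @export
estimate_baseline <- function(recording, window_s = 150, percentile = 1,
                              align = c("centered", "trailing")) {
  align <- match.arg(align)
  stopifnot(is.numeric(window_s), window_s > 0,
            is.numeric(percentile), percentile > 0, percentile <= 100)
  check_recording_cols(recording, "f")

  recording |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::group_modify(function(d, key) {
      fs <- d$sampling_rate_hz[1]
      if (window_s < 2 / fs) {
        abort("`window_s` must cover at least two frames.")
      }
      n <- nrow(d)
      w_frames <- round(window_s * fs)
      if (w_frames >= n) {
        warn(sprintf("Baseline window (%g s) exceeds recording '%s' (%g s); using global percentile.",
                     window_s, key$larva_id[[1]], n / fs))
      }
      if (align == "centered") {
        half <- as.integer(round(window_s * fs / 2))
        f0 <- roll_quantile_cpp(d$f, half, percentile / 100)
      } else {
        before <- as.integer(max(round(window_s * fs) - 1, 1))
        f0 <- roll_quantile_trailing_cpp(d$f, before, percentile / 100)
      }
      if (any(f0 <= 0)) {
        abort("Baseline is non-positive in at least one window; dF/F0 is undefined for this trace.")
      }
      d$f0 <- f0
      d
    }) |>
    dplyr::ungroup()
}

#' Fractional change in fluorescence (dF/F0)
#'
#' Converts raw fluorescence to percent dF/F0 against the moving-window
#' percentile baseline: `dff_pct = 100 * (f - f0) / f0`. If the baseline
#' has not been computed yet it is estimated first with the given
#' parameters.
#'
#' @inheritParams estimate_baseline
#' @return The input tibble with `f0` (if absent) and `dff_pct` columns,
#'   plus a `baseline_window_s` column recording the window used.
#' @examples
#' rec <- new_recording(rep(c(100, 100, 150, 100), 25), "fish01", sampling_rate_hz = 1)
#' dff <- compute_dff(rec, window_s = 20)
#' max(dff$dff_pct)  # 50% transient
#' @export
compute_dff <- function(recording, window_s = 150, percentile = 1,
                        align = c("centered", "trailing")) {
  align <- match.arg(align)
  if (!"f0" %in% names(recording)) {
    recording <- estimate_baseline(recording, window_s = window_s,
                                   percentile = percentile, align = align)
  }
  if (any(recording$f0 <= 0)) abort("Baseline must be strictly positive.")
  recording |>
    dplyr::mutate(dff_pct = 100 * (.data$f - .data$f0) / .data$f0,
                  baseline_window_s = window_s)
}

check_recording_cols <- function(x, ..., caller = sys.call(-1)) {
  need <- c("larva_id", "time_s", "sampling_rate_hz", ...)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Input is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  invisible(x)
}
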