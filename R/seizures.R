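#' Detect calcium seizures
#'
#' A seizure is a calcium fluctuation whose peak reaches at least
#' `peak_pct` (default 100%) dF/F0, bounded by the `boundary_pct`
#' (default 50%) crossings: onset is the first frame with
#' `dff_pct > boundary_pct`, offset the first subsequent frame below it.
#' Candidate runs that reach the end of the trace still above the
#' boundary are kept and flagged `truncated`, with offset at the trace
#' end; truncated seizures count toward seizure numbers but are usually
#' dropped from duration statistics.
#'
#' @inheritParams detect_events
#' @param boundary_pct Seizure initiation/termination threshold (percent
#'   dF/F0).
#' @param peak_pct Minimum peak dF/F0 (percent); the "at least" rule is
#'   inclusive.
#' @param align_fraction Fraction of the maximum used for the alignment
#'   time (`align_time_s` = first frame at or above
#'   `align_fraction * amplitude`).
#' @return Tibble with one row per seizure: `larva_id`, `group`,
#'   `onset_s`, `offset_s`, `duration_s`, `amplitude_pct`, `peak_time_s`,
#'   `align_time_s`, `truncated`.
#' @export
detect_seizures <- function(dff, boundary_pct = 50, peak_pct = 100,
                            align_fraction = 0.5) {
  stopifnot(boundary_pct > 0, peak_pct > boundary_pct,
            align_fraction > 0, align_fraction <= 1)
  check_recording_cols(dff, "dff_pct")
  dff |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::group_modify(function(d, key) {
      runs <- supra_runs(d$dff_pct, d$time_s, d$sampling_rate_hz[1], boundary_pct)
      runs <- runs[runs$amplitude_pct >= peak_pct, , drop = FALSE]
      if (nrow(runs) == 0) return(empty_seizures())
      align_t <- purrr::pmap_dbl(
        list(runs$start_idx, runs$end_idx, runs$amplitude_pct),
        function(a, b, amp) {
          i <- a + which(d$dff_pct[a:b] >= align_fraction * amp)[1] - 1L
          d$time_s[i]
        }
      )
      tibble(
        group = d$group[1],
        onset_s = runs$onset_s,
        offset_s = runs$offset_s,
        duration_s = runs$offset_s - runs$onset_s,
        amplitude_pct = runs$amplitude_pct,
        peak_time_s = runs$peak_time_s,
        align_time_s = align_t,
        truncated = runs$truncated_end
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$larva_id, .data$onset_s)
}

empty_seizures <- function() {
  tibble(group = character(), onset_s = numeric(), offset_s = numeric(),
         duration_s = numeric(), amplitude_pct = numeric(),
         peak_time_s = numeric(), align_time_s = numeric(),
         truncated = logical())
}

#' Align seizures at a fraction of their maximum
#'
#' Extracts, for every seizure, the dF/F0 segment around its alignment
#' point (the first frame at or above `align_fraction` of the seizure's
#' maximum; 50% in the published overlays) onto a common time grid
#' `[-pre_s, post_s)`, padding with `NA` where the recording does not
#' extend that far. The per-timepoint mean and SEM over the available
#' traces give the averaged seizure waveform.
#'
#' @param seizures Seizure tibble from [detect_seizures()].
#' @param dff The dF/F0 tibble the seizures were detected in (all larvae
#'   must share one sampling rate).
#' @param align_fraction Fraction of the maximum for the alignment point.
#' @param pre_s,post_s Seconds of trace before/after the alignment point.
#' @return An object of class `"aligned_seizures"`: a list with
#'   `time_s` (grid relative to the alignment point), `traces`
#'   (seizure x time matrix), `mean_trace`, `sem_trace`, and `seizures`
#'   (the input rows plus `seizure_id`). Use [tidy()] for a long tibble,
#'   [seizure_metrics()] for per-seizure AUC and time to peak, and
#'   [autoplot()] for the mean +/- SEM overlay.
#' @export
align_seizures <- function(seizures, dff, align_fraction = 0.5,
                           pre_s = 0, post_s = 400) {
  stopifnot(align_fraction > 0, align_fraction <= 1, pre_s >= 0, post_s >= 0)
  if (nrow(seizures) == 0) abort("No seizures to align.")
  check_recording_cols(dff, "dff_pct")
  fs <- unique(dff$sampling_rate_hz)
  if (length(fs) != 1) abort("All recordings must share one sampling rate for alignment.")
  dt <- 1 / fs
  n_pre <- as.integer(round(pre_s * fs))
  n_post <- as.integer(round(post_s * fs))
  if (n_pre + n_post < 1) abort("Alignment window contains no frames.")
  grid <- (seq_len(n_pre + n_post) - n_pre - 1) * dt

  by_larva <- split(dff, dff$larva_id)
  segs <- purrr::pmap(
    list(seizures$larva_id, seizures$onset_s, seizures$offset_s,
         seizures$amplitude_pct),
    function(id, onset, offset, amp) {
      d <- by_larva[[id]]
      sel <- which(d$time_s >= onset - dt / 2 & d$time_s < offset - dt / 2)
      i_align <- sel[which(d$dff_pct[sel] >= align_fraction * amp)[1]]
      idx <- i_align + seq(-n_pre, n_post - 1L)
      out <- rep(NA_real_, length(idx))
      ok <- idx >= 1 & idx <= nrow(d)
      out[ok] <- d$dff_pct[idx[ok]]
      out
    }
  )
  traces <- do.call(rbind, segs)
  rownames(traces) <- sprintf("seizure_%03d", seq_len(nrow(traces)))

  n_avail <- colSums(!is.na(traces))
  mean_trace <- ifelse(n_avail > 0, colMeans(traces, na.rm = TRUE), NA_real_)
  sd_trace <- apply(traces, 2, sd, na.rm = TRUE)
  sem_trace <- ifelse(n_avail > 1, sd_trace / sqrt(n_avail),
                      ifelse(n_avail == 1, 0, NA_real_))

  structure(
    list(
      time_s = grid,
      traces = traces,
      mean_trace = as.numeric(mean_trace),
      sem_trace = as.numeric(sem_trace),
      n_traces = nrow(traces),
      align_fraction = align_fraction,
      pre_s = pre_s, post_s = post_s,
      sampling_rate_hz = fs,
      seizures = dplyr::mutate(seizures, seizure_id = rownames(traces),
                               .before = 1)
    ),
    class = "aligned_seizures"
  )
}

#' @export
print.aligned_seizures <- function(x, ...) {
  cat(sprintf("<aligned_seizures> %d seizure(s), grid [%.1f, %.1f) s @ %.2f Hz, aligned at %.0f%% of max\n",
              x$n_traces, min(x$time_s), max(x$time_s) + 1 / x$sampling_rate_hz,
              x$sampling_rate_hz, 100 * x$align_fraction))
  invisible(x)
}

#' @describeIn align_seizures Long tibble of the aligned traces
#'   (`seizure_id`, `larva_id`, `time_s`, `dff_pct`).
#' @param x An `aligned_seizures` object.
#' @param ... Unused.
#' @export
tidy.aligned_seizures <- function(x, ...) {
  ids <- x$seizures$seizure_id
  larvae <- setNames(x$seizures$larva_id, ids)
  tibble(
    seizure_id = rep(ids, each = length(x$time_s)),
    larva_id = unname(larvae[rep(ids, each = length(x$time_s))]),
    time_s = rep(x$time_s, times = length(ids)),
    dff_pct = as.vector(t(x$traces))
  )
}

#' @describeIn align_seizures One-row overview (number of seizures, grid
#'   extent, alignment fraction).
#' @export
glance.aligned_seizures <- function(x, ...) {
  tibble(
    n_seizures = x$n_traces,
    n_larvae = length(unique(x$seizures$larva_id)),
    pre_s = x$pre_s, post_s = x$post_s,
    align_fraction = x$align_fraction,
    sampling_rate_hz = x$sampling_rate_hz
  )
}

#' Per-seizure AUC and time to peak
#'
#' Computes, from the beginning of each aligned seizure segment, the
#' trapezoidal area under the dF/F0 curve (missing padding contributes 0)
#' and the time to peak (time from segment start to the maximum dF/F0).
#' Optionally normalizes AUC to the mean of a set of control-seizure
#' AUCs.
#'
#' @param aligned An `aligned_seizures` object.
#' @param control_aucs Optional numeric vector of control AUCs; when
#'   given, an `auc_normalized` column is added.
#' @return The aligned object's `seizures` tibble with `auc_pct_s` and
#'   `time_to_peak_s` columns (and `auc_normalized` if requested).
#' @export
seizure_metrics <- function(aligned, control_aucs = NULL) {
  stopifnot(inherits(aligned, "aligned_seizures"))
  t_rel <- aligned$time_s
  res <- purrr::map_dfr(seq_len(aligned$n_traces), function(i) {
    y <- aligned$traces[i, ]
    if (all(is.na(y))) abort("Aligned segment is entirely missing.")
    y0 <- ifelse(is.na(y), 0, y)
    peak_i <- which.max(ifelse(is.na(y), -Inf, y))
    tibble(
      auc_pct_s = pracma::trapz(t_rel, y0),
      time_to_peak_s = t_rel[peak_i] - t_rel[1]
    )
  })
  out <- dplyr::bind_cols(aligned$seizures, res)
  if (!is.null(control_aucs)) {
    m <- mean(control_aucs)
    if (!is.finite(m) || m == 0) abort("Control AUC mean is zero or non-finite.")
    out$auc_normalized <- out$auc_pct_s / m
  }
  out
}

#' Fraction of larvae exhibiting seizures
#'
#' Percentage of larvae with at least one detected seizure, rounded to
#' the reporting precision.
#'
#' @param n_seizing Number of larvae with >= 1 seizure.
#' @param n_total Total number of larvae (> 0).
#' @param digits Decimal places for reporting (2 by default).
#' @return Percentage in \[0, 100\].
#' @examples
#' seizing_fraction(12, 21)            # 57.14
#' seizing_fraction(6, 38, digits = 1) # 15.8
#' @export
seizing_fraction <- function(n_seizing, n_total, digits = 2) {
  if (n_total <= 0) abort("`n_total` must be positive.")
  if (n_seizing < 0 || n_seizing > n_total) {
    abort("`n_seizing` must lie in [0, n_total].")
  }
  round(100 * n_seizing / n_total, digits)
}
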