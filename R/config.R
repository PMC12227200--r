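#' Analysis configuration
#'
#' Collects the tunable parameters of the whole-brain calcium-imaging
#' pipeline in one validated list. Defaults follow the published analysis
#' workflow for larval zebrafish wide-field recordings: a 150 s
#' moving-window 1st-percentile baseline (300 s for seizure-model
#' recordings), event tiers at 5% and 10% dF/F0, the hypoactivity
#' seizure-exclusion filter (amplitude > 50% AND duration > 20 s), a
#' 100% dF/F0 seizure peak threshold with 50% boundaries, and seizure
#' alignment at 50% of the maximum.
#'
#' @param baseline_window_s Width (s) of the moving baseline window.
#'   150 for normal brain activity, 300 for seizure-model analysis.
#' @param baseline_percentile Percentile (in (0, 100]) of fluorescence
#'   within the window taken as the baseline F0. Default 1.
#' @param baseline_align `"centered"` (window centered on the frame,
#'   truncated at the recording edges) or `"trailing"` (window ending at
#'   the frame).
#' @param event_thresholds_pct Ascending event-detection tiers in
#'   percent dF/F0. Default `c(5, 10)`.
#' @param tier_mode `"cumulative"` ("above x%" semantics, detection re-run
#'   per tier) or `"band"` (exclusive amplitude bands, e.g. \[5, 10)).
#' @param seizure_peak_threshold_pct Minimum peak dF/F0 (percent) for an
#'   excursion to count as a seizure. Default 100.
#' @param seizure_boundary_threshold_pct dF/F0 level (percent) defining
#'   seizure initiation and termination. Default 50.
#' @param exclusion_apply Apply the seizure-exclusion filter to events
#'   before summarising activity? Default `FALSE` (used for
#'   hypoactivity analysis of seizure-model recordings).
#' @param exclusion_amp_pct,exclusion_dur_s Exclusion-filter thresholds:
#'   events with amplitude above `exclusion_amp_pct` and duration above
#'   `exclusion_dur_s` are removed. Defaults 50% and 20 s.
#' @param exclusion_rule `"and"` (both conditions required; the published
#'   rule) or `"or"`.
#' @param auc_windows Optional list of `c(start, end)` second intervals;
#'   when given, the area under the curve is averaged over these windows
#'   instead of integrating the whole trace.
#' @param align_fraction Fraction of a seizure's maximum dF/F0 at which
#'   seizures are aligned. Default 0.5.
#' @param align_pre_s,align_post_s Seconds of trace kept before/after the
#'   alignment point. Defaults 0 and 400 (long enough for multi-minute
#'   seizures).
#' @param rng_seed Integer seed recorded into run manifests.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(baseline_window_s = 300)
#' cfg$event_thresholds_pct
#' @export
pipeline_config <- function(baseline_window_s = 150,
                            baseline_percentile = 1,
                            baseline_align = c("centered", "trailing"),
                            event_thresholds_pct = c(5, 10),
                            tier_mode = c("cumulative", "band"),
                            seizure_peak_threshold_pct = 100,
                            seizure_boundary_threshold_pct = 50,
                            exclusion_apply = FALSE,
                            exclusion_amp_pct = 50,
                            exclusion_dur_s = 20,
                            exclusion_rule = c("and", "or"),
                            auc_windows = NULL,
                            align_fraction = 0.5,
                            align_pre_s = 0,
                            align_post_s = 400,
                            rng_seed = 1L) {
  baseline_align <- match.arg(baseline_align)
  tier_mode <- match.arg(tier_mode)
  exclusion_rule <- match.arg(exclusion_rule)

  stopifnot(
    is.numeric(baseline_window_s), baseline_window_s > 0,
    is.numeric(baseline_percentile),
    baseline_percentile > 0, baseline_percentile <= 100,
    is.numeric(event_thresholds_pct), length(event_thresholds_pct) >= 1,
    is.numeric(seizure_peak_threshold_pct), seizure_peak_threshold_pct > 0,
    is.numeric(seizure_boundary_threshold_pct),
    is.numeric(align_fraction), align_fraction > 0, align_fraction <= 1,
    align_pre_s >= 0, align_post_s >= 0
  )
  if (any(event_thresholds_pct <= 0) || is.unsorted(event_thresholds_pct, strictly = TRUE)) {
    abort("`event_thresholds_pct` must be strictly positive and strictly ascending.")
  }
  if (seizure_boundary_threshold_pct >= seizure_peak_threshold_pct) {
    abort("`seizure_boundary_threshold_pct` must be below `seizure_peak_threshold_pct`.")
  }
  if (!is.null(auc_windows)) {
    ok <- is.list(auc_windows) && length(auc_windows) > 0 &&
      all(vapply(auc_windows, function(w) length(w) == 2 && w[1] < w[2], logical(1)))
    if (!ok) abort("`auc_windows` must be a non-empty list of c(start, end) with start < end.")
  }

  structure(
    list(
      baseline_window_s = baseline_window_s,
      baseline_percentile = baseline_percentile,
      baseline_align = baseline_align,
      event_thresholds_pct = event_thresholds_pct,
      tier_mode = tier_mode,
      seizure_peak_threshold_pct = seizure_peak_threshold_pct,
      seizure_boundary_threshold_pct = seizure_boundary_threshold_pct,
      exclusion_apply = isTRUE(exclusion_apply),
      exclusion_amp_pct = exclusion_amp_pct,
      exclusion_dur_s = exclusion_dur_s,
      exclusion_rule = exclusion_rule,
      auc_windows = auc_windows,
      align_fraction = align_fraction,
      align_pre_s = align_pre_s,
      align_post_s = align_post_s,
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val)) val <- "NULL"
    if (is.list(val)) val <- paste(vapply(val, function(w) paste(w, collapse = "-"), ""), collapse = ", ")
    cat(sprintf("  %-32s %s\n", nm, paste(format(val), collapse = ", ")))
  }
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML keys mirror the [pipeline_config()] argument names, so a config
#' file is a reproducible snapshot of an analysis run.
#'
#' @param path File path.
#' @param config A `pipeline_config` object.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$auc_windows)) {
    raw$auc_windows <- lapply(raw$auc_windows, unlist)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  if (!is.null(out$auc_windows)) out$auc_windows <- lapply(out$auc_windows, as.numeric)
  yaml::write_yaml(out, path)
  invisible(path)
}
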