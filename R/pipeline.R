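#' End-to-end activity analysis of a cohort
#'
#' Runs the interictal/baseline-activity workflow on a cohort of
#' recordings: dF/F0 against the moving-percentile baseline, tiered
#' event detection (optionally with the seizure-exclusion filter),
#' per-larva summaries with control-normalized AUC, rank-sum tests on
#' mean amplitude, mean duration and AUC per tier, and a
#' negative-binomial model on event counts per tier. Deterministic given
#' its inputs.
#'
#' @param recordings Cohort tibble (recordings bound together; at least
#'   two groups).
#' @param config A [pipeline_config()].
#' @param control_group Reference group for normalization and effects.
#' @return List of class `"ca_run"` with `summaries` (per larva x tier),
#'   `events`, `comparisons` (tidied test results, one row per tier x
#'   measure), and `manifest`.
#' @export
run_activity_analysis <- function(recordings, config = pipeline_config(),
                                  control_group = "control") {
  stopifnot(inherits(config, "pipeline_config"))
  groups <- unique(recordings$group)
  if (length(groups) < 2) abort("Activity analysis needs at least two groups.")
  if (!control_group %in% groups) {
    abort(paste0("Control group '", control_group, "' absent from cohort."))
  }

  dff <- compute_dff(recordings, window_s = config$baseline_window_s,
                     percentile = config$baseline_percentile,
                     align = config$baseline_align)
  events <- classify_tiers(dff, tiers = config$event_thresholds_pct,
                           mode = config$tier_mode)
  if (config$exclusion_apply) {
    events <- exclude_seizure_like(events, amp_pct = config$exclusion_amp_pct,
                                   dur_s = config$exclusion_dur_s,
                                   rule = config$exclusion_rule)
  }
  auc <- compute_auc(dff, windows = config$auc_windows)
  summaries <- summarize_larvae(events, auc, control_group = control_group)

  comparisons <- purrr::map_dfr(sort(unique(summaries$tier)), function(tr) {
    s <- dplyr::filter(summaries, .data$tier == tr)
    rows <- list()
    for (msr in c("mean_amplitude_pct", "mean_duration_s", "auc_pct_s")) {
      d <- s[!is.na(s[[msr]]), c("group", msr)]
      if (length(unique(d$group)) == 2 && nrow(d) >= 2) {
        cmp <- rank_sum_test(d, .data[[msr]], group, ref = control_group,
                             measure = msr)
        rows[[length(rows) + 1]] <- tidy(cmp)
      }
    }
    nb <- negbin_count_model(s, event_count, group, ref = control_group,
                             measure = "event_count")
    rows[[length(rows) + 1]] <- tidy(nb)
    dplyr::bind_rows(rows) |> dplyr::mutate(tier = tr, .before = 1)
  })

  manifest <- run_manifest(
    stage = "activity",
    config = config,
    groups = table(dplyr::distinct(recordings, .data$larva_id, .data$group)$group),
    counts = list(
      n_larvae = dplyr::n_distinct(recordings$larva_id),
      n_frames = nrow(recordings),
      n_events = nrow(events),
      n_comparisons = nrow(comparisons)
    )
  )
  structure(list(summaries = summaries, events = events,
                 comparisons = comparisons, manifest = manifest),
            class = "ca_run")
}

#' End-to-end seizure analysis of a cohort
#'
#' Runs the seizure workflow: dF/F0 (300 s baseline window by
#' convention for seizure-model recordings, set via the config), seizure
#' detection, alignment at 50% of maximum with per-seizure AUC and time
#' to peak, per-group averaged waveforms, per-group seizing fractions,
#' a negative-binomial model on per-larva seizure counts, and rank-sum
#' tests on amplitude, duration (non-truncated seizures only), time to
#' peak and aligned AUC.
#'
#' @inheritParams run_activity_analysis
#' @param fraction_digits Decimal places for the reported seizing
#'   fractions.
#' @return List of class `"ca_run"` with `seizures` (per-seizure metrics),
#'   `aligned` (named list of `aligned_seizures` per group),
#'   `larva_counts`, `fractions` (per group), `comparisons`, `manifest`.
#' @export
run_seizure_analysis <- function(recordings, config = pipeline_config(baseline_window_s = 300),
                                 control_group = "control",
                                 fraction_digits = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  groups <- unique(recordings$group)

  dff <- compute_dff(recordings, window_s = config$baseline_window_s,
                     percentile = config$baseline_percentile,
                     align = config$baseline_align)
  seiz <- detect_seizures(dff,
                          boundary_pct = config$seizure_boundary_threshold_pct,
                          peak_pct = config$seizure_peak_threshold_pct,
                          align_fraction = config$align_fraction)

  roster <- dplyr::distinct(recordings, .data$larva_id, .data$group)
  larva_counts <- roster |>
    dplyr::left_join(dplyr::count(seiz, .data$larva_id, name = "n_seizures"),
                     by = "larva_id") |>
    dplyr::mutate(n_seizures = dplyr::coalesce(.data$n_seizures, 0L))

  fractions <- larva_counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_seizing = sum(.data$n_seizures > 0),
      n_total = dplyr::n(),
      seizing_pct = seizing_fraction(n_seizing, n_total,
                                     digits = fraction_digits),
      .groups = "drop"
    )

  aligned <- list()
  metrics <- empty_seizures()[0, ]
  if (nrow(seiz) > 0) {
    control_aucs <- NULL
    for (g in c(intersect(control_group, groups),
                setdiff(unique(seiz$group), control_group))) {
      gs <- dplyr::filter(seiz, .data$group == g)
      if (nrow(gs) == 0) next
      al <- align_seizures(gs, dplyr::filter(dff, .data$group == g),
                           align_fraction = config$align_fraction,
                           pre_s = config$align_pre_s,
                           post_s = config$align_post_s)
      if (g == control_group) control_aucs <- seizure_metrics(al)$auc_pct_s
      aligned[[g]] <- al
      metrics <- dplyr::bind_rows(metrics, seizure_metrics(al, control_aucs = control_aucs))
    }
  }

  comparisons <- tibble()
  if (length(groups) == 2 && nrow(metrics) > 0 &&
      length(unique(metrics$group)) == 2) {
    rows <- list()
    msrs <- c("amplitude_pct", "time_to_peak_s", "auc_pct_s")
    for (msr in msrs) {
      rows[[length(rows) + 1]] <-
        tidy(rank_sum_test(metrics, .data[[msr]], group,
                           ref = control_group, measure = msr))
    }
    dur <- dplyr::filter(metrics, !.data$truncated)
    if (length(unique(dur$group)) == 2) {
      rows[[length(rows) + 1]] <-
        tidy(rank_sum_test(dur, duration_s, group, ref = control_group,
                           measure = "duration_s"))
    }
    rows[[length(rows) + 1]] <-
      tidy(negbin_count_model(larva_counts, n_seizures, group,
                              ref = control_group, measure = "n_seizures"))
    comparisons <- dplyr::bind_rows(rows)
  }

  manifest <- run_manifest(
    stage = "seizure",
    config = config,
    groups = table(roster$group),
    counts = list(
      n_larvae = nrow(roster),
      n_frames = nrow(recordings),
      n_seizures = nrow(seiz),
      n_truncated = sum(seiz$truncated),
      n_comparisons = nrow(comparisons)
    )
  )
  structure(list(seizures = metrics, aligned = aligned,
                 larva_counts = larva_counts, fractions = fractions,
                 comparisons = comparisons, manifest = manifest),
            class = "ca_run")
}

run_manifest <- function(stage, config, groups, counts) {
  list(
    stage = stage,
    package_version = as.character(packageVersion("calcitrace")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    groups = as.list(setNames(as.integer(groups), names(groups))),
    record_counts = counts
  )
}

#' @export
print.ca_run <- function(x, ...) {
  cat(sprintf("<ca_run> stage = %s\n", x$manifest$stage))
  for (nm in names(x$manifest$record_counts)) {
    cat(sprintf("  %-16s %s\n", nm, x$manifest$record_counts[[nm]]))
  }
  invisible(x)
}

#' Write a run's report files
#'
#' Serialises a [run_activity_analysis()] / [run_seizure_analysis()]
#' result into a directory: CSV tables (summaries/seizures, events or
#' per-larva counts), `stats.json` (the comparisons), and
#' `manifest.json`. All outputs are deterministic functions of the run,
#' so re-running with the same inputs reproduces them byte for byte.
#'
#' @param run A `ca_run` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "ca_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    write_table(x, p)
    files[[name]] <<- p
  }
  if (run$manifest$stage == "activity") {
    put_csv(run$summaries, "summaries.csv")
    put_csv(run$events, "events.csv")
  } else {
    put_csv(run$seizures, "seizures.csv")
    put_csv(run$larva_counts, "larva_counts.csv")
    put_csv(run$fractions, "fractions.csv")
    for (g in names(run$aligned)) {
      al <- run$aligned[[g]]
      mat <- tibble(time_s = al$time_s, mean = al$mean_trace, sem = al$sem_trace)
      put_csv(mat, sprintf("aligned_%s.csv", gsub("[^A-Za-z0-9]+", "", g)))
    }
  }
  p <- file.path(dir, "stats.json")
  jsonlite::write_json(run$comparisons, p, digits = NA, na = "null", pretty = TRUE)
  files[["stats.json"]] <- p
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, p, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files[["manifest.json"]] <- p
  invisible(unlist(files))
}
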