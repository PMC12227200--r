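#' Simulation configuration for synthetic cohorts
#'
#' Parameters of the seeded generator that emulates 1-hour whole-brain
#' fluorescence recordings: a positive baseline with slow multiplicative
#' drift, additive Gaussian noise, small (5-10% dF/F0) and large (>10%)
#' calcium transients with linear rise and exponential decay, and
#' seizure waveforms exceeding 100% dF/F0 with gradual onset and either
#' abrupt or tapering decline. Transients are placed with
#' non-overlapping supports and ground truth is recorded, so analytic
#' threshold crossings are available for every seeded kernel (see
#' [truth_crossings()]).
#'
#' @param duration_s Recording length in seconds (default 3600).
#' @param sampling_rate_hz Camera rate in Hz (default 1.33).
#' @param baseline_level Quiescent fluorescence level in camera units.
#' @param drift `list(amplitude_fraction, period_s)`: sinusoidal
#'   multiplicative drift of the baseline.
#' @param noise_sd_pct Additive Gaussian noise SD, percent of
#'   `baseline_level`.
#' @param small_event,large_event `list(rate_per_min, amplitude_pct_range,
#'   rise_s, decay_s)` for the two transient classes.
#' @param seizure `list(count | probability_per_recording | rate_per_recording,
#'   amplitude_pct_range, rise_s, plateau_s, decay_s, decay_shape)`.
#'   `count` fixes the number of seizures; otherwise a Bernoulli or
#'   Poisson draw is used. `decay_shape` `"abrupt"` (tens of seconds) or
#'   `"tapering"` (minutes) selects the default decay constant when
#'   `decay_s` is `NULL`.
#' @param group_effects Named list of per-group multiplier lists with any
#'   of `small_rate`, `large_rate`, `amplitude`, `seizure_rate`,
#'   `seizure_amplitude`. Defaults encode the directions seen in the
#'   galanin perturbations: galanin overexpression halves the large-event
#'   rate; galanin loss doubles the small-event rate and shrinks
#'   amplitudes.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(duration_s = 3600,
                       sampling_rate_hz = 1.33,
                       baseline_level = 1000,
                       drift = list(amplitude_fraction = 0.05, period_s = 1800),
                       noise_sd_pct = 1,
                       small_event = list(rate_per_min = 2,
                                          amplitude_pct_range = c(5, 10),
                                          rise_s = 1.5, decay_s = 4),
                       large_event = list(rate_per_min = 1,
                                          amplitude_pct_range = c(10, 50),
                                          rise_s = 1.5, decay_s = 6),
                       seizure = list(count = NULL,
                                      probability_per_recording = NULL,
                                      rate_per_recording = 0,
                                      amplitude_pct_range = c(100, 200),
                                      rise_s = 20, plateau_s = 5,
                                      decay_s = NULL,
                                      decay_shape = "abrupt"),
                       group_effects = list(
                         "hsp70l:gal" = list(large_rate = 0.5),
                         "gal-/-" = list(small_rate = 2, amplitude = 0.8)
                       )) {
  stopifnot(duration_s > 0, sampling_rate_hz > 0, baseline_level > 0,
            noise_sd_pct >= 0)
  for (ev in list(small_event, large_event)) {
    stopifnot(ev$rate_per_min >= 0, length(ev$amplitude_pct_range) == 2,
              ev$amplitude_pct_range[1] <= ev$amplitude_pct_range[2],
              ev$amplitude_pct_range[1] > 0, ev$rise_s > 0, ev$decay_s > 0)
  }
  seizure$decay_shape <- match.arg(seizure$decay_shape, c("abrupt", "tapering"))
  if (is.null(seizure$decay_s)) {
    seizure$decay_s <- if (seizure$decay_shape == "tapering") 150 else 30
  }
  stopifnot(length(seizure$amplitude_pct_range) == 2,
            seizure$amplitude_pct_range[1] >= 100,
            seizure$rise_s > 0, seizure$plateau_s >= 0, seizure$decay_s > 0)
  structure(
    list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         baseline_level = baseline_level, drift = drift,
         noise_sd_pct = noise_sd_pct, small_event = small_event,
         large_event = large_event, seizure = seizure,
         group_effects = group_effects),
    class = "sim_config"
  )
}

# Kernel contribution (percent dF/F0) of one transient at times t:
# linear rise 0 -> A over rise_s, optional plateau, exponential decay
# with time constant decay_s, truncated to exactly 0 once it falls below
# `floor_pct` so quiescent frames sit exactly on the baseline.
kernel_floor_pct <- 0.1

kernel_values <- function(t, start, amp, rise_s, plateau_s, decay_s) {
  tt <- t - start
  out <- numeric(length(t))
  r <- tt >= 0 & tt < rise_s
  out[r] <- amp * tt[r] / rise_s
  p <- tt >= rise_s & tt < rise_s + plateau_s
  out[p] <- amp
  d <- tt >= rise_s + plateau_s
  out[d] <- amp * exp(-(tt[d] - rise_s - plateau_s) / decay_s)
  out[out < kernel_floor_pct] <- 0
  out
}

kernel_support_len <- function(amp, rise_s, plateau_s, decay_s) {
  rise_s + plateau_s + decay_s * log(amp / kernel_floor_pct)
}

#' Analytic threshold crossings of seeded kernels
#'
#' Given a ground-truth table from the simulator, returns each kernel's
#' exact crossing times of a dF/F0 threshold: the rising crossing at
#' `t_start + rise_s * thr / amplitude` and the decaying crossing at
#' `t_start + rise_s + plateau_s + decay_s * log(amplitude / thr)`.
#' Kernels whose amplitude does not exceed the threshold are dropped.
#' This is the oracle that detection on noiseless traces is checked
#' against.
#'
#' @param truth Ground-truth tibble (`events` or `seizures` component of
#'   a simulation) with columns `t_start_s`, `amplitude_pct`, `rise_s`,
#'   `plateau_s`, `decay_s`.
#' @param threshold_pct Threshold in percent dF/F0.
#' @return The input rows (amplitude > threshold) with `onset_s`,
#'   `offset_s`, `duration_s`, `peak_time_s` at that threshold.
#' @export
truth_crossings <- function(truth, threshold_pct) {
  stopifnot(threshold_pct > 0)
  truth |>
    dplyr::filter(.data$amplitude_pct > threshold_pct) |>
    dplyr::mutate(
      onset_s = .data$t_start_s + .data$rise_s * threshold_pct / .data$amplitude_pct,
      offset_s = .data$t_start_s + .data$rise_s + .data$plateau_s +
        .data$decay_s * log(.data$amplitude_pct / threshold_pct),
      duration_s = .data$offset_s - .data$onset_s,
      peak_time_s = .data$t_start_s + .data$rise_s
    )
}

# Place `n` kernel starts uniformly in [lo, hi - support], rejecting
# candidates whose padded support would overlap an already-placed one.
place_starts <- function(n, lo, hi, support, occupied, gap_s, max_tries = 200) {
  starts <- numeric(0)
  occ <- occupied  # matrix-ish list of c(start, end)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- runif(1, lo, max(hi - support, lo))
      span <- c(cand - gap_s, cand + support + gap_s)
      clash <- any(vapply(occ, function(o) span[1] < o[2] && o[1] < span[2],
                          logical(1)))
      if (!clash) {
        starts <- c(starts, cand)
        occ <- c(occ, list(c(cand, cand + support)))
        placed <- TRUE
        break
      }
    }
    if (!placed) break  # trace saturated; truth reflects what was placed
  }
  list(starts = starts, occupied = occ)
}

#' Simulate one whole-brain recording with ground truth
#'
#' Generates a single larva's raw fluorescence trace
#' `F(t) = baseline * (1 + drift(t)) * (1 + sum(kernels(t)) / 100) + noise`
#' on the uniform frame grid, together with a ground-truth annotation of
#' every seeded transient and seizure. Transients are placed with
#' non-overlapping (padded) supports and seizures are kept clear of the
#' recording edges, so on a noiseless trace every kernel produces exactly
#' one detection run and its analytic crossings ([truth_crossings()])
#' match the detector within one frame. Identical seeds give
#' bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @param larva_id,group,treatment Metadata for the recording.
#' @param seed Integer seed (fully determines the output).
#' @return List with `recording` (a recording tibble) and `truth`
#'   (list of `events` and `seizures` tibbles with kernel parameters).
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 300), seed = 7)
#' nrow(sim$recording)
#' @export
simulate_recording <- function(cfg, larva_id = "larva_01", group = "control",
                               treatment = "none", seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), {
    fs <- cfg$sampling_rate_hz
    n <- floor(cfg$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    eff <- cfg$group_effects[[group]] %||% list()
    m_small <- eff$small_rate %||% 1
    m_large <- eff$large_rate %||% 1
    m_amp <- eff$amplitude %||% 1
    m_srate <- eff$seizure_rate %||% 1
    m_samp <- eff$seizure_amplitude %||% 1
    gap_s <- 4 / fs

    # seizures first: they occupy long stretches
    sz <- cfg$seizure
    n_sz <- if (!is.null(sz$count)) {
      as.integer(sz$count)
    } else if (!is.null(sz$probability_per_recording)) {
      rbinom(1, 1, min(1, sz$probability_per_recording * m_srate))
    } else {
      rpois(1, sz$rate_per_recording * m_srate)
    }
    sz_amp <- runif(n_sz, sz$amplitude_pct_range[1], sz$amplitude_pct_range[2]) * m_samp
    sz_amp <- pmax(sz_amp, 100)
    occupied <- list()
    sz_rows <- vector("list", n_sz)
    for (i in seq_len(n_sz)) {
      supp <- kernel_support_len(sz_amp[i], sz$rise_s, sz$plateau_s, sz$decay_s)
      pl <- place_starts(1, 5, cfg$duration_s - 5, supp, occupied, gap_s)
      occupied <- pl$occupied
      if (length(pl$starts) == 0) next
      sz_rows[[i]] <- tibble(larva_id = larva_id, t_start_s = pl$starts,
                             amplitude_pct = sz_amp[i], rise_s = sz$rise_s,
                             plateau_s = sz$plateau_s, decay_s = sz$decay_s,
                             decay_shape = sz$decay_shape)
    }
    truth_sz <- dplyr::bind_rows(sz_rows)
    if (nrow(truth_sz) == 0) truth_sz <- empty_truth(seizure = TRUE)

    # transients
    ev_rows <- list()
    for (kind in c("small", "large")) {
      ev <- if (kind == "small") cfg$small_event else cfg$large_event
      mult <- if (kind == "small") m_small else m_large
      n_ev <- rpois(1, ev$rate_per_min * mult * cfg$duration_s / 60)
      if (n_ev == 0) next
      amps <- runif(n_ev, ev$amplitude_pct_range[1], ev$amplitude_pct_range[2]) * m_amp
      amps <- pmax(amps, kernel_floor_pct * 2)
      for (i in seq_len(n_ev)) {
        supp <- kernel_support_len(amps[i], ev$rise_s, 0, ev$decay_s)
        pl <- place_starts(1, 1, cfg$duration_s - 1, supp, occupied, gap_s)
        occupied <- pl$occupied
        if (length(pl$starts) == 0) next
        ev_rows[[length(ev_rows) + 1]] <-
          tibble(larva_id = larva_id, kind = kind, t_start_s = pl$starts,
                 amplitude_pct = amps[i], rise_s = ev$rise_s, plateau_s = 0,
                 decay_s = ev$decay_s)
      }
    }
    truth_ev <- dplyr::bind_rows(ev_rows)
    if (nrow(truth_ev) == 0) truth_ev <- empty_truth(seizure = FALSE)
    truth_ev <- dplyr::arrange(truth_ev, .data$t_start_s)
    truth_sz <- dplyr::arrange(truth_sz, .data$t_start_s)

    pct <- numeric(n)
    add_kernels <- function(tbl) {
      for (i in seq_len(nrow(tbl))) {
        pct <<- pct + kernel_values(t, tbl$t_start_s[i], tbl$amplitude_pct[i],
                                    tbl$rise_s[i], tbl$plateau_s[i],
                                    tbl$decay_s[i])
      }
    }
    add_kernels(truth_sz)
    add_kernels(truth_ev)

    drift <- cfg$drift$amplitude_fraction *
      sin(2 * pi * t / cfg$drift$period_s)
    f <- cfg$baseline_level * (1 + drift) * (1 + pct / 100)
    if (cfg$noise_sd_pct > 0) {
      f <- f + rnorm(n, 0, cfg$noise_sd_pct / 100 * cfg$baseline_level)
    }
    f <- pmax(f, 0)

    list(
      recording = new_recording(f, larva_id = larva_id, group = group,
                                treatment = treatment, sampling_rate_hz = fs),
      truth = list(events = truth_ev, seizures = truth_sz)
    )
  })
}

empty_truth <- function(seizure) {
  base <- tibble(larva_id = character(), t_start_s = numeric(),
                 amplitude_pct = numeric(), rise_s = numeric(),
                 plateau_s = numeric(), decay_s = numeric())
  if (seizure) dplyr::mutate(base, decay_shape = character())
  else dplyr::mutate(base, kind = character(), .after = "larva_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic, order-independent 31-bit hash of (seed, group, index);
# doubles stay exact well below 2^53 so the modular arithmetic is exact.
larva_seed <- function(seed, group, index) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (c in utf8ToInt(paste0(group, "#", index))) {
    s <- (s * 31 + c) %% m
  }
  max(1, floor(s))
}

#' Simulate a cohort of recordings
#'
#' Draws independent recordings for several groups, applying the
#' configured per-group effect multipliers, with one sub-seed per larva
#' derived deterministically from `seed`.
#'
#' @param cfg A [sim_config()].
#' @param groups Named integer vector: larvae per group, e.g.
#'   `c(control = 25, "gal-/-" = 24)`.
#' @param seed Integer master seed.
#' @param treatment Treatment label applied to all recordings.
#' @param seizure_counts Optional named list mapping a group to an
#'   integer vector (length = group size) of fixed per-larva seizure
#'   counts; overrides the config's seizure draw for that group.
#' @return List with `recordings` (all larvae bound into one tibble) and
#'   `truth` (`events`, `seizures` tibbles across the cohort, plus a
#'   `larvae` roster with each larva's group).
#' @examples
#' coh <- simulate_cohort(sim_config(duration_s = 120), c(control = 2), seed = 1)
#' dplyr::count(coh$recordings, larva_id)
#' @export
simulate_cohort <- function(cfg, groups, seed = 1L, treatment = "none",
                            seizure_counts = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(groups) >= 1,
            !is.null(names(groups)), all(groups >= 1))
  roster <- tibble(
    group = rep(names(groups), times = groups),
    index_in_group = unlist(lapply(groups, seq_len), use.names = FALSE)
  )
  roster$larva_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", roster$group),
                             roster$index_in_group)
  if (anyDuplicated(roster$larva_id) > 0) {
    roster$larva_id <- sprintf("%s_%02d", make.unique(roster$group), roster$index_in_group)
  }

  # Per-larva seeds hash (master seed, group, index) so that reordering the
  # `groups` argument permutes the cohort without changing any recording.
  sub_seeds <- purrr::map2_dbl(roster$group, roster$index_in_group,
                               function(g, i) larva_seed(seed, g, i))

  sims <- purrr::pmap(
    list(roster$larva_id, roster$group, roster$index_in_group, sub_seeds),
    function(id, grp, idx, s) {
      cfg_i <- cfg
      if (!is.null(seizure_counts) && grp %in% names(seizure_counts)) {
        cfg_i$seizure$count <- seizure_counts[[grp]][idx]
      }
      simulate_recording(cfg_i, larva_id = id, group = grp,
                         treatment = treatment, seed = s)
    }
  )
  list(
    recordings = dplyr::bind_rows(purrr::map(sims, "recording")),
    truth = list(
      larvae = dplyr::select(roster, "larva_id", "group"),
      events = dplyr::bind_rows(purrr::map(sims, ~ .x$truth$events)),
      seizures = dplyr::bind_rows(purrr::map(sims, ~ .x$truth$seizures))
    )
  )
}

#' Simulate a qPCR Ct panel with a known fold change
#'
#' Forward-generates a two-condition Ct table: reference-gene Cts are
#' constant across conditions, the target gene's Ct is shifted by
#' `-log2(true_fold_change)` in the case condition, Gaussian noise of SD
#' `ct_noise_sd` cycles is added per reaction, and every sample x gene is
#' measured in technical triplicates (configurable).
#'
#' @param true_fold_change Positive fold change of the target in the
#'   case condition.
#' @param ct_noise_sd Per-reaction Ct noise SD in cycles (0 = noiseless).
#' @param n_pools Biological samples (pools) per condition.
#' @param n_replicates Technical replicates per reaction.
#' @param seed Integer seed.
#' @param target_gene,reference_genes Gene names.
#' @param base_ct Named baseline Cts; must cover the target and all
#'   reference genes.
#' @param conditions Length-2 labels, baseline first.
#' @return A tidy Ct panel tibble (`sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`) ready for [relative_expression()].
#' @examples
#' pan <- simulate_qpcr(15.4, ct_noise_sd = 0, seed = 1)
#' glance(relative_expression(pan))$fold_change
#' @export
simulate_qpcr <- function(true_fold_change = 1, ct_noise_sd = 0, n_pools = 3,
                          n_replicates = 3, seed = 1L, target_gene = "gal",
                          reference_genes = c("actb1", "tbp", "rpl13a"),
                          base_ct = c(gal = 26, actb1 = 18, tbp = 27, rpl13a = 20),
                          conditions = c("control", "case")) {
  stopifnot(true_fold_change > 0, ct_noise_sd >= 0, n_pools >= 1,
            n_replicates >= 1, length(conditions) == 2)
  genes <- c(target_gene, reference_genes)
  if (!all(genes %in% names(base_ct))) {
    abort("`base_ct` must name the target and every reference gene.")
  }
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(
      condition = conditions,
      pool = seq_len(n_pools),
      gene = genes,
      replicate = seq_len(n_replicates)
    )
    grid$sample_id <- sprintf("%s_pool%02d", grid$condition, grid$pool)
    grid$ct <- unname(base_ct[grid$gene]) -
      ifelse(grid$gene == target_gene & grid$condition == conditions[2],
             log2(true_fold_change), 0)
    if (ct_noise_sd > 0) grid$ct <- grid$ct + rnorm(nrow(grid), 0, ct_noise_sd)
    dplyr::select(grid, "sample_id", "condition", "gene", "replicate", "ct")
  })
}
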