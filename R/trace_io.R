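#' Construct a recording tibble
#'
#' A recording is one larva's uniformly sampled whole-brain fluorescence
#' trace in tidy (one row per frame) form, with metadata carried as
#' constant columns so that dplyr verbs and grouped pipelines work
#' naturally on cohorts of recordings bound together.
#'
#' @param f Numeric vector of raw fluorescence values, one per frame.
#'   Must be finite, non-negative, and of length >= 2.
#' @param larva_id Identifier for the animal.
#' @param group Experimental group label (e.g. `"control"`,
#'   `"hsp70l:gal"`, `"gal-/-"`, `"galr1aKO"`, `"eaat2a-/-"`).
#' @param treatment One of `"none"`, `"ptz_acute"`, `"ptz_rebound"`.
#' @param sampling_rate_hz Sampling rate in Hz (default 1.33, the
#'   wide-field camera rate for 1 h recordings).
#' @param t0_s Time of the first frame in seconds.
#'
#' @return A tibble with columns `larva_id`, `group`, `treatment`,
#'   `frame` (0-based), `time_s`, `f`, `sampling_rate_hz`.
#' @examples
#' rec <- new_recording(c(100, 104, 99), larva_id = "fish01")
#' rec
#' @export
new_recording <- function(f, larva_id, group = "control", treatment = "none",
                          sampling_rate_hz = 1.33, t0_s = 0) {
  f <- as.numeric(f)
  if (length(f) < 2) abort("A recording needs at least 2 frames.")
  if (anyNA(f) || any(!is.finite(f))) abort("Fluorescence must be finite (no NA/Inf).")
  if (any(f < 0)) abort("Fluorescence must be non-negative.")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive number.")
  }
  treatment <- match.arg(treatment, c("none", "ptz_acute", "ptz_rebound"))
  k <- seq_along(f) - 1L
  tibble(
    larva_id = as.character(larva_id),
    group = as.character(group),
    treatment = treatment,
    frame = k,
    time_s = t0_s + k / sampling_rate_hz,
    f = f,
    sampling_rate_hz = sampling_rate_hz
  )
}

#' Read a fluorescence time-series table
#'
#' Reads a comma-separated table with one header row of ROI names and one
#' row per frame, and returns a tidy recording for the designated
#' whole-brain signal. The published analysis treats each larva as a
#' single whole-brain ROI; with multiple ROI columns the default takes
#' the first, or their per-frame mean with `roi = "mean"`.
#'
#' @param path Path to a CSV file (header row mandatory, `.` decimal).
#' @param roi ROI selection: a column name, a column index, or `"mean"`
#'   to average all ROI columns per frame. Default: first column.
#' @inheritParams new_recording
#' @return A recording tibble (see [new_recording()]).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("brain", "10", "11", "12"), tf)
#' read_recording(tf, larva_id = "fish01")
#' @export
read_recording <- function(path, larva_id, group = "control",
                           treatment = "none", sampling_rate_hz = 1.33,
                           t0_s = 0, roi = NULL) {
  tab <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(paste0("Malformed table '", path, "': ", conditionMessage(e)),
                              class = "calcitrace_parse_error")
  )
  if (ncol(tab) < 1 || nrow(tab) < 1) {
    abort(paste0("Table '", path, "' has no data rows."), class = "calcitrace_parse_error")
  }
  num <- purrr::imap(tab, function(col, nm) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric cell in column '%s', row %d: '%s'",
                    nm, bad[1], col[bad[1]]),
            class = "calcitrace_parse_error")
    }
    neg <- which(x < 0)
    if (length(neg) > 0) {
      abort(sprintf("Negative fluorescence in column '%s', row %d: %s",
                    nm, neg[1], col[neg[1]]),
            class = "calcitrace_parse_error")
    }
    x
  })
  mat <- do.call(cbind, num)

  if (is.null(roi)) {
    f <- mat[, 1]
  } else if (identical(roi, "mean")) {
    f <- rowMeans(mat)
  } else if (is.numeric(roi)) {
    if (roi < 1 || roi > ncol(mat)) abort("`roi` index out of range.", class = "calcitrace_parse_error")
    f <- mat[, roi]
  } else {
    if (!roi %in% colnames(mat)) {
      abort(paste0("ROI column '", roi, "' not found."), class = "calcitrace_parse_error")
    }
    f <- mat[, roi]
  }
  new_recording(f, larva_id = larva_id, group = group, treatment = treatment,
                sampling_rate_hz = sampling_rate_hz, t0_s = t0_s)
}

#' Write a recording's raw trace to CSV
#'
#' Writes a single-column CSV (header = `larva_id`) readable back with
#' [read_recording()]; values round-trip at full double precision.
#'
#' @param recording A recording tibble for one larva.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(all(c("larva_id", "f") %in% names(recording)))
  ids <- unique(recording$larva_id)
  if (length(ids) != 1) abort("`write_recording()` expects a single larva; filter first.")
  out <- tibble(!!ids := recording$f)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write event, seizure or summary tables to CSV
#'
#' Rows are ordered deterministically (by `larva_id`, then onset time when
#' present) and written with full-precision doubles so that a re-read
#' reproduces the table.
#'
#' @param x A tibble of events, seizures or per-larva summaries.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  ord <- intersect(c("larva_id", "onset_s", "tier"), names(x))
  if (length(ord) > 0) x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(ord)))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
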