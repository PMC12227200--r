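#' Shapiro-Wilk normality report per group
#'
#' The analysis protocol tests each measure for normality before group
#' comparison; because the imaging measures are typically non-normal, the
#' pipeline's comparisons are nonparametric regardless, and this gate is
#' a report, not a branch.
#'
#' @param data A data frame of per-larva (or per-seizure) values.
#' @param value,group Columns (tidy-eval) holding the measure and the
#'   group label.
#' @return Tibble with `group`, `n`, `statistic` (W), `p_value`,
#'   `degenerate` (TRUE for zero-variance samples, where W is undefined).
#' @export
normality_gate <- function(data, value, group) {
  value <- enquo(value); group <- enquo(group)
  d <- dplyr::transmute(data, g = !!group, v = !!value)
  d |>
    dplyr::group_by(.data$g) |>
    dplyr::group_modify(function(x, key) {
      n <- nrow(x)
      if (n < 3) abort("Shapiro-Wilk requires n >= 3 per group.")
      if (sd(x$v) == 0) {
        return(tibble(n = n, statistic = NA_real_, p_value = NA_real_,
                      degenerate = TRUE))
      }
      sw <- shapiro.test(x$v)
      tibble(n = n, statistic = unname(sw$statistic),
             p_value = sw$p.value, degenerate = FALSE)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "g")
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' The pipeline's comparison for continuous per-larva and per-seizure
#' measures (amplitudes, durations, AUC, time to peak). P-values come
#' from exact enumeration of the Mann-Whitney U null when both samples
#' are tie-free and the smaller has at most 8 observations, and from the
#' normal approximation with mid-ranks, tie correction and continuity
#' correction otherwise. The effect reported is the difference of group
#' medians (second group minus reference).
#'
#' @param data Data frame with one row per observation.
#' @param value,group Columns (tidy-eval): the measure and a two-level
#'   group label.
#' @param ref Reference group label; defaults to the first level (or
#'   first value encountered).
#' @param measure Optional name for the measure (used in reports).
#' @param exact_max_n Largest min-group size for which the exact null is
#'   enumerated (default 8).
#' @return An object of class `"ca_comparison"`; see [tidy.ca_comparison()].
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 10, 11, 12))
#' tidy(rank_sum_test(d, y, g))  # exact p = 0.1
#' @export
rank_sum_test <- function(data, value, group, ref = NULL, measure = NULL,
                          exact_max_n = 8) {
  value <- enquo(value); group <- enquo(group)
  if (is.null(measure)) measure <- as_name(value)
  d <- dplyr::transmute(data, g = as.character(!!group), v = !!value)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  labs <- unique(d$g)
  if (length(labs) != 2) abort("`rank_sum_test()` needs exactly two groups.")
  if (is.null(ref)) ref <- labs[1]
  other <- setdiff(labs, ref)
  x <- d$v[d$g == ref]; y <- d$v[d$g == other]
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")

  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max_n
  wt <- suppressWarnings(
    wilcox.test(y, x, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  new_ca_comparison(
    measure = measure, test = "rank_sum",
    group_labels = c(ref, other),
    n_per_group = c(length(x), length(y)),
    statistic = unname(wt$statistic),  # U of `other` vs reference
    p_value = wt$p.value,
    effect = median(y) - median(x),
    effect_name = "median_difference",
    exact = use_exact,
    fit = wt
  )
}

#' Negative-binomial regression on event counts
#'
#' Event and seizure numbers per larva are overdispersed counts, so
#' groups are compared with a log-link negative-binomial GLM
#' (gamma-Poisson), `count ~ group`, fitted by maximum likelihood with
#' the dispersion profiled jointly (via [MASS::glm.nb()]). The effect is
#' the rate ratio `exp(beta_group)`; the p-value is the Wald test of the
#' group coefficient by default, with a likelihood-ratio alternative.
#'
#' @param data Data frame with one row per larva.
#' @param count,group Columns (tidy-eval): non-negative integer counts
#'   and a two-level group label.
#' @param ref Reference group (rate-ratio denominator).
#' @param measure Optional measure name for reports.
#' @param p_method `"wald"` (default) or `"lrt"`.
#' @return An object of class `"ca_comparison"`; the underlying `glm.nb`
#'   fit is in `$fit`. `$unstable` flags fits with an all-zero group or
#'   non-convergence (e.g. dispersion at the Poisson boundary).
#' @export
negbin_count_model <- function(data, count, group, ref = NULL,
                               measure = NULL, p_method = c("wald", "lrt")) {
  p_method <- match.arg(p_method)
  count <- enquo(count); group <- enquo(group)
  if (is.null(measure)) measure <- as_name(count)
  d <- dplyr::transmute(data, g = as.character(!!group), y = !!count)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  labs <- unique(d$g)
  if (length(labs) != 2) abort("`negbin_count_model()` needs exactly two groups.")
  if (any(d$y < 0) || any(d$y != round(d$y))) {
    abort("Counts must be non-negative integers.")
  }
  if (is.null(ref)) ref <- labs[1]
  d$g <- factor(d$g, levels = c(ref, setdiff(labs, ref)))

  unstable <- FALSE
  all_zero <- any(tapply(d$y, d$g, function(v) all(v == 0)))
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ g, data = d),
      warning = function(w) {
        unstable <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # dispersion at the Poisson boundary (e.g. under-dispersed counts):
    # theta -> Inf, where the NB likelihood degenerates to the Poisson one
    fit <- stats::glm(y ~ g, family = stats::poisson(), data = d)
    fit$theta <- Inf
    unstable <- TRUE
  }
  if (all_zero) unstable <- TRUE
  sm <- summary(fit)
  co <- sm$coefficients
  beta <- co[2, "Estimate"]
  if (p_method == "wald") {
    stat <- co[2, "z value"]
    p <- co[2, "Pr(>|z|)"]
  } else {
    fit0 <- if (is.infinite(fit$theta)) {
      stats::glm(y ~ 1, family = stats::poisson(), data = d)
    } else {
      suppressWarnings(MASS::glm.nb(y ~ 1, data = d))
    }
    stat <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(fit0)))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  new_ca_comparison(
    measure = measure, test = "negbin_glm",
    group_labels = levels(d$g),
    n_per_group = as.integer(table(d$g)),
    statistic = unname(stat),
    p_value = unname(p),
    effect = unname(exp(beta)),
    effect_name = "rate_ratio",
    unstable = unstable,
    theta = fit$theta,
    fit = fit
  )
}

new_ca_comparison <- function(measure, test, group_labels, n_per_group,
                              statistic, p_value, effect, effect_name, ...) {
  structure(
    c(list(
      measure = measure, test = test,
      group_labels = group_labels, n_per_group = n_per_group,
      statistic = statistic, p_value = p_value,
      effect = effect, effect_name = effect_name,
      significance = label_significance(p_value)
    ), list(...)),
    class = "ca_comparison"
  )
}

#' Significance labels at the conventional thresholds
#'
#' Maps p-values to `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"`
#' (p < 0.05) and `"ns"` otherwise. Vectorized and monotone in p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @examples
#' label_significance(c(0.04, 0.0005, 0.5))
#' @export
label_significance <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
print.ca_comparison <- function(x, ...) {
  cat(sprintf("<ca_comparison> %s: %s vs %s (n = %d, %d)\n",
              x$measure, x$group_labels[1], x$group_labels[2],
              x$n_per_group[1], x$n_per_group[2]))
  cat(sprintf("  test = %s, statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$significance))
  cat(sprintf("  %s = %.4g\n", x$effect_name, x$effect))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `ca_comparison` from [rank_sum_test()] or
#'   [negbin_count_model()].
#' @param ... Unused.
#' @return A one-row tibble with the comparison's fields (`measure`,
#'   `test`, group labels and sizes, `statistic`, `p_value`, `effect`,
#'   `effect_name`, `significance`).
#' @export
tidy.ca_comparison <- function(x, ...) {
  tibble(
    measure = x$measure,
    test = x$test,
    group_ref = x$group_labels[1],
    group_alt = x$group_labels[2],
    n_ref = x$n_per_group[1],
    n_alt = x$n_per_group[2],
    statistic = x$statistic,
    p_value = x$p_value,
    effect = x$effect,
    effect_name = x$effect_name,
    significance = x$significance
  )
}

#' @describeIn tidy.ca_comparison Model-level summary; for
#'   negative-binomial fits adds the dispersion `theta` and stability
#'   flag.
#' @export
glance.ca_comparison <- function(x, ...) {
  out <- tibble(
    test = x$test,
    n_total = sum(x$n_per_group),
    p_value = x$p_value,
    significance = x$significance
  )
  if (x$test == "negbin_glm") {
    out$theta <- x$theta
    out$unstable <- isTRUE(x$unstable)
    out$aic <- stats::AIC(x$fit)
  }
  if (x$test == "rank_sum") out$exact <- isTRUE(x$exact)
  out
}
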