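#' Primer efficiency from a dilution series
#'
#' Fits a least-squares line of mean Ct against log10 template dilution;
#' the amplification efficiency is `10^(-1/slope) - 1`, with the ideal
#' doubling chemistry giving slope -3.3219 and efficiency 1.0.
#' Efficiencies within \[0.9, 1.1\] are flagged acceptable.
#'
#' @param data Data frame of dilution points.
#' @param dilution_log10,ct Columns (tidy-eval): log10 of the dilution
#'   factor and the (replicate-averaged) Ct.
#' @return One-row tibble: `n_points`, `slope`, `efficiency`,
#'   `acceptable`, `r_squared`.
#' @examples
#' d <- data.frame(dil = -(0:4), ct = 20 + 3.3219 * (0:4))
#' primer_efficiency(d, dil, ct)  # efficiency 1.0
#' @export
primer_efficiency <- function(data, dilution_log10, ct) {
  dilution_log10 <- enquo(dilution_log10); ct <- enquo(ct)
  d <- dplyr::transmute(data, x = !!dilution_log10, y = !!ct)
  if (nrow(d) < 3) abort("A dilution series needs at least 3 points.")
  if (sd(d$x) == 0) abort("Dilutions are constant; slope undefined.")
  fit <- stats::lm(y ~ x, data = d)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) abort("Degenerate dilution series (zero slope).")
  eff <- 10^(-1 / slope) - 1
  tibble(
    n_points = nrow(d),
    slope = slope,
    efficiency = eff,
    acceptable = eff >= 0.9 & eff <= 1.1,
    r_squared = stats::cor(d$x, d$y)^2
  )
}

#' Relative expression by the ddCt method
#'
#' Computes a condition contrast's fold change from a Ct panel with
#' multiple reference genes. Technical replicates are averaged per
#' sample x gene; each sample's reference Ct is the arithmetic mean of
#' its reference-gene Cts (equivalent to the geometric mean of their
#' expression levels); dCt = Ct_target - Ct_ref; ddCt is the difference
#' of mean dCt between case and control; fold change = 2^(-ddCt),
#' assuming equal (near-perfect) primer efficiencies as verified by the
#' dilution series. An efficiency-corrected mode replaces base 2 with
#' `1 + efficiency` per gene (Pfaffl-style).
#'
#' @param panel Data frame with columns `sample_id`, `condition`
#'   (two levels), `gene`, `ct` (one row per technical replicate;
#'   a `replicate` column is allowed and ignored).
#' @param target_gene Gene of interest (default `"gal"`).
#' @param reference_genes Reference panel (default `actb1`, `tbp`,
#'   `rpl13a`).
#' @param control Condition label used as the baseline; default
#'   `"control"` if present, else the first level.
#' @param efficiencies Optional named numeric vector of per-gene
#'   amplification efficiencies (fractions, 1 = perfect doubling);
#'   enables the efficiency-corrected mode.
#' @return Object of class `"ddct_result"`: fold change, ddCt, per-sample
#'   dCt and per-sample fold changes (case samples vs the control mean;
#'   used for dispersion/error bars). [tidy()] returns the per-sample
#'   table, [glance()] the one-row result.
#' @examples
#' pan <- simulate_qpcr(true_fold_change = 4, ct_noise_sd = 0, seed = 1)
#' glance(relative_expression(pan))$fold_change  # 4
#' @export
relative_expression <- function(panel, target_gene = "gal",
                                reference_genes = c("actb1", "tbp", "rpl13a"),
                                control = NULL, efficiencies = NULL) {
  need <- c("sample_id", "condition", "gene", "ct")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  conds <- unique(panel$condition)
  if (length(conds) != 2) abort("Panel must contain exactly two conditions.")
  if (is.null(control)) control <- if ("control" %in% conds) "control" else conds[1]
  if (!control %in% conds) abort(paste0("Control condition '", control, "' not in panel."))
  case <- setdiff(conds, control)
  genes <- c(target_gene, reference_genes)

  per_gene <- panel |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$sample_id, .data$condition, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  wide <- tidyr::pivot_wider(per_gene, names_from = "gene", values_from = "ct")
  miss <- setdiff(genes, names(wide))
  if (length(miss) > 0 || anyNA(wide[genes])) {
    abort("Every sample needs Ct values for the target and all reference genes.")
  }

  if (is.null(efficiencies)) {
    ref_ct <- rowMeans(wide[reference_genes])
    dct <- wide[[target_gene]] - ref_ct
    samples <- dplyr::transmute(wide, .data$sample_id, .data$condition, dct = dct)
    ddct <- mean(samples$dct[samples$condition == case]) -
      mean(samples$dct[samples$condition == control])
    fold <- 2^(-ddct)
    ctrl_mean_dct <- mean(samples$dct[samples$condition == control])
    samples$fold_vs_control <- 2^(-(samples$dct - ctrl_mean_dct))
  } else {
    if (!all(genes %in% names(efficiencies))) {
      abort("`efficiencies` must be named for the target and every reference gene.")
    }
    # Pfaffl-style: per-gene base (1 + E); relative quantity per sample is
    # base^(-Ct), normalized by the geometric mean of reference quantities.
    base <- 1 + efficiencies
    logq <- purrr::map(genes, function(g) -wide[[g]] * log(base[[g]]))
    names(logq) <- genes
    log_ref <- Reduce(`+`, logq[reference_genes]) / length(reference_genes)
    log_rel <- logq[[target_gene]] - log_ref
    samples <- dplyr::transmute(wide, .data$sample_id, .data$condition,
                                dct = -log_rel / log(2))
    ddct <- mean(samples$dct[samples$condition == case]) -
      mean(samples$dct[samples$condition == control])
    fold <- 2^(-ddct)
    ctrl_mean_dct <- mean(samples$dct[samples$condition == control])
    samples$fold_vs_control <- 2^(-(samples$dct - ctrl_mean_dct))
  }

  structure(
    list(
      contrast = c(control = control, case = case),
      target_gene = target_gene,
      reference_genes = reference_genes,
      ddct = ddct,
      fold_change = fold,
      samples = samples,
      efficiency_corrected = !is.null(efficiencies)
    ),
    class = "ddct_result"
  )
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s vs %s: fold change = %.4g (ddCt = %.4g)\n",
              x$contrast[["case"]], x$contrast[["control"]],
              x$fold_change, x$ddct))
  cat(sprintf("  target %s, references %s\n", x$target_gene,
              paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' Tidy a ddCt result
#'
#' @param x A `ddct_result` from [relative_expression()].
#' @param ... Unused.
#' @return [tidy()]: per-sample tibble (`sample_id`, `condition`, `dct`,
#'   `fold_vs_control`). [glance()]: one-row tibble with the contrast,
#'   `ddct` and `fold_change`.
#' @export
tidy.ddct_result <- function(x, ...) as_tibble(x$samples)

#' @rdname tidy.ddct_result
#' @export
glance.ddct_result <- function(x, ...) {
  tibble(
    control = x$contrast[["control"]],
    case = x$contrast[["case"]],
    target_gene = x$target_gene,
    n_reference_genes = length(x$reference_genes),
    ddct = x$ddct,
    fold_change = x$fold_change,
    efficiency_corrected = x$efficiency_corrected
  )
}
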