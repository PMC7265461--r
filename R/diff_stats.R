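# Relative-quantification statistics: fold changes on mean intensities,
# unpaired two-sided t tests, the mean-adjusted ("mean-centered") test with
# its +/-0.07 log2 exemption, CV summaries, and the Gaussian bound on the
# fold-change distribution.

#' Per-peptide fold changes between two conditions
#'
#' `FC = mean(treated) / mean(control)` on intensities (arithmetic means,
#' n replicates per condition); reported as log2. Only peptides complete in
#' both groups are scored; peptides with zero control mean are excluded
#' with a message.
#'
#' @param x A `peptide_quant`.
#' @param condition_map Named character: sample/channel -> condition.
#' @param treated,control Condition labels.
#' @param use `"adjusted"` or `"raw"` values.
#' @return Data frame with `key`, `log2_fc`, `mean_treated`, `mean_control`.
#' @export
fold_changes <- function(x, condition_map, treated, control,
                         use = c("adjusted", "raw")) {
  use <- match.arg(use)
  if (use == "adjusted" && is.null(x$adjusted)) use <- "raw"
  g <- .group_cols(x, condition_map, treated, control)
  v <- quant_values(x, use)
  complete <- rowSums(is.na(v[, c(g$treated, g$control), drop = FALSE])) == 0
  v <- v[complete, , drop = FALSE]
  mt <- rowMeans(v[, g$treated, drop = FALSE])
  mc <- rowMeans(v[, g$control, drop = FALSE])
  zero <- mc == 0
  if (any(zero)) {
    message(sum(zero), " peptide(s) with zero control mean excluded")
  }
  data.frame(key = rownames(v)[!zero],
             log2_fc = log2(mt[!zero] / mc[!zero]),
             mean_treated = mt[!zero], mean_control = mc[!zero],
             row.names = NULL, stringsAsFactors = FALSE)
}

.group_cols <- function(x, condition_map, treated, control) {
  cm <- condition_map[x$samples]
  tr <- x$samples[!is.na(cm) & cm == treated]
  ct <- x$samples[!is.na(cm) & cm == control]
  if (!length(tr)) stop("no sample mapped to treated condition '", treated, "'")
  if (!length(ct)) stop("no sample mapped to control condition '", control, "'")
  list(treated = tr, control = ct)
}

#' Unpaired two-sided t test between two replicate groups
#'
#' Thin wrapper over [stats::t.test()] (equal-variance Student's test by
#' default, Welch optional) that handles the degenerate zero-variance cases
#' `t.test()` refuses: identical constant groups give p = 1, constant
#' groups with different means give p = 0.
#'
#' @param x,y Numeric replicate vectors (>= 2 values each).
#' @param var.equal Pool variances (Student) rather than Welch.
#' @return Two-sided p value.
#' @export
two_group_t <- function(x, y, var.equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var.equal)$p.value
}

.row_t_test <- function(treated_mat, control_mat, var.equal = TRUE) {
  vapply(seq_len(nrow(treated_mat)), function(i) {
    two_group_t(treated_mat[i, ], control_mat[i, ], var.equal = var.equal)
  }, numeric(1))
}

#' Mean-adjusted significance for enrichment above the global shift
#'
#' Treated intensities are mean centered by dividing each peptide's values
#' by the arithmetic mean fold change across all peptides, after which an
#' unpaired two-sided Student's t test against control is performed.
#' Centering is skipped (and `p_mean_adjusted = p_raw`) when the mean log2
#' fold change lies within the exemption band of +/-0.07.
#'
#' @param x A `peptide_quant`.
#' @param condition_map,treated,control As in [fold_changes()].
#' @param use `"adjusted"` or `"raw"` values.
#' @param exemption Half-width of the log2 exemption band (default 0.07).
#' @param center_stat `"arithmetic"` mean of per-peptide ratios (default) or
#'   `"geometric"`.
#' @param var.equal Pool variances in the t test.
#' @return Data frame `key`, `p_raw`, `p_mean_adjusted`; attributes
#'   `mean_fc` (ratio scale) and `centered` (logical).
#' @export
mean_adjusted_test <- function(x, condition_map, treated, control,
                               use = c("adjusted", "raw"), exemption = 0.07,
                               center_stat = c("arithmetic", "geometric"),
                               var.equal = TRUE) {
  use <- match.arg(use)
  if (use == "adjusted" && is.null(x$adjusted)) use <- "raw"
  center_stat <- match.arg(center_stat)
  g <- .group_cols(x, condition_map, treated, control)
  v <- quant_values(x, use)
  complete <- rowSums(is.na(v[, c(g$treated, g$control), drop = FALSE])) == 0
  v <- v[complete, , drop = FALSE]
  if (nrow(v) == 0) stop("no complete-case peptide in the comparison")
  tr <- v[, g$treated, drop = FALSE]
  ct <- v[, g$control, drop = FALSE]
  fc <- rowMeans(tr) / rowMeans(ct)
  m <- if (center_stat == "arithmetic") mean(fc) else exp(mean(log(fc)))
  p_raw <- .row_t_test(tr, ct, var.equal = var.equal)
  centered <- abs(log2(m)) > exemption
  p_adj <- if (centered) .row_t_test(tr / m, ct, var.equal = var.equal) else p_raw
  out <- data.frame(key = rownames(v), p_raw = p_raw, p_mean_adjusted = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "mean_fc") <- m
  attr(out, "centered") <- centered
  out
}

#' Two-condition comparison: fold changes, significance and flags
#'
#' The per-peptide summary used to call treatment effects: log2 fold change
#' of mean intensities, raw unpaired two-sided t-test p value, mean-adjusted
#' p value ([mean_adjusted_test()]), and the standard flags —
#' `significantly_increased` (p_raw <= 0.05 and FC > 1) and
#' `significantly_enriched` (p_mean_adjusted <= 0.05).
#'
#' @inheritParams mean_adjusted_test
#' @param alpha Significance threshold for the flags (default 0.05).
#' @return Data frame of class `quant_comparison` with columns `key`,
#'   `log2_fc`, `p_raw`, `p_mean_adjusted`, `significantly_increased`,
#'   `significantly_enriched`; attributes `mean_fc`, `centered`,
#'   `group_sizes`.
#' @export
quant_comparison <- function(x, condition_map, treated, control,
                             use = c("adjusted", "raw"), exemption = 0.07,
                             center_stat = c("arithmetic", "geometric"),
                             var.equal = TRUE, alpha = 0.05) {
  use <- match.arg(use)
  if (use == "adjusted" && is.null(x$adjusted)) use <- "raw"
  fc <- fold_changes(x, condition_map, treated, control, use = use)
  mt <- mean_adjusted_test(x, condition_map, treated, control, use = use,
                           exemption = exemption, center_stat = center_stat,
                           var.equal = var.equal)
  out <- merge(fc[, c("key", "log2_fc")], mt, by = "key", sort = FALSE)
  out$significantly_increased <- out$p_raw <= alpha & out$log2_fc > 0
  out$significantly_enriched <- out$p_mean_adjusted <= alpha
  g <- .group_cols(x, condition_map, treated, control)
  attr(out, "mean_fc") <- attr(mt, "mean_fc")
  attr(out, "centered") <- attr(mt, "centered")
  attr(out, "group_sizes") <- c(treated = length(g$treated),
                                control = length(g$control))
  class(out) <- c("quant_comparison", "data.frame")
  out
}

#' @export
print.quant_comparison <- function(x, ...) {
  cat(sprintf(
    "quant_comparison: %d peptides (n = %d vs %d), mean FC %.3f, centering %s\n",
    nrow(x), attr(x, "group_sizes")[1], attr(x, "group_sizes")[2],
    attr(x, "mean_fc"),
    if (isTRUE(attr(x, "centered"))) "applied" else "skipped"))
  cat(sprintf("significantly increased: %d; significantly enriched: %d\n",
              sum(x$significantly_increased), sum(x$significantly_enriched)))
  invisible(x)
}

#' Coefficient-of-variation summary across replicate samples
#'
#' Per peptide, `CV = 100 * sd / mean` (sample SD, n - 1) across the listed
#' replicates, on complete cases; the median CV summarizes the run. Raw and
#' adjusted values are both summarized when available.
#'
#' @param x A `peptide_quant`.
#' @param samples Replicate sample/channel ids (>= 2); default all.
#' @return Object of class `cv_summary`: per-peptide CVs and medians for
#'   raw and (if present) adjusted values.
#' @export
cv_summary <- function(x, samples = x$samples) {
  if (length(samples) < 2) stop("need >= 2 replicate samples")
  xx <- completeness_mask(x, samples)
  cv_of <- function(m) {
    m <- m[, samples, drop = FALSE]
    100 * apply(m, 1, stats::sd) / rowMeans(m)
  }
  cv_raw <- cv_of(xx$raw)
  cv_adj <- if (!is.null(xx$adjusted)) cv_of(xx$adjusted) else NULL
  structure(list(cv_raw = cv_raw, cv_adjusted = cv_adj,
                 median_cv_raw = stats::median(cv_raw),
                 median_cv_adjusted = if (is.null(cv_adj)) NA_real_ else stats::median(cv_adj),
                 n_peptides = length(cv_raw)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("cv_summary over %d peptides: median CV raw %.2f%%", x$n_peptides,
              x$median_cv_raw))
  if (!is.na(x$median_cv_adjusted)) cat(sprintf(", adjusted %.2f%%",
                                                x$median_cv_adjusted))
  cat("\n")
  invisible(x)
}

#' Pooled log2 deviations of each value from its peptide mean
#'
#' For every complete-case peptide, `log2(value / mu)` where `mu` is that
#' peptide's mean across the listed samples; pooled over peptides and
#' samples. This is the ratio distribution whose Gaussian width bounds the
#' technical fold-change variation.
#'
#' @param x A `peptide_quant`.
#' @param samples Replicate ids; default all.
#' @param use `"adjusted"` or `"raw"`.
#' @return Numeric vector of log2 deviations.
#' @export
log2_deviations <- function(x, samples = x$samples, use = c("adjusted", "raw")) {
  use <- match.arg(use)
  if (use == "adjusted" && is.null(x$adjusted)) use <- "raw"
  xx <- completeness_mask(x, samples)
  v <- quant_values(xx, use)[, samples, drop = FALSE]
  as.numeric(log2(v / rowMeans(v)))
}

#' Gaussian bound on the fold-change distribution
#'
#' Fits a Gaussian to the histogram of pooled log2 ratios (least squares on
#' binned counts, Freedman-Diaconis bins) and reports the 3-sigma
#' fold-change bound `2^(3 sigma)`: the fold change from the mean within
#' which 99.7% of the technical variation falls. The direct sample SD is
#' reported alongside the histogram fit.
#'
#' @param ratios Pooled log2 deviations (see [log2_deviations()]); >= 30
#'   values unless degenerate.
#' @return List with `sigma` (histogram fit), `sigma_direct` (sample SD),
#'   `mean`, `fc_bound_3sd`, `fc_bound_3sd_direct`, `converged`.
#' @export
fc_distribution_bound <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (stats::sd(ratios) == 0) {
    return(list(sigma = 0, sigma_direct = 0, mean = mean(ratios),
                fc_bound_3sd = 1, fc_bound_3sd_direct = 1, converged = TRUE))
  }
  if (length(ratios) < 30) stop("need >= 30 ratios for a distribution fit")
  h <- graphics::hist(ratios, breaks = "FD", plot = FALSE)
  mid <- h$mids; counts <- h$counts
  sd0 <- stats::sd(ratios)
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ C * exp(-(mid - m)^2 / (2 * s^2)),
                      start = list(C = max(counts), m = mean(ratios), s = sd0),
                      lower = c(0, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sigma <- sd0; mu <- mean(ratios); converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    sigma <- abs(unname(cf["s"])); mu <- unname(cf["m"]); converged <- TRUE
  }
  list(sigma = sigma, sigma_direct = sd0, mean = mu,
       fc_bound_3sd = 2^(3 * sigma), fc_bound_3sd_direct = 2^(3 * sd0),
       converged = converged)
}
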