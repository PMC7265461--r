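# Correction factors from correction hipMHCs and dynamic-range suppression
# from titrated standards. Factors are defined as the multiplier applied to
# raw intensities, i.e. the reciprocal of the standards' observed ratio to
# the reference, so the reference sample/channel is the fixed frame.

.new_correction_factors <- function(method, reference, factors,
                                    standards_used = character(),
                                    n_standard_psms = NA_integer_,
                                    condition_scoped = FALSE,
                                    by_condition = NULL) {
  stopifnot(all(factors > 0))
  for (ref in reference) factors[ref] <- 1  # exact, not up to rounding
  structure(list(method = method, reference = reference, factors = factors,
                 standards_used = standards_used,
                 n_standard_psms = n_standard_psms,
                 condition_scoped = condition_scoped,
                 by_condition = by_condition),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("correction_factors (%s, reference %s%s):\n", x$method,
              paste(x$reference, collapse = "/"),
              if (x$condition_scoped) ", per condition" else ""))
  print(round(x$factors, 4))
  if (!is.na(x$n_standard_psms)) {
    cat(sprintf("from %d standard PSM(s): %s\n", x$n_standard_psms,
                paste(x$standards_used, collapse = ", ")))
  }
  invisible(x)
}

#' Restrict standard PSMs to the endogenous abundance window
#'
#' Reporter intensities of spiked standards well outside the endogenous
#' abundance regime drift the correction. Standard PSMs are kept only when
#' their mean reporter intensity lies within 10-fold of the interquartile
#' range of the endogenous per-PSM mean reporter intensities, i.e. inside
#' `[Q1/fold, Q3*fold]` (inclusive; linear-interpolation quantiles).
#'
#' @param standard_psms `psm_table` of standard PSMs (TMT mode).
#' @param endogenous_psms Non-empty `psm_table` of endogenous PSMs.
#' @param fold Window width on each side of the IQR; default 10.
#' @return The retained standard PSMs.
#' @export
abundance_window_filter <- function(standard_psms, endogenous_psms, fold = 10) {
  if (nrow(endogenous_psms) == 0) stop("endogenous PSM set is empty")
  endo_means <- .psm_mean_reporter(endogenous_psms)
  q <- stats::quantile(endo_means, c(0.25, 0.75), na.rm = TRUE, type = 7)
  window <- c(q[[1]] / fold, q[[2]] * fold)
  std_means <- .psm_mean_reporter(standard_psms)
  keep <- !is.na(std_means) & std_means >= window[1] & std_means <= window[2]
  if (nrow(standard_psms) > 0 && !any(keep)) {
    stop("all standard PSMs fall outside the endogenous abundance window [",
         signif(window[1], 4), ", ", signif(window[2], 4),
         "]; adjust the spiked amounts")
  }
  out <- standard_psms[keep, , drop = FALSE]
  attr(out, "window") <- window
  out
}

.reporter_matrix <- function(psms) {
  channels <- attr(psms, "channels")
  if (is.null(channels)) {
    cols <- grep("^reporter_", names(psms), value = TRUE)
    channels <- sub("^reporter_", "", cols)
  }
  m <- as.matrix(as.data.frame(psms)[, paste0("reporter_", channels), drop = FALSE])
  colnames(m) <- channels
  m
}

.psm_mean_reporter <- function(psms) {
  m <- .reporter_matrix(psms)
  if (nrow(m) == 0) return(numeric())
  rowMeans(m, na.rm = TRUE)
}

#' TMT correction factors from correction-standard PSMs
#'
#' For each retained correction-standard PSM, reporter intensities are
#' ratioed against the reference channel; the per-channel median of all
#' ratios (pooled across standards, charge states and fractions) determines
#' the final correction: `factor(c) = 1 / median(ratio(c))`, and
#' `factor(reference) = 1`.
#'
#' @param standard_psms Retained correction-standard PSMs
#'   (see [abundance_window_filter()]).
#' @param reference Reference channel label.
#' @param standards_used Optional spec ids for provenance.
#' @return A `correction_factors` object.
#' @export
compute_tmt_correction <- function(standard_psms, reference,
                                   standards_used = unique(standard_psms$sequence)) {
  m <- .reporter_matrix(standard_psms)
  if (!reference %in% colnames(m)) stop("reference channel '", reference,
                                        "' not present in reporter columns")
  ref <- m[, reference]
  bad <- is.na(ref) | ref <= 0
  if (any(bad)) {
    warning(sum(bad), " standard PSM(s) with missing/zero reference intensity excluded")
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no correction-standard PSM with positive reference intensity")
  ratios <- m / m[, reference]
  med <- apply(ratios, 2, stats::median, na.rm = TRUE)
  .new_correction_factors("tmt_median", reference, 1 / med,
                          standards_used = standards_used,
                          n_standard_psms = nrow(m))
}

#' Label-free correction factors from per-sample standard AUCs
#'
#' Per correction standard, the summed AUC in each sample is ratioed against
#' the reference sample; the factor for a sample is the reciprocal of the
#' mean ratio across standards. A standard missing in some sample is
#' excluded from that sample's mean with a warning.
#'
#' @param standard_auc Numeric matrix, standards x samples (rownames =
#'   standard ids, colnames = sample ids).
#' @param reference Reference sample id.
#' @return A `correction_factors` object.
#' @export
compute_lf_correction <- function(standard_auc, reference) {
  if (!reference %in% colnames(standard_auc)) {
    stop("reference sample '", reference, "' not in standard AUC matrix")
  }
  ref <- standard_auc[, reference]
  if (any(is.na(ref) | ref <= 0)) {
    stop("every correction standard must be quantified in the reference sample")
  }
  ratios <- standard_auc / ref
  if (anyNA(ratios)) {
    warning("standard(s) missing in some sample(s) excluded from those means")
  }
  mean_r <- colMeans(ratios, na.rm = TRUE)
  if (anyNA(mean_r) | any(!is.finite(mean_r))) {
    stop("a sample has no quantified correction standard")
  }
  .new_correction_factors("lf_mean", reference, 1 / mean_r,
                          standards_used = rownames(standard_auc),
                          n_standard_psms = NA_integer_)
}

#' Apply correction factors to a peptide table
#'
#' Fills the `adjusted` matrix: `adjusted(p, s) = raw(p, s) * factor(s)`;
#' raw values are retained.
#'
#' @param x A `peptide_quant`.
#' @param factors A `correction_factors` covering all samples of `x`.
#' @return The table with `adjusted` and `factors` set.
#' @export
apply_correction <- function(x, factors) {
  f <- factors$factors
  missing <- setdiff(x$samples, names(f))
  if (length(missing)) stop("no correction factor for: ",
                            paste(missing, collapse = ", "))
  x$adjusted <- sweep(x$raw, 2, f[x$samples], "*")
  x$factors <- factors
  x
}

#' Check whether per-condition correction is warranted
#'
#' Global correction standards can no longer correct between conditions when
#' the endogenous repertoire shifts more than about 2-fold between them
#' (e.g. interferon-gamma stimulation), because co-isolated endogenous
#' signal drags the standards' ratios toward the endogenous median. The
#' trigger fires when the absolute mean log2 fold change between the two
#' conditions exceeds `log2(2) = 1`.
#'
#' @param x A `peptide_quant` (raw values are used).
#' @param condition_map Named character: sample/channel -> condition.
#' @param treated,control Condition labels to compare.
#' @param threshold_log2 Trigger threshold on |mean log2 FC|; default 1.
#' @return List with `mean_log2_fc` and logical `triggered`.
#' @export
correction_trigger <- function(x, condition_map, treated, control,
                               threshold_log2 = 1) {
  fc <- fold_changes(x, condition_map, treated, control, use = "raw")
  m <- mean(fc$log2_fc)
  list(mean_log2_fc = m, triggered = abs(m) > threshold_log2)
}

#' Per-condition TMT correction factors
#'
#' Computes correction factors independently within each condition group,
#' each against its own reference channel. Used when the between-condition
#' shift trips [correction_trigger()].
#'
#' @param standard_psms Retained correction-standard PSMs.
#' @param condition_map Named character: channel -> condition (>= 2
#'   conditions, each with at least one channel).
#' @param references Named character: condition -> reference channel.
#' @return A `correction_factors` object with `condition_scoped = TRUE`;
#'   `$factors` covers all channels, `$by_condition` holds the per-condition
#'   objects.
#' @export
per_condition_correction <- function(standard_psms, condition_map, references) {
  conds <- unique(condition_map)
  if (length(conds) < 2) stop("condition_map must define >= 2 conditions")
  missing_ref <- setdiff(conds, names(references))
  if (length(missing_ref)) stop("no reference channel for condition(s): ",
                                paste(missing_ref, collapse = ", "))
  by_cond <- lapply(stats::setNames(nm = conds), function(cc) {
    ch <- names(condition_map)[condition_map == cc]
    if (length(ch) < 1) stop("condition '", cc, "' has no channel")
    sub <- standard_psms
    keep_cols <- !grepl("^reporter_", names(sub)) |
      names(sub) %in% paste0("reporter_", ch)
    sub <- sub[, keep_cols, drop = FALSE]
    attr(sub, "channels") <- ch
    attr(sub, "mode") <- "tmt"
    class(sub) <- c("psm_table", "data.frame")
    compute_tmt_correction(sub, references[[cc]])
  })
  factors <- unlist(lapply(by_cond, `[[`, "factors"))
  names(factors) <- unlist(lapply(by_cond, function(f) names(f$factors)))
  .new_correction_factors("tmt_median",
                          reference = vapply(by_cond, `[[`, "", "reference"),
                          factors = factors,
                          standards_used = unique(standard_psms$sequence),
                          n_standard_psms = sum(vapply(by_cond, `[[`, 0L,
                                                       "n_standard_psms")),
                          condition_scoped = TRUE, by_condition = by_cond)
}

#' Estimate dynamic-range suppression from a titrated standard
#'
#' A standard titrated across samples probes how far measured fold changes
#' are compressed relative to the spiked amounts. The suppression factor is
#' the expected fold range (max/min spiked fmol) divided by the observed
#' fold range of the adjusted intensities at those extreme points; values
#' above 1 mean the measured differences understate the true ones. An OLS
#' fit of intensity versus fmol is reported for raw and adjusted values.
#'
#' @param amounts_fmol Named numeric: sample/channel -> spiked fmol
#'   (>= 2 distinct values).
#' @param adjusted Named numeric: normalized intensity per sample/channel.
#' @param raw Optional named numeric of raw intensities (for `fit_r2_raw`).
#' @param method `"extremes"` (ratio of the extreme titration points,
#'   default) or `"slope"` (fold range of the fitted line at the extremes).
#' @param id Standard identifier for provenance.
#' @return Object of class `suppression_estimate` with `expected_fold`,
#'   `observed_fold`, `suppression`, `fit_r2_adjusted`, `fit_r2_raw`.
#' @export
estimate_suppression <- function(amounts_fmol, adjusted, raw = NULL,
                                 method = c("extremes", "slope"), id = NULL) {
  method <- match.arg(method)
  common <- intersect(names(amounts_fmol), names(adjusted))
  if (length(unique(amounts_fmol[common])) < 2) {
    stop("need >= 2 distinct spiked amounts observed")
  }
  a <- amounts_fmol[common]
  y <- adjusted[common]
  i_min <- which.min(a); i_max <- which.max(a)
  expected_fold <- a[[i_max]] / a[[i_min]]
  fit <- stats::lm(y ~ a)
  r2_adj <- suppressWarnings(summary(fit)$r.squared)
  r2_raw <- if (!is.null(raw)) {
    suppressWarnings(summary(stats::lm(raw[common] ~ a))$r.squared)
  } else NA_real_
  if (method == "extremes") {
    if (y[[i_min]] <= 0) stop("intensity at the minimum titration point must be > 0")
    observed_fold <- y[[i_max]] / y[[i_min]]
  } else {
    pred <- stats::predict(fit, data.frame(a = c(a[[i_min]], a[[i_max]])))
    if (pred[1] <= 0) stop("fitted intensity at the minimum titration point must be > 0")
    observed_fold <- pred[2] / pred[1]
  }
  structure(list(id = id, method = method,
                 expected_fold = unname(expected_fold),
                 observed_fold = unname(observed_fold),
                 suppression = unname(expected_fold / observed_fold),
                 fit_r2_adjusted = r2_adj, fit_r2_raw = r2_raw,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "suppression_estimate")
}

#' @export
print.suppression_estimate <- function(x, ...) {
  cat(sprintf(
    "suppression_estimate%s: expected %.3gx, observed %.3gx -> %.2fx suppression\n",
    if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
    x$expected_fold, x$observed_fold, x$suppression))
  cat(sprintf("linear fit r2: adjusted %.4f%s\n", x$fit_r2_adjusted,
              if (is.na(x$fit_r2_raw)) "" else sprintf(", raw %.4f", x$fit_r2_raw)))
  invisible(x)
}
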