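# Targeted absolute quantification: Gaussian elution-profile fitting, the
# embedded hipMHC calibration curve, and conversion to copies per cell.

#' Avogadro's number (exact, 2019 SI definition)
#' @export
AVOGADRO <- 6.02214076e23

#' Fit a Gaussian to a chromatographic elution profile
#'
#' Nonlinear least squares of `I(t) = A * exp(-(t - mu)^2 / (2 sigma^2))`
#' over per-scan reporter intensities. Initial values: `mu` at the
#' maximum-intensity scan, `A` at the maximum intensity, `sigma` from the
#' full width at half maximum. The apex is the fitted amplitude `A`; if the
#' fit fails to converge, the apex falls back to the tallest observed scan
#' and the result is flagged.
#'
#' @param rt Retention times (seconds), >= 4 points.
#' @param intensity Reporter intensities; at least one must be positive.
#' @param offset If `TRUE`, add a constant baseline term `c` to the model.
#' @return List with `A`, `mu`, `sigma`, `apex`, `offset`, `residual_norm`,
#'   `converged`, `fallback`.
#' @export
fit_gaussian_profile <- function(rt, intensity, offset = FALSE) {
  stopifnot(length(rt) == length(intensity))
  keep <- !is.na(rt) & !is.na(intensity)
  rt <- rt[keep]; intensity <- intensity[keep]
  if (length(rt) < 4) stop("need >= 4 scans to fit an elution profile")
  if (all(intensity <= 0)) stop("all-zero elution profile")
  ord <- order(rt)
  rt <- rt[ord]; intensity <- intensity[ord]

  i0 <- which.max(intensity)
  A0 <- intensity[i0]
  mu0 <- rt[i0]
  above <- rt[intensity >= A0 / 2]
  fwhm <- diff(range(above))
  sigma0 <- if (fwhm > 0) fwhm / (2 * sqrt(2 * log(2))) else diff(range(rt)) / 6
  if (sigma0 <= 0) sigma0 <- 1

  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(
        intensity ~ A * exp(-(rt - mu)^2 / (2 * sigma^2)) + c0,
        start = list(A = A0, mu = mu0, sigma = sigma0, c0 = min(intensity)),
        lower = c(0, min(rt) - fwhm, 1e-9, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        intensity ~ A * exp(-(rt - mu)^2 / (2 * sigma^2)),
        start = list(A = A0, mu = mu0, sigma = sigma0),
        lower = c(0, min(rt) - fwhm, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)

  if (is.null(fit)) {
    return(list(A = NA_real_, mu = mu0, sigma = NA_real_, apex = A0,
                offset = 0, residual_norm = NA_real_,
                converged = FALSE, fallback = TRUE))
  }
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), mu = unname(cf["mu"]), sigma = unname(cf["sigma"]),
       apex = unname(cf["A"]),
       offset = if (offset) unname(cf["c0"]) else 0,
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       converged = TRUE, fallback = FALSE)
}

#' Build an embedded calibration curve
#'
#' Ordinary least squares of adjusted (normalization-corrected) apex
#' intensity on spiked fmol; the fitted line back-calculates endogenous
#' femtomoles from measured apexes.
#'
#' @param fmol Spiked amounts (>= 2 distinct values).
#' @param apex Adjusted apex intensities, same length.
#' @param id Calibrant identifier.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r2`, `points`, and the underlying `lm` fit.
#' @export
build_calibration_curve <- function(fmol, apex, id = NULL) {
  stopifnot(length(fmol) == length(apex))
  if (length(unique(fmol)) < 2) stop("calibration needs >= 2 distinct fmol points")
  fit <- stats::lm(apex ~ fmol)
  cf <- stats::coef(fit)
  structure(list(id = id, slope = unname(cf[2]), intercept = unname(cf[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 points = data.frame(fmol = fmol, apex = apex),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve%s: apex = %.4g * fmol + %.4g (r2 = %.6f, %d points)\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$slope, x$intercept, x$r2, nrow(x$points)))
  invisible(x)
}

#' Back-calculate endogenous femtomoles from a calibration curve
#'
#' `fmol = (apex - intercept) / slope`; negative back-calculations are
#' clamped to zero and flagged in the `clamped` attribute.
#'
#' @param curve A [build_calibration_curve()] result with positive slope.
#' @param apex Adjusted apex intensity per replicate.
#' @return Numeric fmol per replicate, attribute `clamped` (logical).
#' @export
quantify_endogenous <- function(curve, apex) {
  if (!inherits(curve, "calibration_curve")) stop("curve must be a calibration_curve")
  if (curve$slope <= 0) stop("calibration curve has non-positive slope")
  fmol <- (apex - curve$intercept) / curve$slope
  clamped <- fmol < 0
  if (any(clamped)) {
    warning(sum(clamped), " replicate(s) below the calibration intercept clamped to 0 fmol")
    fmol[clamped] <- 0
  }
  attr(fmol, "clamped") <- clamped
  fmol
}

#' Convert femtomoles to copies per cell
#'
#' `copies = fmol * 1e-15 * N_A / n_cells` with Avogadro's number
#' `N_A = 6.02214076e23`; 0.1 fmol over 1e7 cells is about 6 copies per
#' cell.
#'
#' @param fmol Amount in femtomoles (>= 0).
#' @param n_cells Number of cells the sample was prepared from (> 0).
#' @return Copies per cell.
#' @export
copies_per_cell <- function(fmol, n_cells) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0")
  if (any(fmol < 0)) stop("fmol must be >= 0")
  fmol * 1e-15 * AVOGADRO / n_cells
}

#' Correction factors for a targeted run from its normalization standards
#'
#' Fits the elution profile of each normalization-standard trace per
#' channel, then derives median-of-ratios correction factors from the apex
#' intensities with the same algorithm as [compute_tmt_correction()] (each
#' standard's apex row plays the role of one PSM).
#'
#' @param scans Scan-level reporter table (`target`, `rt_sec`,
#'   `reporter_<label>` columns).
#' @param standard_targets `target` values of the normalization-standard
#'   traces.
#' @param reference Reference channel label.
#' @return A `correction_factors` object.
#' @export
targeted_correction <- function(scans, standard_targets, reference) {
  cols <- grep("^reporter_", names(scans), value = TRUE)
  channels <- sub("^reporter_", "", cols)
  apex_rows <- lapply(standard_targets, function(tg) {
    sub <- scans[scans$target == tg, , drop = FALSE]
    if (nrow(sub) == 0) stop("no scans for normalization standard '", tg, "'")
    vapply(cols, function(cc) fit_gaussian_profile(sub$rt_sec, sub[[cc]])$apex,
           numeric(1))
  })
  m <- do.call(rbind, apex_rows)
  df <- as.data.frame(m)
  names(df) <- cols
  df$sequence <- standard_targets
  psms <- .as_psm_table(df, "tmt", channels = channels)
  compute_tmt_correction(psms, reference, standards_used = standard_targets)
}

#' Absolute quantification of a target from a scan-level reporter table
#'
#' Full targeted loop: per channel, the MS2 scan trace of the heavy
#' calibrant target is fitted with a Gaussian ([fit_gaussian_profile()]);
#' apexes are adjusted by the run's correction factors; the calibrant
#' channels form the embedded curve; the endogenous (light) target's
#' adjusted apexes are back-calculated to fmol and converted to copies per
#' cell.
#'
#' @param scans Data frame with columns `target`, `rt_sec`, and
#'   `reporter_<label>` columns.
#' @param calibrant_target Value of `target` identifying the heavy calibrant
#'   trace.
#' @param endogenous_target Value of `target` identifying the light
#'   endogenous trace.
#' @param calibrant_fmol Named numeric: channel -> spiked fmol (the
#'   calibration channels).
#' @param endogenous_channels Channels holding the endogenous replicates.
#' @param factors Optional `correction_factors` applied to the apexes.
#' @param n_cells Cells per sample.
#' @return Object of class `copies_per_cell_result` with per-replicate fmol
#'   and copies, their mean and SD, and the `calibration_curve`.
#' @export
absolute_quantify <- function(scans, calibrant_target, endogenous_target,
                              calibrant_fmol, endogenous_channels,
                              factors = NULL, n_cells) {
  apexes <- function(target, channels) {
    sub <- scans[scans$target == target, , drop = FALSE]
    if (nrow(sub) == 0) stop("no scans for target '", target, "'")
    vapply(channels, function(ch) {
      y <- sub[[paste0("reporter_", ch)]]
      if (all(is.na(y) | y <= 0)) return(0)  # channel without signal
      fit_gaussian_profile(sub$rt_sec, y)$apex
    }, numeric(1))
  }
  adj <- function(apex, channels) {
    if (is.null(factors)) return(apex)
    f <- factors$factors[channels]
    if (anyNA(f)) stop("missing correction factor for a targeted channel")
    apex * f
  }
  cal_ch <- names(calibrant_fmol)
  cal_apex <- adj(apexes(calibrant_target, cal_ch), cal_ch)
  curve <- build_calibration_curve(unname(calibrant_fmol), unname(cal_apex),
                                   id = calibrant_target)
  endo_apex <- adj(apexes(endogenous_target, endogenous_channels),
                   endogenous_channels)
  fmol <- quantify_endogenous(curve, unname(endo_apex))
  copies <- copies_per_cell(as.numeric(fmol), n_cells)
  structure(list(target = endogenous_target, curve = curve,
                 replicates = data.frame(channel = endogenous_channels,
                                         apex = unname(endo_apex),
                                         fmol = as.numeric(fmol),
                                         copies_per_cell = copies),
                 fmol_mean = mean(fmol), fmol_sd = stats::sd(fmol),
                 copies_mean = mean(copies), copies_sd = stats::sd(copies),
                 n_cells = n_cells),
            class = "copies_per_cell_result")
}

#' @export
print.copies_per_cell_result <- function(x, ...) {
  cat(sprintf("copies_per_cell_result [%s]: %.3g +/- %.3g copies/cell (%.4g +/- %.2g fmol, n = %d)\n",
              x$target, x$copies_mean,
              ifelse(is.na(x$copies_sd), 0, x$copies_sd),
              x$fmol_mean, ifelse(is.na(x$fmol_sd), 0, x$fmol_sd),
              nrow(x$replicates)))
  cat(sprintf("calibration: r2 = %.6f over %d points\n", x$curve$r2,
              nrow(x$curve$points)))
  invisible(x)
}
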