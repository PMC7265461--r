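# Seeded simulator for PSM tables and targeted scan-level runs with known
# ground truth. The generative model is multiplicative: every intensity is
# base abundance x condition fold change (compressed by suppression) x
# per-sample loss factor x PSM share x lognormal reporter noise. Spiked
# standards run through exactly the same loss/noise path as endogenous
# peptides - the premise that makes internal-standard correction work.

#' Default hipMHC standard panel for a simulated run
#'
#' Two quantification-correction standards spiked at 30 fmol everywhere and
#' one standard titrated from 30 to 300 fmol across samples, mirroring the
#' reference experimental design.
#'
#' @param ids Sample/channel labels in order.
#' @return List of [hipmhc_spec()] objects.
#' @export
default_hipmhc_standards <- function(ids) {
  titr <- c(30, 60, 100, 150, 200, 300)
  titr <- stats::setNames(titr[round(seq(1, 6, length.out = length(ids)))], ids)
  list(
    hipmhc_spec("ALNEQIARL", 9, "correction",
                stats::setNames(rep(30, length(ids)), ids)),
    hipmhc_spec("SLEEPIGHL", 9, "correction",
                stats::setNames(rep(30, length(ids)), ids)),
    hipmhc_spec("SVVESVKFL", 9, "titration", titr)
  )
}

#' Simulation configuration
#'
#' Defines the conditions a simulated experiment emulates: a 6-plex (or
#' label-free series) of technical/biological replicates with per-sample
#' loss factors, lognormal reporter noise, Poisson PSM multiplicity,
#' power-law dynamic-range suppression and a spiked hipMHC panel.
#'
#' @param mode `"tmt"` or `"lf"`.
#' @param n_peptides Number of endogenous peptides.
#' @param ids Channel labels (TMT) or sample ids (LF).
#' @param conditions Named character: id -> condition label; default all
#'   `"replicate"`.
#' @param reference Reference id for normalization.
#' @param loss_factors Named multiplicative per-sample losses `k_s` (> 0);
#'   default all 1.
#' @param sigma_log2 SD (log2) of the lognormal noise applied independently
#'   to every reporter/AUC measurement; default 0.2.
#' @param psm_scale_sd SD (log2) of the relative PSM-share scatter within a
#'   peptide; default 0.5.
#' @param psms_per_peptide Mean PSMs per endogenous peptide
#'   (`1 + Poisson(mean - 1)`).
#' @param standard_psms PSMs per standard peptide; default 10.
#' @param suppression Dynamic-range suppression exponent gamma >= 1:
#'   observed fold ranges are `expected^(1/gamma)`; default 1 (none).
#' @param standards List of [hipmhc_spec()]; default
#'   [default_hipmhc_standards()].
#' @param n_cells Cells per sample (absolute quantification); default 1e7.
#' @param base_meanlog,base_sdlog Lognormal (natural log) parameters of the
#'   endogenous base-abundance distribution.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(mode = c("tmt", "lf"), n_peptides = 2000,
                              ids = paste0("TMT", 126:131),
                              conditions = NULL, reference = ids[1],
                              loss_factors = NULL, sigma_log2 = 0.2,
                              psm_scale_sd = 0.5, psms_per_peptide = 2,
                              standard_psms = 10, suppression = 1,
                              standards = NULL, n_cells = 1e7,
                              base_meanlog = log(1e6), base_sdlog = 2) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  if (is.null(conditions)) {
    conditions <- stats::setNames(rep("replicate", length(ids)), ids)
  }
  if (is.null(loss_factors)) loss_factors <- stats::setNames(rep(1, length(ids)), ids)
  loss_factors <- loss_factors[ids]
  if (anyNA(loss_factors) || any(loss_factors <= 0)) {
    stop("loss_factors must be positive and cover every sample/channel")
  }
  if (sigma_log2 < 0) stop("sigma_log2 must be >= 0")
  if (suppression < 1) stop("suppression exponent must be >= 1")
  if (!reference %in% ids) stop("reference must be one of the sample/channel ids")
  if (is.null(standards)) standards <- default_hipmhc_standards(ids)
  structure(list(mode = mode, n_peptides = n_peptides, ids = ids,
                 conditions = conditions[ids], reference = reference,
                 loss_factors = loss_factors, sigma_log2 = sigma_log2,
                 psm_scale_sd = psm_scale_sd,
                 psms_per_peptide = psms_per_peptide,
                 standard_psms = standard_psms, suppression = suppression,
                 standards = standards, n_cells = n_cells,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog),
            class = "simulation_config")
}

.random_peptides <- function(n, length = 9, avoid = character()) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2), function(i) {
      paste(sample(aa, length, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, setdiff(cand, avoid)))
  }
  out[seq_len(n)]
}

.noise2 <- function(n, sigma_log2) {
  if (sigma_log2 == 0) rep(1, n) else 2^stats::rnorm(n, 0, sigma_log2)
}

# normalized PSM shares: always sum to 1, so aggregation conserves the
# peptide-level intensity and noise-free runs are exact
.psm_shares <- function(n, sd_log2) {
  u <- .noise2(n, sd_log2)
  u / sum(u)
}

#' Generate a multiplexed (or label-free) replicate experiment
#'
#' Endogenous base abundances are drawn lognormal; each sample's value is
#' `base x fold^(1/gamma) x k_s x noise`, split over a Poisson number of
#' PSMs. Standards are injected at their configured fmol through the same
#' loss and noise path; alternating standard PSMs carry the C-terminal
#' amidation variant. Fully reproducible from `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param log2_fc Optional per-peptide true log2 fold change applied to the
#'   channels of `treated_condition` (length `n_peptides`); default none.
#' @param treated_condition Condition label receiving `log2_fc`.
#' @param global_log2_shift Additional uniform log2 shift applied to the
#'   treated condition's endogenous peptides (not the standards).
#' @return List with `psms` (a `psm_table`) and `truth` (loss factors, base
#'   abundances, per-peptide fold changes, standard amounts, seed).
#' @export
generate_replicate_experiment <- function(config, seed = 1, log2_fc = NULL,
                                          treated_condition = NULL,
                                          global_log2_shift = 0) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  ids <- config$ids
  n_id <- length(ids)
  gamma <- config$suppression
  std_seqs <- vapply(config$standards, `[[`, "", "sequence")
  peptides <- .random_peptides(config$n_peptides, avoid = std_seqs)
  base <- stats::rlnorm(config$n_peptides, config$base_meanlog, config$base_sdlog)
  if (is.null(log2_fc)) log2_fc <- rep(0, config$n_peptides)
  stopifnot(length(log2_fc) == config$n_peptides)

  treated_ids <- if (is.null(treated_condition)) character() else
    ids[config$conditions == treated_condition]
  # per-peptide per-sample expected fold, compressed by suppression
  fold <- matrix(1, config$n_peptides, n_id, dimnames = list(peptides, ids))
  if (length(treated_ids)) {
    f <- 2^(log2_fc + global_log2_shift)
    fold[, treated_ids] <- f^(1 / gamma)
  }

  rows <- vector("list", config$n_peptides + length(config$standards))
  for (p in seq_len(config$n_peptides)) {
    n_psm <- 1 + stats::rpois(1, max(config$psms_per_peptide - 1, 0))
    w <- .psm_shares(n_psm, config$psm_scale_sd)
    level <- base[p] * fold[p, ] * config$loss_factors        # per id
    rows[[p]] <- .sim_psm_rows(config, peptides[p], "", n_psm, w, level)
  }
  # standards: intensity ~ response x (amount/amin)^(1/gamma), median-scale
  amounts <- lapply(config$standards, `[[`, "amounts_fmol")
  for (h in seq_along(config$standards)) {
    s <- config$standards[[h]]
    a <- s$amounts_fmol[ids]
    a_min <- min(a)
    response <- exp(config$base_meanlog) / a_min
    level <- response * a_min * (a / a_min)^(1 / gamma) * config$loss_factors
    n_psm <- config$standard_psms
    w <- .psm_shares(n_psm, config$psm_scale_sd)
    mods <- paste0("heavy_leu@", s$heavy_positions[1])
    mods <- ifelse(seq_len(n_psm) %% 2 == 0,
                   paste0(mods, ";amidated@", nchar(s$sequence)), mods)
    rows[[config$n_peptides + h]] <-
      .sim_psm_rows(config, s$sequence, mods, n_psm, w, level)
  }
  psms <- do.call(rbind, rows)
  psms$scan <- seq_len(nrow(psms))
  psms <- .as_psm_table(psms, config$mode,
                        channels = if (config$mode == "tmt") ids else NULL)
  truth <- list(seed = seed, loss_factors = config$loss_factors,
                base_abundance = stats::setNames(base, peptides),
                log2_fc = stats::setNames(log2_fc, peptides),
                treated_ids = treated_ids,
                global_log2_shift = global_log2_shift,
                suppression = gamma,
                standard_amounts = stats::setNames(amounts, std_seqs))
  list(psms = psms, truth = truth)
}

# one peptide's PSM rows; `level` is the per-id expected intensity and
# `mods` is recycled over PSMs
.sim_psm_rows <- function(config, sequence, mods, n_psm, w, level) {
  ids <- config$ids
  meta <- data.frame(
    sequence = rep(sequence, n_psm),
    modifications = rep(mods, length.out = n_psm),
    charge = 2L,
    ion_score = stats::runif(n_psm, 30, 80),
    percolator_q = stats::runif(n_psm, 0, 0.04),
    isolation_interference_pct = stats::runif(n_psm, 0, 25),
    search_rank = 1L,
    fraction_id = paste0("f", 1 + (seq_len(n_psm) - 1) %% 2),
    rt_sec = stats::runif(n_psm, 600, 7000),
    scan = NA_integer_,
    stringsAsFactors = FALSE)
  if (config$mode == "tmt") {
    meta$sample_id <- "plex1"
    rep_mat <- outer(w, level) *
      matrix(.noise2(n_psm * length(ids), config$sigma_log2), n_psm)
    colnames(rep_mat) <- paste0("reporter_", ids)
    cbind(meta, as.data.frame(rep_mat))
  } else {
    # LF: each sample is a separate analysis with its own PSMs
    out <- do.call(rbind, lapply(seq_along(ids), function(j) {
      m <- meta
      m$sample_id <- ids[j]
      m$auc <- w * level[j] * .noise2(n_psm, config$sigma_log2)
      m
    }))
    rownames(out) <- NULL
    out
  }
}

#' Generate a two-condition comparison with known effects
#'
#' Three-versus-three (by default) comparison with no condition effect
#' except `n_true_effects` spiked peptides at `effect_log2fc` and an
#' optional uniform shift of the treated condition; used to calibrate the
#' type-I error and mean-centering behavior of the differential statistics.
#'
#' @param config A [simulation_config()]; its `ids` are split in half into
#'   `control` then `treated` unless `conditions` already defines the two
#'   groups.
#' @param seed Integer seed.
#' @param n_true_effects Number of peptides given a real effect (the first
#'   `n_true_effects` peptides).
#' @param effect_log2fc True log2 FC of the spiked effects.
#' @param global_log2_shift Uniform log2 shift of all treated endogenous
#'   peptides.
#' @return As [generate_replicate_experiment()]; conditions are in
#'   `attr(result$psms, "conditions")` and `result$condition_map`.
#' @export
generate_null_comparison <- function(config, seed = 1, n_true_effects = 0,
                                     effect_log2fc = 2, global_log2_shift = 0) {
  ids <- config$ids
  if (length(unique(config$conditions)) != 2) {
    half <- length(ids) %/% 2
    config$conditions <- stats::setNames(
      rep(c("control", "treated"), c(half, length(ids) - half)), ids)
  }
  treated <- setdiff(unique(config$conditions), "control")[1]
  log2_fc <- rep(0, config$n_peptides)
  if (n_true_effects > 0) {
    log2_fc[seq_len(min(n_true_effects, config$n_peptides))] <- effect_log2fc
  }
  out <- generate_replicate_experiment(config, seed = seed, log2_fc = log2_fc,
                                       treated_condition = treated,
                                       global_log2_shift = global_log2_shift)
  out$condition_map <- config$conditions
  out
}

#' Generate a targeted scan-level run with an embedded calibration curve
#'
#' Emulates a targeted absolute-quantification analysis: Gaussian elution
#' profiles (shared retention center and width) sampled at a fixed scan
#' cadence, with channel amplitudes proportional to the spiked calibrant
#' amounts, the endogenous level, and the per-channel loss factors; two
#' normalization standards at equal amounts ride along for correction.
#'
#' @param seed Integer seed.
#' @param calibrant_fmol Named numeric: channel -> spiked calibrant fmol
#'   (default the 0.3/1/3 fmol series on the first three channels).
#' @param endogenous_fmol True endogenous amount E (fmol).
#' @param endogenous_channels Channels carrying the endogenous replicates.
#' @param loss_factors Named per-channel losses over all channels.
#' @param noise_cv Relative (lognormal) noise per scan point; 0.05 = 5%.
#' @param response Apex intensity per fmol at the detector.
#' @param rt_center,rt_sigma Elution center and width (seconds).
#' @param scan_interval Seconds between MS2 scans.
#' @param n_cells Cells per sample.
#' @param calibrant_sequence Heavy target peptide sequence.
#' @return List with `scans` (data frame: target, scan, rt_sec,
#'   reporter_*), `norm_targets` (names of the normalization-standard
#'   traces) and `truth`.
#' @export
generate_targeted_run <- function(seed = 1,
                                  calibrant_fmol = c(TMT126 = 0.3, TMT127 = 1,
                                                     TMT128 = 3),
                                  endogenous_fmol = 0.81,
                                  endogenous_channels = paste0("TMT", 129:131),
                                  loss_factors = NULL, noise_cv = 0,
                                  response = 1e6, rt_center = 600,
                                  rt_sigma = 8, scan_interval = 3,
                                  n_cells = 1e7,
                                  calibrant_sequence = "KQVSDLISV") {
  set.seed(seed)
  channels <- unique(c(names(calibrant_fmol), endogenous_channels))
  if (is.null(loss_factors)) {
    loss_factors <- stats::setNames(rep(1, length(channels)), channels)
  }
  if (!all(channels %in% names(loss_factors))) {
    stop("loss_factors must cover every channel")
  }
  if (endogenous_fmol > 0 &&
      (endogenous_fmol < min(calibrant_fmol) ||
       endogenous_fmol > max(calibrant_fmol))) {
    warning("endogenous amount is not bracketed by the calibrant series")
  }
  n_side <- floor(4 * rt_sigma / scan_interval)
  rt <- rt_center + seq(-n_side, n_side) * scan_interval
  trace <- function(target, fmol_by_channel) {
    amp <- response * fmol_by_channel[channels] * loss_factors[channels]
    amp[is.na(amp)] <- 0
    m <- vapply(seq_along(channels), function(j) {
      prof <- amp[j] * exp(-(rt - rt_center)^2 / (2 * rt_sigma^2))
      if (noise_cv > 0) prof <- prof * exp(stats::rnorm(length(rt), 0, noise_cv))
      prof
    }, numeric(length(rt)))
    colnames(m) <- paste0("reporter_", channels)
    cbind(data.frame(target = target, scan = seq_along(rt), rt_sec = rt,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  }
  endo <- stats::setNames(rep(0, length(channels)), channels)
  endo[endogenous_channels] <- endogenous_fmol
  norm_amt <- stats::setNames(rep(30, length(channels)), channels)
  scans <- rbind(
    trace(paste0(calibrant_sequence, "_heavy"), calibrant_fmol),
    trace(calibrant_sequence, endo),
    trace("ALNEQIARL_heavy", norm_amt),
    trace("SLEEPIGHL_heavy", norm_amt))
  list(scans = scans,
       norm_targets = c("ALNEQIARL_heavy", "SLEEPIGHL_heavy"),
       truth = list(seed = seed, endogenous_fmol = endogenous_fmol,
                    calibrant_fmol = calibrant_fmol,
                    loss_factors = loss_factors, response = response,
                    copies_per_cell = copies_per_cell(endogenous_fmol, n_cells),
                    n_cells = n_cells))
}
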