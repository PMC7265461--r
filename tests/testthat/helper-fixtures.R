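# In-code fixtures shared across tests.

# minimal TMT psm_table built by hand
make_tmt_psms <- function(rows, channels = c("TMT126", "TMT127")) {
  defaults <- list(sequence = "AAAAAAAAA", modifications = "", charge = 2,
                   ion_score = 50, percolator_q = 0.01,
                   isolation_interference_pct = 5, search_rank = 1,
                   sample_id = "plex1", fraction_id = "f1", rt_sec = 1000,
                   scan = 1)
  df <- do.call(rbind, lapply(rows, function(r) {
    row <- utils::modifyList(defaults, r[setdiff(names(r), "reporter")])
    rep <- r$reporter
    stopifnot(length(rep) == length(channels))
    row <- c(row, as.list(stats::setNames(rep, paste0("reporter_", channels))))
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  hipquant:::.as_psm_table(df, "tmt", channels = channels)
}

make_lf_psms <- function(rows) {
  defaults <- list(sequence = "AAAAAAAAA", modifications = "", charge = 2,
                   ion_score = 50, percolator_q = NA_real_,
                   isolation_interference_pct = NA_real_, search_rank = 1,
                   sample_id = "s1", fraction_id = "f1", rt_sec = 1000,
                   scan = 1, auc = 100)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
  hipquant:::.as_psm_table(df, "lf")
}

# assemble the correction-standard PSM subset of a simulated experiment,
# pooled across the correction specs and window-filtered
pooled_correction_psms <- function(sim, cfg, window = TRUE) {
  filt <- filter_psms(sim$psms)
  part <- match_standards(filt$psms, cfg$standards)
  corr <- vapply(cfg$standards, function(s) s$role == "correction", logical(1))
  ids <- vapply(cfg$standards[corr], `[[`, "", "sequence")
  std <- pool_standard_psms(part, ids)
  if (window) std <- abundance_window_filter(std, part$endogenous)
  list(standards = std, endogenous = part$endogenous, partition = part)
}

# independent enrichment-score oracle: direct scalar enumeration of the
# running sum, sharing no code with the package implementation
brute_force_es <- function(scores, set, w = 1) {
  scores <- scores[order(-scores, names(scores))]
  hit <- names(scores) %in% set
  nr <- sum(abs(scores[hit])^w)
  run <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_along(scores)) {
    run <- run + if (hit[i]) {
      if (nr > 0) abs(scores[[i]])^w / nr else 1 / sum(hit)
    } else {
      -1 / (length(scores) - sum(hit))
    }
    hi <- max(hi, run); lo <- min(lo, run)
  }
  if (hi + lo > 1e-12) hi else lo   # tie resolves to the negative extreme
}

write_yaml_config <- function(text) {
  path <- tempfile(fileext = ".yaml")
  writeLines(text, path)
  path
}
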