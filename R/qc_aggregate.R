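# Post-search PSM filtering and aggregation to a peptide x sample matrix.

#' Post-search PSM filter policy
#'
#' Thresholds applied to identified PSMs before quantification. Defaults are
#' the standard MHC class I criteria: search-engine rank 1, isolation
#' interference at most 30%, peptide length 8-15, minimum ion score 20
#' (label-free) or 15 plus percolator q <= 0.05 (TMT). All thresholds are
#' inclusive.
#'
#' @param mode `"tmt"` or `"lf"`.
#' @param min_ion_score Minimum Mascot ion score.
#' @param max_isolation_interference Maximum isolation interference, percent.
#' @param max_percolator_q Maximum percolator q value (TMT only; `NA`
#'   disables the rule).
#' @param length_range Inclusive peptide length bounds.
#' @param require_rank1 Keep only search-engine rank 1 PSMs.
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(mode = c("tmt", "lf"),
                          min_ion_score = if (mode[1] == "lf") 20 else 15,
                          max_isolation_interference = 30,
                          max_percolator_q = if (mode[1] == "tmt") 0.05 else NA,
                          length_range = c(8, 15),
                          require_rank1 = TRUE) {
  mode <- match.arg(mode)
  stopifnot(min_ion_score >= 0, max_isolation_interference >= 0,
            length(length_range) == 2, length_range[1] <= length_range[2])
  structure(list(mode = mode, min_ion_score = min_ion_score,
                 max_isolation_interference = max_isolation_interference,
                 max_percolator_q = max_percolator_q,
                 length_range = length_range, require_rank1 = require_rank1),
            class = "filter_policy")
}

#' Filter PSMs by the post-search policy
#'
#' A record survives iff it passes every applicable rule. Rules with missing
#' inputs (e.g. absent percolator q in LF data) do not reject. Each rejected
#' record is tallied under the first rule it fails, so the tally sums to the
#' rejected count.
#'
#' @param psms A `psm_table`.
#' @param policy A [filter_policy()]; must match the table's mode.
#' @return List with `psms` (surviving records) and `tally` (named integer
#'   rejections per rule).
#' @export
filter_psms <- function(psms, policy = filter_policy(attr(psms, "mode"))) {
  mode <- attr(psms, "mode")
  if (!is.null(mode) && !identical(mode, policy$mode)) {
    stop("policy mode '", policy$mode, "' does not match PSM table mode '",
         mode, "'")
  }
  n <- nrow(psms)
  rules <- c("rank", "length", "ion_score", "isolation_interference",
             "percolator_q")
  if (n == 0) {
    return(list(psms = psms,
                tally = stats::setNames(integer(length(rules)), rules)))
  }
  len <- nchar(psms$sequence)
  fails <- list(
    rank = if (policy$require_rank1) {
      !is.na(psms$search_rank) & psms$search_rank != 1
    } else rep(FALSE, n),
    length = len < policy$length_range[1] | len > policy$length_range[2],
    ion_score = is.na(psms$ion_score) | psms$ion_score < policy$min_ion_score,
    isolation_interference = !is.na(psms$isolation_interference_pct) &
      psms$isolation_interference_pct > policy$max_isolation_interference,
    percolator_q = if (policy$mode == "tmt" && !is.na(policy$max_percolator_q)) {
      !is.na(psms$percolator_q) & psms$percolator_q > policy$max_percolator_q
    } else rep(FALSE, n)
  )
  fail_mat <- do.call(cbind, fails)
  rejected <- rowSums(fail_mat) > 0
  first_fail <- apply(fail_mat, 1, function(f) which(f)[1])
  tally <- table(factor(names(fails)[first_fail[rejected]],
                        levels = names(fails)))
  list(psms = psms[!rejected, , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(tally)))
}

# ---- peptide quantification table ---------------------------------------

.peptide_key <- function(sequence, modifications) {
  m <- ifelse(is.na(modifications) | !nzchar(modifications), "",
              paste0("/", modifications))
  paste0(sequence, m)
}

#' Aggregate filtered PSMs into a peptide quantification table
#'
#' Per unique peptide (sequence plus full modification state) and per
#' sample/channel, intensities of all its PSMs across fractions and analyses
#' of the same sample are summed. For internal-standard sequences the
#' C-terminal amidation variant is merged into the same peptide. Unobserved
#' cells are missing (`NA`), never zero.
#'
#' @param psms A filtered `psm_table`.
#' @param standard_sequences Sequences whose amidation variants are merged
#'   (typically the hipMHC standards).
#' @return Object of class `peptide_quant`: list with `raw` (peptide x
#'   sample matrix), `adjusted` (`NULL` until [apply_correction()]),
#'   `n_psms`, `peptides` (data frame key/sequence/modifications),
#'   `samples`, `mode`, `factors`.
#' @export
aggregate_to_peptides <- function(psms, standard_sequences = character()) {
  mode <- attr(psms, "mode")
  mods <- psms$modifications
  merge <- psms$sequence %in% standard_sequences
  mods[merge] <- .strip_mod(mods[merge], "amidated")
  key <- .peptide_key(psms$sequence, mods)

  if (identical(mode, "lf")) {
    samples <- unique(psms$sample_id)
    vals <- matrix(NA_real_, nrow = length(unique(key)), ncol = length(samples),
                   dimnames = list(unique(key), samples))
    npsm <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    for (j in seq_along(samples)) {
      sel <- psms$sample_id == samples[j] & !is.na(psms$auc)
      if (!any(sel)) next
      s <- rowsum(psms$auc[sel], key[sel])
      vals[rownames(s), j] <- s[, 1]
      cnt <- table(key[sel])
      npsm[names(cnt), j] <- as.integer(cnt)
    }
  } else {
    channels <- attr(psms, "channels")
    if (is.null(channels) || !length(channels)) {
      stop("TMT PSM table carries no channel attribute")
    }
    cols <- paste0("reporter_", channels)
    vals <- matrix(NA_real_, nrow = length(unique(key)), ncol = length(channels),
                   dimnames = list(unique(key), channels))
    npsm <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    for (j in seq_along(channels)) {
      v <- psms[[cols[j]]]
      sel <- !is.na(v)
      if (!any(sel)) next
      s <- rowsum(v[sel], key[sel])
      vals[rownames(s), j] <- s[, 1]
      cnt <- table(key[sel])
      npsm[names(cnt), j] <- as.integer(cnt)
    }
    samples <- channels
  }
  first <- !duplicated(key)
  peptides <- data.frame(key = key[first], sequence = psms$sequence[first],
                         modifications = mods[first],
                         stringsAsFactors = FALSE)
  peptides <- peptides[match(rownames(vals), peptides$key), , drop = FALSE]
  rownames(peptides) <- NULL
  structure(list(raw = vals, adjusted = NULL, n_psms = npsm,
                 peptides = peptides, samples = colnames(vals),
                 mode = mode, factors = NULL),
            class = "peptide_quant")
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat(sprintf("peptide_quant: %d peptides x %d %s (%s mode)%s\n",
              nrow(x$raw), length(x$samples),
              if (x$mode == "tmt") "channels" else "samples", x$mode,
              if (is.null(x$adjusted)) "" else ", normalized"))
  invisible(x)
}

#' Values of a peptide quantification table
#'
#' @param x A `peptide_quant`.
#' @param use `"adjusted"` (requires prior [apply_correction()]) or `"raw"`.
#' @return Numeric peptide x sample matrix.
#' @export
quant_values <- function(x, use = c("adjusted", "raw")) {
  use <- match.arg(use)
  if (use == "adjusted") {
    if (is.null(x$adjusted)) stop("table has no adjusted values; run apply_correction()")
    x$adjusted
  } else {
    x$raw
  }
}

#' Restrict a peptide table to rows quantified in all listed samples
#'
#' @param x A `peptide_quant`.
#' @param samples Sample/channel ids that must all be non-missing; defaults
#'   to every sample in the table.
#' @return A `peptide_quant` restricted to the complete rows.
#' @export
completeness_mask <- function(x, samples = x$samples) {
  unknown <- setdiff(samples, x$samples)
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  keep <- rowSums(is.na(x$raw[, samples, drop = FALSE])) == 0
  subset_peptides(x, keep)
}

#' Subset a peptide table by row index or logical mask
#'
#' @param x A `peptide_quant`.
#' @param i Row indices or logical mask.
#' @return A `peptide_quant`.
#' @export
subset_peptides <- function(x, i) {
  x$raw <- x$raw[i, , drop = FALSE]
  if (!is.null(x$adjusted)) x$adjusted <- x$adjusted[i, , drop = FALSE]
  x$n_psms <- x$n_psms[i, , drop = FALSE]
  x$peptides <- x$peptides[i, , drop = FALSE]
  rownames(x$peptides) <- NULL
  x
}
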