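# PSM tables are plain data frames of class `psm_table` with one row per
# peptide-spectrum match. Quantitative values live either in an `auc` column
# (label-free mode) or in one `reporter_<label>` column per isobaric channel
# (TMT mode); channel labels in attr(x, "channels"), mode in attr(x, "mode").
# Modifications are `name@position` tokens joined by `;`.

# canonical column set; auc / reporter_* are mode-dependent
.psm_base_cols <- c(
  "sequence", "modifications", "charge", "ion_score", "percolator_q",
  "isolation_interference_pct", "search_rank", "sample_id", "fraction_id",
  "rt_sec", "scan"
)

.psm_numeric_cols <- c(
  "charge", "ion_score", "percolator_q", "isolation_interference_pct",
  "search_rank", "rt_sec", "scan", "auc"
)

#' Column-name aliases for common search-engine export dialects
#'
#' Maps canonical column names to alternative headers seen in Proteome
#' Discoverer / Mascot style exports. Matching is case-insensitive and
#' ignores spaces, dots and dashes.
#'
#' @return Named list: canonical name -> character vector of aliases.
#' @export
psm_column_aliases <- function() {
  list(
    sequence = c("peptide", "annotated sequence", "peptide sequence"),
    modifications = c("mods", "modification"),
    charge = c("z", "precursor charge"),
    ion_score = c("ions score", "ionscore", "score"),
    percolator_q = c("percolator q value", "q value", "qvalue"),
    isolation_interference_pct = c("isolation interference", "isolation interference [%]"),
    search_rank = c("rank", "search engine rank"),
    sample_id = c("sample", "analysis"),
    fraction_id = c("fraction"),
    rt_sec = c("rt", "retention time", "rt [sec]"),
    scan = c("scan number", "first scan"),
    auc = c("area", "precursor area", "precursor abundance")
  )
}

.norm_header <- function(x) gsub("[ ._-]", "", tolower(x))

#' Read a PSM-level quantification table
#'
#' Reads a delimited text export of peptide-spectrum matches into the
#' canonical `psm_table` layout. Unknown columns are ignored; known columns
#' may appear under common export aliases (see [psm_column_aliases()]).
#' Malformed numeric cells become `NA` and are reported with their row
#' numbers. A reporter cell of `NA` means that channel was not observed for
#' that PSM.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param mode `"tmt"` (per-channel `reporter_<label>` columns) or `"lf"`
#'   (an `auc` column).
#' @param sep Field separator; default tab, use `","` for CSV.
#' @param aliases Alias map as returned by [psm_column_aliases()].
#' @return A `psm_table` data frame; attributes `mode` and (TMT) `channels`.
#' @export
read_psm_table <- function(path, mode = c("tmt", "lf"), sep = "\t",
                           aliases = psm_column_aliases()) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0) {
    warning("empty PSM table: ", path)
    return(.as_psm_table(.empty_psms(mode), mode,
                         channels = if (mode == "tmt") character() else NULL))
  }
  # resolve aliases onto canonical names
  hdr <- .norm_header(names(raw))
  for (canon in names(aliases)) {
    if (canon %in% names(raw)) next
    hit <- which(hdr %in% .norm_header(c(canon, aliases[[canon]])))
    if (length(hit)) names(raw)[hit[1]] <- canon
  }
  mandatory <- c("sequence", "ion_score", "search_rank", "sample_id")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("PSM table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  reporter_cols <- grep("^reporter_", names(raw), value = TRUE)
  if (mode == "tmt" && length(reporter_cols) == 0) {
    stop("PSM table is missing mandatory column(s): reporter_<label>")
  }
  if (mode == "lf" && !"auc" %in% names(raw)) {
    stop("PSM table is missing mandatory column(s): auc")
  }

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in .psm_base_cols) {
    out[[col]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  num_cols <- intersect(c(.psm_numeric_cols, reporter_cols),
                        c(names(out), names(raw)))
  if (mode == "lf") out[["auc"]] <- raw[["auc"]]
  for (col in reporter_cols) out[[col]] <- raw[[col]]
  for (col in intersect(num_cols, names(out))) {
    v <- out[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & toupper(v) != "NA" & is.na(parsed))
    if (length(bad)) {
      warning(sprintf("column '%s': malformed numeric cells at row(s) %s set to NA",
                      col, paste(bad, collapse = ", ")))
    }
    na_marked <- if (grepl("^reporter_", col)) which(is.na(v) | toupper(v) == "NA") else integer()
    if (length(na_marked)) {
      message(sprintf("column '%s': %d reporter cell(s) marked NA (channel absent)",
                      col, length(na_marked)))
    }
    out[[col]] <- parsed
  }
  out$sequence <- toupper(out$sequence)
  out$modifications[is.na(out$modifications)] <- ""
  .as_psm_table(out, mode,
                channels = sub("^reporter_", "", reporter_cols))
}

.empty_psms <- function(mode) {
  out <- data.frame(matrix(character(), nrow = 0, ncol = length(.psm_base_cols),
                           dimnames = list(NULL, .psm_base_cols)),
                    stringsAsFactors = FALSE)
  if (mode == "lf") out$auc <- numeric()
  out
}

.as_psm_table <- function(df, mode, channels = NULL) {
  class(df) <- c("psm_table", "data.frame")
  attr(df, "mode") <- mode
  if (!is.null(channels)) attr(df, "channels") <- channels
  df
}

#' Write a PSM table to disk
#'
#' Inverse of [read_psm_table()]: writing and re-reading reproduces the
#' records field for field.
#'
#' @param psms A `psm_table`.
#' @param path Output path (TSV).
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(as.data.frame(psms), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table: %d records, mode=%s", nrow(x), attr(x, "mode")))
  ch <- attr(x, "channels")
  if (length(ch)) cat(sprintf(", %d channels (%s)", length(ch),
                              paste(ch, collapse = ", ")))
  cat("\n")
  invisible(x)
}

# ---- modification string helpers ----------------------------------------

#' Parse a modification string into name/position pairs
#'
#' @param x Character vector of `name@pos` tokens joined by `;`.
#' @return List of data frames with columns `name`, `pos`.
#' @export
parse_mods <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(name = character(), pos = integer()))
    }
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    parts <- strsplit(toks, "@", fixed = TRUE)
    data.frame(name = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, function(p) {
                 if (length(p) > 1) p[2] else NA_character_
               }, "")),
               stringsAsFactors = FALSE)
  })
}

#' Test whether modification strings carry a modification
#'
#' @param mods Character vector of modification strings.
#' @param name Modification name (e.g. `"heavy_leu"`).
#' @param pos Optional position(s); if given, all listed positions must carry
#'   the modification.
#' @return Logical vector.
#' @export
has_mod <- function(mods, name, pos = NULL) {
  parsed <- parse_mods(mods)
  vapply(parsed, function(m) {
    hit <- m$name == name
    if (is.null(pos)) return(any(hit))
    all(pos %in% m$pos[hit])
  }, logical(1))
}

.strip_mod <- function(mods, name) {
  vapply(mods, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    keep <- !grepl(paste0("^", name, "(@|$)"), toks)
    paste(toks[keep], collapse = ";")
  }, "", USE.NAMES = FALSE)
}

# ---- hipMHC standards and experiment configuration ----------------------

#' Define a hipMHC internal-standard peptide
#'
#' A heavy-isotope-coded peptide-MHC spiked into lysate before
#' immunoprecipitation. `correction` standards are spiked at one equal
#' amount in every sample/channel and drive normalization; `titration`
#' standards are spiked at increasing amounts to probe dynamic-range
#' suppression; `calibrant` standards form the embedded curve for absolute
#' quantification.
#'
#' @param sequence Upper-case amino-acid sequence.
#' @param heavy_positions Positions carrying the +7 heavy-leucine label.
#' @param role One of `"correction"`, `"titration"`, `"calibrant"`.
#' @param amounts_fmol Named numeric: sample/channel -> fmol spiked.
#' @return An object of class `hipmhc_spec`.
#' @export
hipmhc_spec <- function(sequence, heavy_positions, role, amounts_fmol) {
  role <- match.arg(role, c("correction", "titration", "calibrant"))
  sequence <- toupper(sequence)
  heavy_positions <- as.integer(heavy_positions)
  if (length(heavy_positions) == 0) stop("heavy_positions must be non-empty")
  if (any(heavy_positions < 1 | heavy_positions > nchar(sequence))) {
    stop("heavy_positions outside sequence for ", sequence)
  }
  amounts_fmol <- unlist(amounts_fmol)
  if (is.null(names(amounts_fmol)) || any(!nzchar(names(amounts_fmol)))) {
    stop("amounts_fmol must be named by sample or channel")
  }
  if (any(amounts_fmol <= 0)) stop("spiked amounts must be positive")
  if (role == "correction" && length(unique(amounts_fmol)) != 1) {
    stop("correction standard '", sequence, "' must be spiked at equal amounts")
  }
  if (role != "correction" && length(unique(amounts_fmol)) < 2) {
    stop(role, " standard '", sequence,
         "' needs >= 2 distinct spiked amounts")
  }
  structure(list(sequence = sequence, heavy_positions = heavy_positions,
                 role = role, amounts_fmol = amounts_fmol),
            class = "hipmhc_spec")
}

#' @export
print.hipmhc_spec <- function(x, ...) {
  cat(sprintf("hipMHC %s standard %s (heavy at %s): %s fmol\n",
              x$role, x$sequence, paste(x$heavy_positions, collapse = ","),
              paste(signif(x$amounts_fmol, 4), collapse = "/")))
  invisible(x)
}

#' Define the experiment layout
#'
#' @param mode `"tmt"` or `"lf"`.
#' @param channel_labels Ordered channel labels (TMT) or sample ids (LF).
#' @param reference Sample/channel used as ratio denominator
#'   (TMT126 in a standard 6-plex).
#' @param condition_map Named character: channel/sample -> condition label.
#' @param n_cells Cells per sample, used for copies-per-cell conversion.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("tmt", "lf"), channel_labels,
                              reference, condition_map = NULL,
                              n_cells = NA_real_) {
  mode <- match.arg(mode)
  channel_labels <- as.character(channel_labels)
  if (!reference %in% channel_labels) {
    stop("reference '", reference, "' is not among the declared channels/samples")
  }
  if (!is.null(condition_map)) {
    condition_map <- unlist(condition_map)
    if (!all(channel_labels %in% names(condition_map))) {
      stop("condition_map must cover every channel/sample")
    }
    condition_map <- condition_map[channel_labels]
  }
  structure(list(mode = mode, channel_labels = channel_labels,
                 reference = reference, condition_map = condition_map,
                 n_cells = as.numeric(n_cells)),
            class = "experiment_config")
}

#' Load hipMHC standards and experiment layout from a YAML config
#'
#' The config declares `mode`, `channels` (in channel order), `reference`,
#' optional `conditions` and `n_cells`, and a list of `standards`, each with
#' `sequence`, `heavy_positions`, `role` and `amounts_fmol` (either a single
#' number applied to every channel, or one value per channel in channel
#' order, or a named map).
#'
#' @param path Path to the YAML file.
#' @return List with elements `standards` (list of [hipmhc_spec()]) and
#'   `experiment` ([experiment_config()]).
#' @export
load_hipmhc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("mode", "channels", "reference", "standards")) {
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
  }
  channels <- as.character(unlist(cfg$channels))
  exp <- experiment_config(cfg$mode, channels, cfg$reference,
                           condition_map = cfg$conditions,
                           n_cells = if (is.null(cfg$n_cells)) NA_real_ else cfg$n_cells)
  standards <- lapply(cfg$standards, function(s) {
    amt <- unlist(s$amounts_fmol)
    if (is.null(names(amt))) {
      if (length(amt) == 1) amt <- rep(amt, length(channels))
      if (length(amt) != length(channels)) {
        stop("standard '", s$sequence, "': amounts_fmol must be length 1, ",
             "one per channel, or a named map")
      }
      names(amt) <- channels
    }
    hipmhc_spec(s$sequence, s$heavy_positions, s$role, amt)
  })
  # titration amounts must increase along the declared channel order
  for (s in standards) {
    if (s$role == "titration") {
      ord <- s$amounts_fmol[intersect(channels, names(s$amounts_fmol))]
      if (any(diff(ord) <= 0)) {
        stop("titration standard '", s$sequence,
             "' amounts must be strictly increasing in channel order")
      }
    }
  }
  list(standards = standards, experiment = exp)
}

#' Partition PSMs into internal standards and endogenous peptides
#'
#' A PSM belongs to a standard iff its sequence matches the standard's and it
#' carries the heavy-leucine label at every declared heavy position. Presence
#' or absence of C-terminal amidation does not split a standard (synthetic
#' standards occur with both amidated and free-acid C termini). Unlabeled
#' (light) versions of standard sequences stay endogenous.
#'
#' @param psms A `psm_table`.
#' @param specs List of [hipmhc_spec()] objects.
#' @param heavy_mod Modification name marking the heavy label.
#' @return List with `standards` (named list of `psm_table` subsets, one per
#'   spec sequence), `endogenous` (`psm_table`), and `assignment` (character
#'   vector, `NA` for endogenous rows).
#' @export
match_standards <- function(psms, specs, heavy_mod = "heavy_leu") {
  mode <- attr(psms, "mode")
  channels <- attr(psms, "channels")
  assignment <- rep(NA_character_, nrow(psms))
  for (s in specs) {
    hit <- psms$sequence == s$sequence &
      has_mod(psms$modifications, heavy_mod, s$heavy_positions)
    assignment[hit & is.na(assignment)] <- s$sequence
  }
  std <- lapply(stats::setNames(nm = vapply(specs, `[[`, "", "sequence")),
                function(id) {
                  .as_psm_table(psms[which(assignment == id), , drop = FALSE],
                                mode, channels)
                })
  if (all(is.na(assignment)) && length(specs)) {
    message("no standard PSMs matched any hipMHC spec")
  }
  list(standards = std,
       endogenous = .as_psm_table(psms[is.na(assignment), , drop = FALSE],
                                  mode, channels),
       assignment = assignment)
}

#' Pool matched standard PSM subsets into one table
#'
#' Convenience for feeding several standards' PSMs (typically the
#' correction standards) to [abundance_window_filter()] or the
#' correction-factor functions as one `psm_table`.
#'
#' @param partition Result of [match_standards()].
#' @param ids Standard sequences to pool; default all matched standards.
#' @return A `psm_table` with the same mode/channel attributes as the input.
#' @export
pool_standard_psms <- function(partition, ids = names(partition$standards)) {
  subsets <- partition$standards[ids]
  pooled <- do.call(rbind, lapply(subsets, as.data.frame))
  rownames(pooled) <- NULL
  .as_psm_table(pooled, attr(partition$endogenous, "mode"),
                attr(partition$endogenous, "channels"))
}
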