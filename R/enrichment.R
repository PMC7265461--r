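# Pre-ranked gene-set enrichment: peptide -> protein collapse, the weighted
# running-sum enrichment score (weight 1), and a seeded gene-label
# permutation null. GMT and .rnk interchange formats are handled here.

#' Read a GMT gene-set file
#'
#' @param path Tab-delimited GMT: set name, description, then member genes.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write a two-column .rnk file
#'
#' @param ranked Data frame with columns `gene`, `score` (or a named
#'   numeric vector).
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  if (is.numeric(ranked)) {
    ranked <- data.frame(gene = names(ranked), score = as.numeric(ranked))
  }
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column .rnk file
#'
#' @param path Path to a gene/score TSV without header.
#' @return Data frame with `gene`, `score`, sorted descending by score.
#' @export
read_rnk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "score"),
                         stringsAsFactors = FALSE)
  d[order(-d$score, d$gene), , drop = FALSE]
}

#' Collapse peptide fold changes to a ranked protein list
#'
#' Gene names of peptide source proteins are extracted and rank ordered by
#' log2 fold change. When several peptides map to the same protein, the
#' maximum (positive direction) or minimum (negative direction) peptide
#' score is kept. Ties in rank are broken by gene name for determinism.
#'
#' @param peptide_scores Named numeric vector (peptide key -> log2 FC) or a
#'   data frame with columns `key`/`peptide` and `log2_fc`/`score`.
#' @param map Data frame with columns `peptide`, `gene` (peptide keys ->
#'   gene symbols); unmapped peptides are dropped with a message.
#' @param direction `"positive"` (max collapse) or `"negative"` (min).
#' @return Data frame of class `ranked_gene_list` with `gene`, `score`,
#'   sorted descending.
#' @export
collapse_to_proteins <- function(peptide_scores, map,
                                 direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (is.data.frame(peptide_scores)) {
    keycol <- intersect(c("key", "peptide"), names(peptide_scores))[1]
    scorecol <- intersect(c("log2_fc", "score"), names(peptide_scores))[1]
    peptide_scores <- stats::setNames(peptide_scores[[scorecol]],
                                      peptide_scores[[keycol]])
  }
  if (nrow(map) == 0) stop("empty peptide-to-gene map")
  gene <- map$gene[match(names(peptide_scores), map$peptide)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message(sum(unmapped), " peptide(s) without gene mapping dropped")
  }
  if (all(unmapped)) stop("no scored peptide is covered by the map")
  s <- peptide_scores[!unmapped]
  g <- gene[!unmapped]
  agg <- if (direction == "positive") {
    tapply(s, g, max)
  } else {
    tapply(s, g, min)
  }
  out <- data.frame(gene = names(agg), score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_gene_list", "data.frame")
  attr(out, "direction") <- direction
  out
}

.ranked_vector <- function(ranked) {
  if (is.data.frame(ranked)) {
    v <- stats::setNames(ranked$score, ranked$gene)
  } else {
    v <- ranked
  }
  if (is.null(names(v))) stop("ranked list must carry gene names")
  v[order(-v, names(v))]
}

# running sum for hit positions (logical over the ranked list)
.es_running <- function(scores, hit, weight = 1) {
  n <- length(scores)
  n_hit <- sum(hit)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  inc <- numeric(n)
  if (nr > 0) {
    inc[hit] <- w[hit] / nr
  } else {
    inc[hit] <- 1 / n_hit  # all-zero hit scores: unweighted steps
  }
  inc[!hit] <- -1 / (n - n_hit)
  cumsum(inc)
}

# signed maximum deviation; an exact tie between the positive and negative
# extreme resolves to the negative one (the usual pre-ranked convention)
.es_from_run <- function(run, tol = 1e-12) {
  max_p <- max(run)
  min_p <- min(run)
  if (max_p + min_p > tol) max_p else min_p
}

#' Weighted running-sum enrichment score
#'
#' Standard pre-ranked enrichment statistic with weight `p = 1`: walking
#' down the descending ranked list, set members ("hits") increment the
#' running sum by `|score|^w / sum_hits |score|^w` and non-members decrement
#' it by `1 / (N - N_hits)`; the enrichment score is the signed maximum
#' deviation from zero.
#'
#' @param ranked A `ranked_gene_list` (or named numeric vector of scores;
#'   it is sorted descending internally, ties broken by name).
#' @param gene_set Character vector of member genes.
#' @param weight Exponent on |score| for hit increments; default 1.
#' @return List with `es`, `running_sum`, `hit_positions`, `n_hits`, and
#'   `flagged` (`TRUE` when the set is degenerate: no overlap or the whole
#'   list).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  v <- .ranked_vector(ranked)
  hit <- names(v) %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) {
    return(list(es = NA_real_, running_sum = numeric(length(v)),
                hit_positions = integer(), n_hits = 0L, flagged = TRUE))
  }
  if (n_hit == length(v)) {
    return(list(es = NA_real_, running_sum = rep(NA_real_, length(v)),
                hit_positions = seq_along(v), n_hits = n_hit, flagged = TRUE))
  }
  run <- .es_running(v, hit, weight)
  es <- .es_from_run(run)
  list(es = es, running_sum = run, hit_positions = which(hit),
       n_hits = as.integer(n_hit), flagged = FALSE)
}

#' Permutation null for pre-ranked enrichment
#'
#' Gene-label permutations: for each set, null enrichment scores are drawn
#' by placing the same number of hits at random positions of the ranked
#' list. The nominal p value is the sign-matched tail fraction
#' `(count + 1) / (m + 1)` over the `m` null scores of the observed sign
#' (so the smallest reportable p is the 1/n_perm-scale bound); NES is the
#' observed ES divided by the mean magnitude of same-sign null scores, and
#' FDR q values are Benjamini-Hochberg across the tested sets.
#'
#' @param ranked A `ranked_gene_list` or named numeric vector.
#' @param gene_sets Named list of character vectors (or a single vector).
#' @param n_perm Number of permutations (>= 100; 1000 typical).
#' @param seed Integer seed; same seed gives identical results.
#' @param weight Hit weight exponent (default 1).
#' @param min_size Minimum set-list overlap to test (8 for pMHC lists,
#'   15 for expression lists).
#' @return Data frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p_value`, `q_value`, `n_perm`, `testable`.
#' @export
permutation_null <- function(ranked, gene_sets, n_perm = 1000, seed = NULL,
                             weight = 1, min_size = 8) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  }
  if (!is.null(seed)) set.seed(seed)
  v <- .ranked_vector(ranked)
  n <- length(v)
  rows <- lapply(names(gene_sets), function(nm) {
    size <- sum(names(v) %in% gene_sets[[nm]])
    obs <- enrichment_score(v, gene_sets[[nm]], weight)
    if (obs$flagged || size < min_size) {
      return(data.frame(set = nm, size = size, es = obs$es, nes = NA_real_,
                        p_value = NA_real_, q_value = NA_real_,
                        n_perm = n_perm, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    null_es <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, size)] <- TRUE
      .es_from_run(.es_running(v, hit, weight))
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    m <- length(same)
    p <- (sum(abs(same) >= abs(obs$es)) + 1) / (m + 1)
    nes <- if (m > 0) obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = size, es = obs$es, nes = nes,
               p_value = p, q_value = NA_real_, n_perm = n_perm,
               testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value[out$testable] <- stats::p.adjust(out$p_value[out$testable],
                                               method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enrichment results at the standard reporting thresholds
#'
#' Keeps testable sets with nominal p <= 0.05 and FDR q <= 0.25.
#'
#' @param results An `enrichment_result` data frame.
#' @param max_p Nominal p threshold (default 0.05).
#' @param max_q FDR q threshold (default 0.25).
#' @return The filtered data frame.
#' @export
filter_enrichment <- function(results, max_p = 0.05, max_q = 0.25) {
  keep <- results$testable & !is.na(results$p_value) &
    results$p_value <= max_p & results$q_value <= max_q
  results[keep, , drop = FALSE]
}
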