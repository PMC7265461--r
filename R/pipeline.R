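# End-to-end orchestration: simulate or read -> filter -> aggregate ->
# normalize -> compare, with a versioned run manifest in the output
# directory. The YAML config mirrors the function arguments stage by stage.

#' Run the quantification pipeline from a config
#'
#' Stages run in fixed order: input (simulate from a seed, or read a PSM
#' table), PSM filtering, aggregation, hipMHC normalization, and (when a
#' comparison is configured) differential statistics. Any stage failure
#' aborts with the stage name and removes partial outputs. Outputs are
#' plain TSV/JSON plus a `manifest.json` with the package version, config
#' and input hashes, seed, timestamps and per-stage record counts.
#'
#' Config keys: `mode`; either `simulate: {seed, n_peptides, loss_factors,
#' sigma_log2, ...}` or `input: {psm_table, standards_config}`; optional
#' `filter: {min_ion_score, max_isolation_interference, max_percolator_q,
#' len_min, len_max}`; `normalize: {reference}`; optional `compare:
#' {treated, control, conditions}`.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  counts <- list()
  stage <- "config"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  manifest <- tryCatch({
    mode <- match.arg(config$mode, c("tmt", "lf"))

    stage <- "input"
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      args <- sc[setdiff(names(sc), c("seed"))]
      args$mode <- mode
      if (!is.null(args$loss_factors)) args$loss_factors <- unlist(args$loss_factors)
      if (!is.null(args$conditions)) args$conditions <- unlist(args$conditions)
      sim_cfg <- do.call(simulation_config, args)
      seed <- if (is.null(sc$seed)) 1 else sc$seed
      sim <- generate_replicate_experiment(sim_cfg, seed = seed)
      psms <- sim$psms
      standards <- sim_cfg$standards
      reference <- sim_cfg$reference
      conditions <- sim_cfg$conditions
      inputs <- character()
      emit("ground_truth.json", function(p) {
        jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA)
      })
    } else if (!is.null(config$input)) {
      for (k in c("psm_table", "standards_config")) {
        if (is.null(config$input[[k]]) || !file.exists(config$input[[k]])) {
          stop("input.", k, " missing or not found")
        }
      }
      psms <- read_psm_table(config$input$psm_table, mode = mode)
      hc <- load_hipmhc_config(config$input$standards_config)
      standards <- hc$standards
      reference <- hc$experiment$reference
      conditions <- hc$experiment$condition_map
      seed <- NA
      inputs <- c(config$input$psm_table, config$input$standards_config)
    } else {
      stop("config must declare either 'simulate' or 'input'")
    }
    counts$input <- nrow(psms)

    stage <- "filter"
    fcfg <- config$filter
    policy <- filter_policy(
      mode,
      min_ion_score = fcfg$min_ion_score %||% if (mode == "lf") 20 else 15,
      max_isolation_interference = fcfg$max_isolation_interference %||% 30,
      max_percolator_q = fcfg$max_percolator_q %||% if (mode == "tmt") 0.05 else NA,
      length_range = c(fcfg$len_min %||% 8, fcfg$len_max %||% 15))
    filt <- filter_psms(psms, policy)
    counts$filtered <- nrow(filt$psms)

    stage <- "aggregate"
    std_seqs <- vapply(standards, `[[`, "", "sequence")
    part <- match_standards(filt$psms, standards)
    table <- aggregate_to_peptides(part$endogenous)
    counts$peptides <- nrow(table$raw)

    stage <- "normalize"
    if (!is.null(config$normalize$reference)) reference <- config$normalize$reference
    corr_specs <- std_seqs[vapply(standards, `[[`, "", "role") == "correction"]
    std_psms <- pool_standard_psms(part, corr_specs)
    if (mode == "tmt") {
      std_psms <- abundance_window_filter(std_psms, part$endogenous)
      factors <- compute_tmt_correction(std_psms, reference)
    } else {
      std_table <- aggregate_to_peptides(std_psms,
                                         standard_sequences = std_seqs)
      factors <- compute_lf_correction(std_table$raw, reference)
    }
    table <- apply_correction(table, factors)
    counts$standard_psms <- factors$n_standard_psms
    emit("correction_factors.json", function(p) {
      jsonlite::write_json(
        list(method = factors$method, reference = factors$reference,
             factors = as.list(factors$factors),
             standards_used = factors$standards_used,
             n_standard_psms = factors$n_standard_psms),
        p, auto_unbox = TRUE, digits = NA)
    })
    emit("peptide_table.tsv", function(p) {
      out <- cbind(table$peptides,
                   as.data.frame(table$raw, check.names = FALSE),
                   stats::setNames(as.data.frame(table$adjusted,
                                                 check.names = FALSE),
                                   paste0("adj_", colnames(table$adjusted))))
      utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })

    if (!is.null(config$compare)) {
      stage <- "stats"
      cmp_cfg <- config$compare
      cm <- if (!is.null(cmp_cfg$conditions)) unlist(cmp_cfg$conditions) else conditions
      cmp <- quant_comparison(completeness_mask(table), cm,
                              cmp_cfg$treated, cmp_cfg$control)
      counts$compared_peptides <- nrow(cmp)
      emit("comparison.tsv", function(p) {
        utils::write.table(as.data.frame(cmp), p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
    }

    stage <- "manifest"
    manifest <- list(
      tool = "hipquant",
      version = as.character(utils::packageVersion("hipquant")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      config_md5 = if (is.null(cfg_path)) NA else unname(tools::md5sum(cfg_path)),
      input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
      counts = counts)
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    })
    manifest
  }, error = on_fail)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
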