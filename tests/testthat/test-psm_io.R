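# PSM table IO, hipMHC configuration, and standard/endogenous partitioning.

test_that("PSM tables round-trip through disk field for field", {
  psms <- make_tmt_psms(list(
    list(sequence = "SVVESVKFL", modifications = "heavy_leu@9",
         reporter = c(100, 50)),
    list(sequence = "KLDVGNAEV", reporter = c(200, NA)),
    list(sequence = "AAAAAAAAA", ion_score = 15.5, reporter = c(1, 2))))
  path <- tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  back <- suppressMessages(read_psm_table(path, mode = "tmt"))
  expect_equal(nrow(back), 3)
  expect_equal(attr(back, "channels"), c("TMT126", "TMT127"))
  for (col in names(psms)) {
    expect_equal(back[[col]], psms[[col]], info = col)
  }

  lf <- make_lf_psms(list(list(auc = 123.4), list(auc = 5, sample_id = "s2")))
  path2 <- tempfile(fileext = ".tsv")
  write_psm_table(lf, path2)
  back2 <- read_psm_table(path2, mode = "lf")
  expect_equal(back2$auc, lf$auc)
  expect_equal(back2$sample_id, lf$sample_id)
})

test_that("missing mandatory columns give a schema error naming the column", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tsearch_rank\tsample_id\tauc",
               "AAAAAAAAA\t1\ts1\t10"), path)
  expect_error(read_psm_table(path, mode = "lf"), "ion_score")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tion_score\tsearch_rank\tsample_id",
               "AAAAAAAAA\t50\t1\ts1"), path2)
  expect_error(read_psm_table(path2, mode = "lf"), "auc")
  expect_error(read_psm_table(path2, mode = "tmt"), "reporter")
})

test_that("reporter NA cells and malformed numerics are handled row-wise", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence\tion_score\tsearch_rank\tsample_id\treporter_TMT126\treporter_TMT127",
    "AAAAAAAAA\t50\t1\tplex1\t100\tNA",
    "CCCCCCCCC\toops\t1\tplex1\t30\t40"), path)
  expect_message(
    expect_warning(tab <- read_psm_table(path, mode = "tmt"), "malformed"),
    "channel absent")
  expect_true(is.na(tab$reporter_TMT127[1]))
  expect_equal(tab$reporter_TMT126, c(100, 30))
  expect_true(is.na(tab$ion_score[2]))
})

test_that("export dialect aliases map onto the canonical schema", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Annotated Sequence\tIons Score\tRank\tSample\tArea",
               "siinfekl9\t42\t1\ts1\t1e6"), path)
  tab <- read_psm_table(path, mode = "lf")
  expect_equal(tab$sequence, "SIINFEKL9")
  expect_equal(tab$ion_score, 42)
  expect_equal(tab$auc, 1e6)
})

test_that("modification strings parse and query correctly", {
  m <- parse_mods(c("heavy_leu@3;phospho@4", "", "amidated@9"))
  expect_equal(m[[1]]$name, c("heavy_leu", "phospho"))
  expect_equal(m[[1]]$pos, c(3L, 4L))
  expect_equal(nrow(m[[2]]), 0)
  expect_true(has_mod("heavy_leu@3;oxidation@1", "heavy_leu", 3))
  expect_false(has_mod("heavy_leu@3", "heavy_leu", 9))
  expect_false(has_mod("", "heavy_leu"))
})

test_that("hipMHC spec invariants are enforced", {
  expect_error(hipmhc_spec("ALNEQIARL", 9, "correction",
                           c(s1 = 30, s2 = 40)), "equal amounts")
  expect_error(hipmhc_spec("SVVESVKFL", 9, "titration",
                           c(s1 = 30, s2 = 30)), "distinct")
  expect_error(hipmhc_spec("SVVESVKFL", integer(), "titration",
                           c(s1 = 30, s2 = 60)), "heavy_positions")
  expect_error(hipmhc_spec("ABC", 9, "correction", c(s1 = 30)), "outside")
  s <- hipmhc_spec("svvesvkfl", 9, "titration", c(s1 = 30, s2 = 300))
  expect_equal(s$sequence, "SVVESVKFL")
})

test_that("YAML config loads standards and experiment layout", {
  path <- write_yaml_config(c(
    "mode: tmt",
    "reference: TMT126",
    "n_cells: 1.0e7",
    "channels: [TMT126, TMT127, TMT128, TMT129, TMT130]",
    "standards:",
    "  - {sequence: ALNEQIARL, heavy_positions: 9, role: correction, amounts_fmol: 30}",
    "  - {sequence: SLEEPIGHL, heavy_positions: 9, role: correction, amounts_fmol: 30}",
    "  - {sequence: SVVESVKFL, heavy_positions: 9, role: titration,",
    "     amounts_fmol: [30, 60, 100, 150, 300]}"))
  cfg <- load_hipmhc_config(path)
  expect_length(cfg$standards, 3)
  expect_equal(vapply(cfg$standards, `[[`, "", "role"),
               c("correction", "correction", "titration"))
  expect_equal(unname(cfg$standards[[1]]$amounts_fmol), rep(30, 5))
  expect_equal(cfg$experiment$reference, "TMT126")
  expect_equal(cfg$experiment$n_cells, 1e7)

  # three-channel calibrant series
  path2 <- write_yaml_config(c(
    "mode: tmt",
    "reference: TMT126",
    "channels: [TMT126, TMT127, TMT128]",
    "standards:",
    "  - {sequence: KQVSDLISV, heavy_positions: 6, role: calibrant,",
    "     amounts_fmol: [0.3, 1, 3]}"))
  cfg2 <- load_hipmhc_config(path2)
  expect_equal(cfg2$standards[[1]]$role, "calibrant")
  expect_equal(unname(cfg2$standards[[1]]$amounts_fmol), c(0.3, 1, 3))

  # correction standard with unequal amounts is a validation error
  path3 <- write_yaml_config(c(
    "mode: tmt",
    "reference: TMT126",
    "channels: [TMT126, TMT127]",
    "standards:",
    "  - {sequence: ALNEQIARL, heavy_positions: 9, role: correction,",
    "     amounts_fmol: [30, 40]}"))
  expect_error(load_hipmhc_config(path3), "equal amounts")
  # unknown role
  path4 <- write_yaml_config(c(
    "mode: tmt", "reference: TMT126", "channels: [TMT126, TMT127]",
    "standards:",
    "  - {sequence: ALNEQIARL, heavy_positions: 9, role: bogus, amounts_fmol: 30}"))
  expect_error(load_hipmhc_config(path4))
  # titration must increase along channel order
  path5 <- write_yaml_config(c(
    "mode: tmt", "reference: TMT126", "channels: [TMT126, TMT127, TMT128]",
    "standards:",
    "  - {sequence: SVVESVKFL, heavy_positions: 9, role: titration,",
    "     amounts_fmol: [100, 30, 300]}"))
  expect_error(load_hipmhc_config(path5), "increasing")
})

test_that("standards are matched by heavy label; amidation does not split", {
  specs <- list(hipmhc_spec("SVVESVKFL", 9, "titration",
                            c(TMT126 = 30, TMT127 = 60)))
  psms <- make_tmt_psms(list(
    list(sequence = "SVVESVKFL", modifications = "heavy_leu@9",
         reporter = c(1, 2)),
    list(sequence = "SVVESVKFL", modifications = "heavy_leu@9;amidated@9",
         reporter = c(3, 4)),
    list(sequence = "SVVESVKFL", modifications = "", reporter = c(5, 6)),
    list(sequence = "KLDVGNAEV", reporter = c(7, 8))))
  part <- match_standards(psms, specs)
  expect_equal(nrow(part$standards$SVVESVKFL), 2)  # amidated variant pooled
  expect_equal(nrow(part$endogenous), 2)           # light version endogenous
  expect_true("SVVESVKFL" %in% part$endogenous$sequence)
})

test_that("match_standards partitions: |standards| + |endogenous| = |input|", {
  cfg <- simulation_config(n_peptides = 40)
  sim <- generate_replicate_experiment(cfg, seed = 3)
  part <- match_standards(sim$psms, cfg$standards)
  n_std <- sum(vapply(part$standards, nrow, integer(1)))
  expect_equal(n_std + nrow(part$endogenous), nrow(sim$psms))
  # every correction/titration spec attracted PSMs
  expect_true(all(vapply(part$standards, nrow, integer(1)) > 0))
})
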