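# Correction-factor computation, application and suppression estimation.

test_that("abundance window is [Q1/10, Q3*10] on mean reporter intensity", {
  # endogenous per-PSM means 10..100 -> type-7 quantiles Q1=32.5, Q3=77.5
  endo <- make_tmt_psms(lapply(seq(10, 100, 10), function(m) {
    list(sequence = "AAAAAAAAA", reporter = c(m, m))
  }))
  expect_equal(unname(quantile(seq(10, 100, 10), c(.25, .75), type = 7)),
               c(32.5, 77.5))
  std <- make_tmt_psms(list(
    list(sequence = "SVVESVKFL", reporter = c(500, 500)),    # inside
    list(sequence = "SVVESVKFL", reporter = c(2000, 2000)),  # above 775
    list(sequence = "SVVESVKFL", reporter = c(775, 775)),    # boundary, inclusive
    list(sequence = "SVVESVKFL", reporter = c(3.25, 3.25)),  # lower boundary
    list(sequence = "SVVESVKFL", reporter = c(3, 3))))       # below
  kept <- abundance_window_filter(std, endo)
  expect_equal(attr(kept, "window"), c(3.25, 775))
  expect_equal(kept$reporter_TMT126, c(500, 775, 3.25))
  # removing everything is a hard error
  far <- make_tmt_psms(list(list(sequence = "SVVESVKFL", reporter = c(1e6, 1e6))))
  expect_error(abundance_window_filter(far, endo), "spike")
  expect_error(abundance_window_filter(std, endo[0, ]), "empty")
})

test_that("TMT correction is the reciprocal of the median channel ratio", {
  one <- make_tmt_psms(list(list(reporter = c(100, 50))))
  f <- compute_tmt_correction(one, "TMT126")
  expect_identical(unname(f$factors["TMT126"]), 1)
  expect_equal(unname(f$factors["TMT127"]), 2)

  # median over PSM ratios {0.4, 0.5, 0.6} -> factor 2
  three <- make_tmt_psms(list(
    list(reporter = c(100, 40)),
    list(reporter = c(200, 100)),
    list(reporter = c(100, 60))))
  f2 <- compute_tmt_correction(three, "TMT126")
  expect_equal(unname(f2$factors["TMT127"]), 2)
  expect_equal(f2$n_standard_psms, 3L)

  # identical channels -> all factors 1 and application is the identity
  same <- make_tmt_psms(list(list(reporter = c(5, 5)), list(reporter = c(7, 7))))
  f3 <- compute_tmt_correction(same, "TMT126")
  expect_equal(unname(f3$factors), c(1, 1))

  # PSMs with zero reference intensity are excluded with a warning
  zero <- make_tmt_psms(list(list(reporter = c(0, 10)), list(reporter = c(10, 5))))
  expect_warning(f4 <- compute_tmt_correction(zero, "TMT126"), "reference")
  expect_equal(unname(f4$factors["TMT127"]), 2)
})

test_that("LF correction averages per-standard AUC ratios", {
  m <- rbind(ALNEQIARL = c(s1 = 100, s2 = 80),
             SLEEPIGHL = c(s1 = 200, s2 = 240))
  f <- compute_lf_correction(m, "s1")     # ratios 0.8, 1.2 -> mean 1
  expect_equal(unname(f$factors["s2"]), 1)
  expect_identical(unname(f$factors["s1"]), 1)

  m2 <- rbind(a = c(s1 = 100, s2 = 50), b = c(s1 = 200, s2 = 100))
  f2 <- compute_lf_correction(m2, "s1")   # ratios 0.5, 0.5 -> factor 2
  expect_equal(unname(f2$factors["s2"]), 2)

  # standard missing in the reference is an error; in another sample a warning
  m3 <- rbind(a = c(s1 = NA, s2 = 50), b = c(s1 = 200, s2 = 100))
  expect_error(compute_lf_correction(m3, "s1"), "reference")
  m4 <- rbind(a = c(s1 = 100, s2 = NA), b = c(s1 = 200, s2 = 100))
  expect_warning(f4 <- compute_lf_correction(m4, "s1"), "missing")
  expect_equal(unname(f4$factors["s2"]), 2)
})

test_that("applying factors scales raw cells and is idempotent on standards", {
  tmt <- make_tmt_psms(list(list(sequence = "KLDVGNAEV", reporter = c(100, 300))))
  tab <- aggregate_to_peptides(tmt)
  f <- structure(list(method = "tmt_median", reference = "TMT126",
                      factors = c(TMT126 = 1, TMT127 = 2),
                      standards_used = character(), n_standard_psms = 1L,
                      condition_scoped = FALSE),
                 class = "correction_factors")
  adj <- apply_correction(tab, f)
  expect_equal(adj$adjusted["KLDVGNAEV", "TMT127"], 600)
  expect_equal(adj$adjusted[, "TMT126"], adj$raw[, "TMT126"])
  expect_error(apply_correction(tab, structure(list(factors = c(TMT126 = 1)),
                                               class = "correction_factors")),
               "factor")

  # recomputing the correction on corrected standards gives unit factors
  std <- make_tmt_psms(list(list(reporter = c(100, 40)),
                            list(reporter = c(10, 4.6)),
                            list(reporter = c(50, 21))))
  f1 <- compute_tmt_correction(std, "TMT126")
  corrected <- std
  for (ch in c("TMT126", "TMT127")) {
    corrected[[paste0("reporter_", ch)]] <-
      std[[paste0("reporter_", ch)]] * f1$factors[ch]
  }
  f2 <- compute_tmt_correction(corrected, "TMT126")
  expect_equal(unname(f2$factors), c(1, 1))
})

test_that("noise-free loss factors are recovered exactly (TMT and LF)", {
  k <- c(TMT126 = 1, TMT127 = 0.8, TMT128 = 1.3, TMT129 = 0.5,
         TMT130 = 1, TMT131 = 2)
  cfg <- simulation_config(n_peptides = 100, loss_factors = k, sigma_log2 = 0)
  sim <- generate_replicate_experiment(cfg, seed = 5)
  std <- pooled_correction_psms(sim, cfg)
  f <- compute_tmt_correction(std$standards, "TMT126")
  expect_equal(f$factors * k, setNames(rep(1, 6), names(k)), tolerance = 1e-12)

  ks <- c(s1 = 1, s2 = 0.5, s3 = 1.6)
  lf_cfg <- simulation_config("lf", n_peptides = 50, ids = names(ks),
                              loss_factors = ks, sigma_log2 = 0)
  lf_sim <- generate_replicate_experiment(lf_cfg, seed = 5)
  part <- match_standards(filter_psms(lf_sim$psms)$psms, lf_cfg$standards)
  std_tab <- aggregate_to_peptides(
    pool_standard_psms(part, c("ALNEQIARL", "SLEEPIGHL")),
    standard_sequences = c("ALNEQIARL", "SLEEPIGHL"))
  f_lf <- compute_lf_correction(std_tab$raw, "s1")
  expect_equal(f_lf$factors * ks, setNames(rep(1, 3), names(ks)),
               tolerance = 1e-12)
})

test_that("factor recovery under reporter noise concentrates with PSM depth", {
  # with independent per-channel lognormal noise (sigma_log2 = 0.2) a channel
  # ratio has sigma ~ 0.283; the median of ~100 pooled ratios (50 PSMs per
  # correction standard) keeps |log2(factor * k)| < 0.1 in >= 95% of runs
  k <- c(TMT126 = 1, TMT127 = 0.8, TMT128 = 1.3, TMT129 = 0.5,
         TMT130 = 1, TMT131 = 2)
  cfg <- simulation_config(n_peptides = 40, loss_factors = k, sigma_log2 = 0.2,
                           standard_psms = 50)
  errs <- vapply(1:120, function(s) {
    sim <- generate_replicate_experiment(cfg, seed = 1000 + s)
    std <- pooled_correction_psms(sim, cfg, window = FALSE)
    f <- compute_tmt_correction(std$standards, "TMT126")
    max(abs(log2(f$factors * k)))
  }, numeric(1))
  expect_gte(mean(errs < 0.1), 0.95)
})

test_that("correction never increases the median CV under sample-level losses", {
  k <- c(TMT126 = 1, TMT127 = 0.6, TMT128 = 1.5, TMT129 = 0.8,
         TMT130 = 1.2, TMT131 = 2)
  for (s in 1:5) {
    cfg <- simulation_config(n_peptides = 150, loss_factors = k,
                             sigma_log2 = 0.2, standard_psms = 30)
    sim <- generate_replicate_experiment(cfg, seed = 200 + s)
    std <- pooled_correction_psms(sim, cfg)
    f <- compute_tmt_correction(std$standards, "TMT126")
    tab <- apply_correction(aggregate_to_peptides(std$endogenous), f)
    cv <- cv_summary(tab)
    expect_lt(cv$median_cv_adjusted, cv$median_cv_raw)
  }
})

test_that("per-condition factors and the 2x trigger behave as specified", {
  # 6-plex split 3 vs 3; within-condition standards equal -> unit factors
  ch <- paste0("TMT", 126:131)
  cond <- setNames(rep(c("dmso", "ifng"), each = 3), ch)
  std <- make_tmt_psms(list(
    list(reporter = c(10, 10, 10, 40, 40, 40)),
    list(reporter = c(7, 7, 7, 30, 30, 30))), channels = ch)
  pc <- per_condition_correction(std, cond, c(dmso = "TMT126", ifng = "TMT129"))
  expect_true(pc$condition_scoped)
  expect_equal(unname(pc$factors[ch]), rep(1, 6))
  expect_error(per_condition_correction(std, setNames(rep("x", 6), ch),
                                        c(x = "TMT126")), "conditions")

  # trigger: global mean FC 2.4 -> on; 1.3 -> off
  base <- matrix(rep(c(100, 100, 100), 40), ncol = 3, byrow = TRUE)
  mk <- function(fc) {
    tmt <- make_tmt_psms(lapply(1:40, function(i) {
      list(sequence = paste0(strrep("A", 8), LETTERS[(i %% 20) + 1]),
           scan = i, reporter = c(base[i, ], base[i, ] * fc))
    }), channels = ch)
    aggregate_to_peptides(tmt)
  }
  expect_true(correction_trigger(mk(2.4), cond, "ifng", "dmso")$triggered)
  expect_false(correction_trigger(mk(1.3), cond, "ifng", "dmso")$triggered)
})

test_that("suppression is expected fold over observed fold at the extremes", {
  est <- estimate_suppression(c(s1 = 30, s2 = 300),
                              adjusted = c(s1 = 1000, s2 = 4000))
  expect_equal(est$expected_fold, 10)
  expect_equal(est$observed_fold, 4)
  expect_equal(est$suppression, 2.5)

  # perfectly linear through the origin -> no suppression, r2 = 1
  a <- c(s1 = 30, s2 = 60, s3 = 100, s4 = 150, s5 = 300)
  est2 <- estimate_suppression(a, adjusted = a * 50)
  expect_equal(est2$suppression, 1)
  expect_equal(est2$fit_r2_adjusted, 1)

  # full compression: equal intensities -> suppression = expected fold
  est3 <- estimate_suppression(a, adjusted = setNames(rep(500, 5), names(a)))
  expect_equal(est3$observed_fold, 1)
  expect_equal(est3$suppression, 10)

  expect_error(estimate_suppression(c(s1 = 30, s2 = 300),
                                    adjusted = c(s1 = 0, s2 = 10)), "> 0")
  expect_error(estimate_suppression(c(s1 = 30, s2 = 30),
                                    adjusted = c(s1 = 1, s2 = 2)), "distinct")

  # slope method agrees on exact linear data
  est4 <- estimate_suppression(a, adjusted = a * 50, method = "slope")
  expect_equal(est4$suppression, 1)
})

test_that("simulated power-law suppression is recovered by the titration", {
  gamma <- 2
  cfg <- simulation_config(n_peptides = 30, sigma_log2 = 0,
                           suppression = gamma)
  sim <- generate_replicate_experiment(cfg, seed = 9)
  part <- match_standards(filter_psms(sim$psms)$psms, cfg$standards)
  titr <- aggregate_to_peptides(part$standards$SVVESVKFL,
                                standard_sequences = "SVVESVKFL")
  amt <- cfg$standards[[3]]$amounts_fmol
  est <- estimate_suppression(amt, titr$raw[1, ])
  # expected 10x, observed 10^(1/gamma) -> suppression 10^(1 - 1/gamma)
  expect_equal(est$suppression, 10^(1 - 1 / gamma), tolerance = 1e-9)
})
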