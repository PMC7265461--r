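# hipquant

Quantitative immunopeptidomics with internal pMHC standards.

Mass-spectrometry profiling of MHC class I peptides (the immunopeptidome)
loses material at every enrichment step — immunoprecipitation, elution,
filtration — and the losses differ between samples. hipquant implements a
normalization and absolute-quantification workflow for this problem built on
**hipMHCs**: heavy isotope-coded peptide-MHC complexes spiked into lysate so
they experience the same losses as the endogenous peptides. It is aimed at
proteomics groups analyzing label-free (LF) or TMT-multiplexed
peptide-spectrum-match (PSM) tables exported from a search engine.

## What it computes

* **PSM filtering and aggregation** — the standard class I criteria
  (rank 1, isolation interference ≤ 30 %, length 8–15, ion score ≥ 20 LF /
  ≥ 15 TMT with percolator q ≤ 0.05, all inclusive), then summation of PSM
  intensities per unique peptide per sample.
* **Correction factors** — per channel: `factor(c) = 1 / median_PSMs(
  I_c / I_ref )` over correction-standard PSMs whose mean reporter intensity
  lies within `[Q1/10, Q3·10]` of the endogenous intensity IQR; per LF
  sample: the reciprocal of the mean AUC ratio across standards. Applied as
  `adjusted = raw × factor`. Per-condition factors when repertoires shift
  more than ~2× between conditions.
* **Dynamic-range suppression** — for a standard titrated from a_min to
  a_max fmol: `suppression = (a_max/a_min) / (I_max/I_min)` on adjusted
  intensities.
* **Absolute quantification** — Gaussian fits
  `I(t) = A·exp(−(t−µ)²/2σ²)` of targeted elution profiles; adjusted apex
  (`A`) vs fmol OLS calibration; back-calculation and conversion
  `copies = fmol × 10⁻¹⁵ × N_A / n_cells`.
* **Differential statistics** — log2 fold changes of arithmetic mean
  intensities, unpaired two-sided t tests, and the mean-adjusted test
  (treated intensities divided by the arithmetic mean fold change over all
  peptides before re-testing; skipped when |mean log2 FC| ≤ 0.07), plus
  median-CV and Gaussian `2^(3σ)` fold-change-bound summaries.
* **Pre-ranked enrichment** — max/min collapse of peptide scores to
  proteins, the weighted running-sum enrichment score (p = 1), seeded
  gene-label permutation p values, NES and BH FDR; GMT and .rnk
  interchange.
* **A seeded simulator** — PSM tables and targeted scan-level runs with
  known loss factors, suppression, effects and spiked standards, so every
  estimator is testable against ground truth without any download.

## Worked example

Simulate a 6-plex with known per-channel losses, derive correction factors
from the two 30-fmol correction hipMHCs, and normalize:

```r
library(hipquant)
k <- c(TMT126 = 1, TMT127 = 0.8, TMT128 = 1.3,
       TMT129 = 0.5, TMT130 = 1, TMT131 = 2)
cfg  <- simulation_config(n_peptides = 300, loss_factors = k)
sim  <- generate_replicate_experiment(cfg, seed = 1)
part <- match_standards(filter_psms(sim$psms)$psms, cfg$standards)
std  <- abundance_window_filter(
          pool_standard_psms(part, c("ALNEQIARL", "SLEEPIGHL")),
          part$endogenous)
f    <- compute_tmt_correction(std, "TMT126")
f
#> correction_factors (tmt_median, reference TMT126):
#> TMT126 TMT127 TMT128 TMT129 TMT130 TMT131
#> 1.0000 1.3260 0.7879 2.0615 1.0481 0.4914
#> from 20 standard PSM(s): ALNEQIARL, SLEEPIGHL

tab <- apply_correction(aggregate_to_peptides(part$endogenous), f)
cv_summary(tab)
#> cv_summary over 300 peptides: median CV raw 46.81%, adjusted 10.08%
```

The factors are close to `1/k` (exact when reporter noise is switched off),
and the median replicate CV drops from ~47 % to ~10 % after correction —
the loss variation is gone and only reporter noise remains.

Absolute quantification from an embedded 0.3/1/3-fmol calibration curve:

```r
run <- generate_targeted_run(seed = 1, endogenous_fmol = 0.81)
fac <- targeted_correction(run$scans, run$norm_targets, "TMT126")
absolute_quantify(run$scans, "KQVSDLISV_heavy", "KQVSDLISV",
                  run$truth$calibrant_fmol, paste0("TMT", 129:131),
                  factors = fac, n_cells = 1e7)
#> copies_per_cell_result [KQVSDLISV]: 48.8 +/- 0 copies/cell (0.81 +/- 0 fmol, n = 3)
#> calibration: r2 = 1.000000 over 3 points
copies_per_cell(0.1, 1e7)
#> [1] 6.022141
```

The 0.81 fmol truth is recovered exactly on noise-free data; 100 attomole
over 10⁷ cells is ~6 copies per cell.

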