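---
title: "Internal-standard quantitation of the immunopeptidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard quantitation of the immunopeptidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipquant)
```

## The measurement problem

Peptides presented on class I MHC complexes (pMHCs) are isolated by
immunoprecipitation, acid elution and filtration before LC-MS/MS analysis.
Every one of those steps loses material, and the losses differ between
samples. Without an internal control, a peptide that appears two-fold higher
after a drug treatment may simply have survived sample preparation better.
hipquant implements a quantification workflow built around heavy
isotope-coded peptide-MHC complexes (hipMHCs): synthetic heavy-leucine
(+7 Da) peptides loaded onto recombinant MHC monomers and spiked into the
*lysate*, so that they ride through the entire enrichment alongside the
endogenous pMHCs and absorb the same losses. Three roles are distinguished:

* **correction** standards, spiked at one equal amount everywhere, define
  per-sample/per-channel correction factors;
* **titration** standards, spiked at increasing amounts, report how much the
  measured fold range is compressed (dynamic-range suppression);
* **calibrant** standards at several known amounts form an embedded
  calibration curve for absolute quantification in copies per cell.

## From PSMs to a peptide matrix

The unit of input is the peptide-spectrum match (PSM) exported by the search
engine, with either a chromatographic area (label-free, LF) or per-channel
TMT reporter intensities. Identifications are filtered with the standard
class I criteria — search-engine rank 1, isolation interference ≤ 30 %,
length 8–15 residues, ion score ≥ 20 (LF) or ≥ 15 with percolator
q ≤ 0.05 (TMT), all inclusive — and surviving PSM intensities are summed per
unique peptide (sequence plus modification state; the amidated and free-acid
C-terminal forms of a synthetic standard count as one peptide). Missing
cells stay missing: downstream statistics use complete cases only, because
only peptides quantifiable in every compared sample support a ratio.

```{r filter}
cfg <- simulation_config(n_peptides = 300,
                         loss_factors = c(TMT126 = 1, TMT127 = 0.8,
                                          TMT128 = 1.3, TMT129 = 0.5,
                                          TMT130 = 1, TMT131 = 2))
sim <- generate_replicate_experiment(cfg, seed = 1)
filt <- filter_psms(sim$psms)
part <- match_standards(filt$psms, cfg$standards)
tab <- aggregate_to_peptides(part$endogenous)
tab
```

## Correction factors

For TMT data, each retained correction-standard PSM contributes one ratio
per channel against the reference channel (TMT126 by convention); the
correction factor of a channel is the reciprocal of the **median** of all
pooled ratios. For LF data, each standard's summed area per sample is
ratioed against the reference sample and the factor is the reciprocal of
the **mean** across standards. The two definitions mirror how the two data
types behave: TMT ratios come in large numbers of noisy PSM-level
observations (a median resists outliers), LF gives one summed area per
standard per run.

Standard PSMs whose mean reporter intensity falls outside ten-fold of the
interquartile range of the endogenous PSM intensities are excluded before
the median — spikes far above the endogenous regime acquire ratio bias from
co-isolation. We read "within 10-fold of the interquartile range" as the
inclusive window `[Q1/10, Q3×10]` with type-7 (linear interpolation)
quantiles — the widest literal reading — and expose the fold as an argument.

```{r correct}
std <- pool_standard_psms(part, c("ALNEQIARL", "SLEEPIGHL"))
std <- abundance_window_filter(std, part$endogenous)
factors <- compute_tmt_correction(std, "TMT126")
factors
tab <- apply_correction(tab, factors)
cv_summary(tab)
```

Because the simulated losses are sample-level and multiplicative, the
factors recover their reciprocals exactly in the noise-free limit, and the
median coefficient of variation across replicates drops after correction.
When the mean fold change between two *conditions* exceeds about 2×
(`correction_trigger()`), a single global correction is no longer reliable —
co-isolated endogenous signal drags the standards' ratios toward the
endogenous median — and `per_condition_correction()` derives factors within
each condition against its own reference channel instead.

A titrated standard quantifies compression: the suppression factor is the
expected fold range (max/min spiked fmol) over the observed fold range of
the adjusted intensities at those extreme points. We use the extreme points
rather than a slope because a single fold factor per peptide is the quantity
of interest; a slope-based variant is available (`method = "slope"`). Values
near 1 mean linear response; larger values mean measured differences
understate true ones.

## Absolute quantification

Targeted runs monitor one peptide; each MS2 scan contributes one point per
channel to an elution profile, which is fitted with a Gaussian
`I(t) = A·exp(−(t−µ)²/2σ²)`. The apex is defined as the fitted amplitude
`A`, not the tallest raw scan — the fit interpolates the true peak between
scan samples and averages out per-scan noise. Initialization uses the
tallest scan (µ, A) and the full width at half maximum (σ); a fit that fails
to converge falls back to the tallest scan with a flag. No baseline term is
included by default (background is assumed removed upstream); a constant
offset is available behind `offset = TRUE`.

Adjusted apexes of the calibrant channels give an ordinary least-squares
line of intensity on fmol; the endogenous (light) peptide's adjusted apex is
back-calculated through that line and converted with Avogadro's number:
`copies = fmol × 10⁻¹⁵ × 6.02214076×10²³ / n_cells`. Replicates are
quantified independently and summarized as mean ± SD.

```{r absquant}
run <- generate_targeted_run(seed = 1, endogenous_fmol = 0.81,
                             loss_factors = c(TMT126 = 1, TMT127 = 0.7,
                                              TMT128 = 1.2, TMT129 = 0.9,
                                              TMT130 = 1.1, TMT131 = 1.3))
fac <- targeted_correction(run$scans, run$norm_targets, "TMT126")
absolute_quantify(run$scans, "KQVSDLISV_heavy", "KQVSDLISV",
                  run$truth$calibrant_fmol, paste0("TMT", 129:131),
                  factors = fac, n_cells = 1e7)
```

## Differential statistics

Fold changes are ratios of arithmetic mean intensities (n = 3 per condition
typically), tested with an unpaired two-sided Student's t test
(equal-variance by default, Welch behind `var.equal = FALSE`); peptides with
p ≤ 0.05 and FC > 1 are *significantly increased*. To ask which peptides
move **beyond** a global repertoire shift, treated intensities are divided
by the arithmetic mean fold change over all peptides and re-tested; p ≤ 0.05
there marks *significantly enriched*. Centering is skipped when the mean
log2 fold change lies within ±0.07 — shifts that small are inside the
technical variation band and dividing by them only adds noise. We take
"mean fold change" literally as the arithmetic mean of per-peptide ratios;
the geometric mean is available via `center_stat`. No multiple-testing
correction is applied at the peptide level by default, matching how such
screens are usually reported; `p.adjust` can of course be applied to the
returned columns.

Technical spread is summarized two ways: the per-peptide CV (%) across
replicates with its median, and a Gaussian fitted to the histogram
(Freedman–Diaconis bins, least squares on counts) of pooled
`log2(value/µ_peptide)` deviations, whose `2^(3σ)` gives the fold change
from the mean containing 99.7 % of technical variation. The histogram fit
and the direct sample SD are both reported; on clean data they agree.

## Pre-ranked enrichment

Peptide fold changes collapse to proteins by taking the maximum (positive
direction) or minimum (negative direction) peptide log2 FC per gene, ranked
descending with lexicographic tie-breaks for determinism. The enrichment
score is the classic weighted running sum (weight p = 1): hits add
`|s|/Σ_hits|s|`, misses subtract `1/(N−N_hits)`, and the ES is the signed
maximum deviation (an exact tie between the positive and negative extreme
resolves to the negative one, the convention of pre-ranked tools). The null
is gene-label permutation — appropriate because the input is a pre-ranked
list, not per-sample phenotypes — with the sign-matched estimator
`p = (count+1)/(m+1)`, NES as ES over the mean same-sign null magnitude
(a documented stand-in for the external tool's internal scheme), and BH
FDR across sets. Reported sets pass p ≤ 0.05 and q ≤ 0.25 with a minimum
overlap of 8 genes (15 recommended for expression-level lists).

## What the simulator does and does not emulate

`generate_replicate_experiment()` draws base abundances lognormal
(median 10⁶, ~2 natural-log units of spread), applies per-peptide condition
fold changes compressed as `fold^(1/γ)` (a simple, invertible power-law
model of dynamic-range suppression), multiplies by per-sample loss factors
`k_s`, splits each peptide over a Poisson number of PSMs with normalized
lognormal shares, and finally applies independent lognormal reporter noise
(σ_log2 = 0.2 by default) to every reporter measurement. Standards are
injected through the identical loss/noise path — the premise of the method —
at the reference design's amounts: two correction standards at 30 fmol and
one standard titrated 30–300 fmol, with 10 PSMs per standard. All draws are
reproducible from a single seed.

The generator emulates sample-level losses, ion suppression, reporter noise
and PSM multiplicity. It does **not** emulate co-isolation interference,
peptide-specific ionization efficiency, missing-value mechanisms that
correlate with abundance, retention-time drift, or spectrum-level effects.
Passing tests therefore demonstrate the estimators are correct under the
stated generative model, not that real acquisitions are free of those other
artifacts.

One quantitative consequence of the independent per-channel noise model is
worth stating: a channel ratio of two measurements with σ_log2 = 0.2 each
has σ_log2 ≈ 0.28, so the median of the 20 pooled correction-standard
ratios per channel carries a standard error near 0.08 log2 units, and the
probability that a factor lands within 0.1 log2 of truth is about 80 % —
reaching 95 % needs roughly 50 standard PSMs. The factor-recovery test at
50 PSMs per standard reflects what the model supports; deeper standard
sampling (or channel-correlated noise) is what an experiment would need for
tighter factors.

## Numerical choices and problem sizes

* Quantiles are type-7; all filter thresholds are inclusive as printed.
* Gaussian fits (elution profiles, histogram fits) use Levenberg–Marquardt
  least squares with data-driven starts; profile fits that fail fall back
  to the tallest scan and are flagged rather than erroring.
* Degenerate t tests (zero variance in both groups) return p = 1 for equal
  means and p = 0 otherwise, the continuous limit of the statistic.
* Back-calculated amounts below the calibration intercept clamp to 0 fmol
  with a warning; a negative amount is not physical.
* Validation suites run on deliberately modest problem sizes — hundreds to
  two thousand peptides, 100–200 seeded repetitions — chosen so the whole
  suite completes in a couple of minutes while keeping Monte-Carlo error
  well below the tested tolerances.

## Known limitations

Cross-plex (bridge-channel) harmonization, FDR re-estimation, match-between-
runs modelling and spectrum-level simulation are out of scope. NES values
are not numerically comparable to those of external desktop tools, only
rank-comparable. The mean-centered test inherits the usual caveat of global
normalization: if most of the repertoire truly moves, "enrichment above the
mean" understates biology by construction.
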