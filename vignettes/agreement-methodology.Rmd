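---
title: "Assessing agreement between paired pharmacogenomic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing agreement between paired pharmacogenomic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxagree)
```

## The problem

Large cell-line drug screens summarize each (cell line, drug) pair by a
dose–response statistic — an activity-area AUC (a fraction in [0, 1],
higher = more sensitive) or an IC50 (the concentration reaching half-maximal
inhibition, in µM, analysed on the log10 scale, and censored when it
exceeds the tested concentration range). When two groups screen overlapping
panels, two questions arise:

1. **How consistent are the raw measurements?** Per drug, how well do the
   two studies' response profiles correlate across shared cell lines; per
   gene, how well do their molecular profiles agree?
2. **How consistent are the conclusions?** Do the two studies find the same
   gene–drug associations?

The second question is where analysis design quietly matters. If an analyst
reuses one study's mutation calls in both studies' association analyses, the
genomic measurement error becomes *identical* on both sides — an information
leak that can only push apparent concordance upward. Likewise, comparing one
study's IC50-based associations to the other study's AUC-based associations
compares different quantities. This package implements the independent
comparison, the two leaky designs, and a simulation framework that
quantifies the inflation they produce.

## Agreement statistics and thresholds

Per entity (drug or gene) across the common cell lines we compute:

* **Pearson correlation** for continuous data (AUC, log10 IC50, expression,
  copy number). Classification: ≥ 0.8 `GOOD` (the FDA/MAQC
  inter-laboratory reproducibility criterion, boundary inclusive),
  \> 0.5 `REASONABLE`, else `BELOW`.
* **Cohen's kappa** for binary data (mutation status, sensitivity calls):
  κ = (p_o − p_e) / (1 − p_e), classified on the Landis–Koch bands
  (left-closed: 0.2 `FAIR`, 0.4 `MODERATE`, 0.6 `SUBSTANTIAL`,
  0.8 `ALMOST_PERFECT`).

Undefined statistics (fewer than `min_pairs` complete pairs, default 10, or
degenerate marginals) are reported as missing, never as zero; all summary
fractions state their denominators. Correlation on fewer than 10 pairs is
noise-dominated, hence the default.

A **union-of-tests** fraction ("the share of drugs passing *any* criterion")
is computed on request but always labelled non-evidential: it is monotone in
the number of measures added, so adding measures — even uninformative ones —
can only raise it. The per-measure fractions are the evidence;
`union_of_tests()` carries a `non_evidential` flag and the pipeline prints
the warning next to the number.

Distributions of per-entity consistency are compared between data types
(e.g. copy number vs drug response) with a one-sided Wilcoxon rank-sum test:
exact enumeration when the combined sample is ≤ 16 without ties, otherwise
the normal approximation with tie and continuity corrections.

## Sensitivity calling

Two binarization rules are implemented:

* **Fixed cutoffs**: AUC ≥ 0.2 sensitive; IC50 ≤ 1 µM sensitive. Both
  boundaries are inclusive on the sensitive side; the AUC rule is inclusive
  as printed, and for IC50 we treat "above 1 µM" as the insensitive side, so
  exactly 1 µM is sensitive. Both cutoffs are configurable in
  `threshold_config()`.
* **Waterfall**: a drug's values are sorted in decreasing order to form the
  response-distribution curve. If the curve is essentially linear (Pearson
  correlation with its least-squares line over rank ≥ 0.95) there is no
  inflection and the cutoff is the median; otherwise both axes are min-max
  scaled to [0, 1] and the cutoff is the value at maximal perpendicular
  distance from the chord joining the curve's endpoints. The 0.95 linearity
  threshold is the conventional choice and is exposed in
  `threshold_config()`; the min-max scaling makes the inflection scale-free;
  ties in the maximal distance break towards the smallest rank (the
  most-sensitive end), making the rule deterministic.

Cutoffs are always computed on a study's **full** panel and only then are
calls restricted to the cell lines shared with the other study
(`call_waterfall(..., restrict_to = )`). Restricting first would let the
other study's panel composition influence this study's cutoff — a subtle
dependence between supposedly independent analyses. The subset-stability of
calls is enforced by tests.

Degenerate inputs: a constant response vector returns the constant as
cutoff, flagged `degenerate`; a drug with fewer than three non-missing
values yields missing calls with a warning rather than aborting a
screen-wide run.

## The association screen and the three designs

Per (gene, drug), the association test is the equal-variance two-group t
test of mean response in mutant vs wild-type lines — identically the
one-way ANOVA on mutation status (F = t²) — with Benjamini–Hochberg
q-values per study across the whole grid. Groups below `min_group = 3` make
the test undefined (flagged, not fabricated). Tissue covariates are out of
scope: the design question concerns *what data are shared*, not the
covariate structure of the per-study model.

The three comparison designs differ only in wiring:

| design | mutation data | measures |
|---|---|---|
| A (independent) | each study's own | same on both sides |
| B (shared) | one study's, duplicated | same on both sides |
| C (shared + mixed) | one study's, duplicated | IC50 vs AUC |

`biomarker_concordance()` then reports the Pearson correlation of effect
sizes and the kappa of significance calls between the two studies' result
lists. Every result row records which mutation matrix and which measure
produced it, so a leaked design is auditable from its output.

## The synthetic generator

`generate_pair()` draws a latent truth and two noisy views of it:

* latent sensitivity `s(c, d) ~ N(0, 1)` plus `effect_beta ·
  mut(c, g)` for each causal pair `(g, d)`;
* each study observes `√R·s + √(1−R)·ε` with fresh noise — reliability `R`
  is the fraction of observed variance that is signal, so the expected
  inter-study correlation is exactly `√(R₁R₂)` (`expected_attenuation()`);
* the observation is mapped to AUC by a fixed logistic squash
  `plogis(0.6·z)`. The scale 0.6 was chosen by a design-time calculation so
  the squash distorts Pearson correlations by less than 0.002 while keeping
  values inside [0, 1] — the attenuation law survives the transform;
* log10 IC50 comes either from a fixed decreasing nonlinear map
  `−(z + 0.15·z³)` of the same noisy observation (`monotone_nonlinear`,
  the default), or from an independent latent trait carrying the causal
  effects with opposite sign (`none`). The nonlinear link deliberately
  breaks the linearity between the two measures, which is exactly why
  mixed-measure comparisons (design C) are not comparisons of like with
  like; it also attenuates per-drug IC50 Pearson correlations below
  `√(R₁R₂)` (about 0.43 at R = 0.5), so attenuation checks are made on AUC;
* IC50 is censored at `log10(ic50_max_conc)` (default 8 µM, a typical top
  tested concentration), values at the bound flagged rather than dropped;
* latent mutations are Bernoulli(prevalence 0.2); each study miscalls them
  with symmetric flip probability (default 0.1);
* expression and copy number are independent latent features observed at
  reliabilities 0.8 and 0.9 — replicating the empirical ordering in which
  copy number is most consistent, expression close behind, and
  pharmacological measures far lower (default 0.5, the level implied by
  same-protocol replicate screens correlating near 0.5).

All randomness derives from one seed through fixed per-component
substreams, so adding a data type never perturbs the others, and
`write_fixture()` output is byte-reproducible.

Default panel dimensions are 400 cell lines × 15 drugs × 50 genes with 15
causal pairs at `effect_beta = 1`. The drug count matches a typical shared
drug panel; the cell-line count is the order of overlap between large
public screens and was additionally sized by a power calculation: with flip
rate 0.1 the observed-mutant group is only ~69% true mutants, diluting the
observed effect to ≈ 0.47·β latent SD, and a 750-test BH correction then
needs n ≈ 400 for the per-pair t (≈ 4.1 at β = 1) to clear the threshold.
A generator whose planted effects are undetectable cannot support any
statement about the concordance of detected biomarkers.

### What the generator does not emulate

Real screens have tissue-of-origin structure, batch effects, heavy-tailed
and multimodal response distributions, correlated genes, and cell-line
misidentification. Passing tests on this generator therefore demonstrate
the *statistical logic* of the agreement assessment — attenuation,
leak inflation, threshold behaviour — not that any particular pair of real
studies is consistent or inconsistent. There is an optional `study_bias`
term (default 0) for a protocol-level offset, but no attempt to match real
marginal distributions.

## The leak-inflation experiment

The headline simulation (`run_design_comparison()`) repeatedly generates a
pair, screens it under designs A and B, and compares the per-replicate hit
kappas. With miscalled mutations (flip 0.2) and real effects (β = 1),
design B's shared errors make the two studies' t statistics co-vary, so its
hit agreement systematically exceeds design A's; with flip rate 0 the two
designs use bit-identical inputs and the difference is exactly zero.

The experiment is run at 800 cell lines × 150 drugs × 50 genes with one
causal gene per drug. These sizes are a Monte-Carlo design choice, not a
data claim: the per-replicate κ difference has standard deviation
proportional to 1/√(number of causal pairs), and 150 causal pairs with
per-pair power ≈ 0.6 puts the mean inflation (≈ 0.10) three standard
deviations above zero, so the per-replicate ordering is stable by
construction. One causal gene per drug avoids inflating response variance
through overlapping effects.

## Worked example

```{r example}
params <- simulation_params(seed = 1)
pair <- generate_pair(params)
pair

ps <- intersect_studies(pair$study_a, pair$study_b)
per_entity_consistency(ps, "AUC")
per_entity_consistency(ps, "CNV")

scr <- run_association_screen(ps, design_spec("B"))
head(scr$study_a[order(scr$study_a$p), ], 3)
```

A full report bundle, including the design comparison, comes from
`run_full_assessment(pair, "out/")`, or from the command line via the
script in `inst/cli/pgxagree.R`.

## Numerical choices and limitations

* Correlations involving IC50 are always computed on the log10 scale.
* Harmonization of identifiers is uppercase-plus-strip-non-alphanumerics
  with exact matching; no synonym tables. Colliding labels are an error, not
  a silent merge.
* No imputation anywhere: missing values propagate and each statistic uses
  its own complete pairs.
* No multiple-testing correction on descriptive per-entity correlations;
  BH only on the association grid.
* Spearman or concordance-index variants of the consistency metrics are a
  documented extension point, not implemented.
* The elastic-net multivariate predictor sometimes used for cross-study
  signature comparison is represented here by the univariate screen; the
  design flaws it can carry (shared genomic data, mixed measures) are
  preserved exactly, the multivariate machinery is not.
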