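---
title: "Multiomics survival-feature extraction and evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiomics survival-feature extraction and evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`survomics` implements a feature-engineering and evaluation pipeline for
predicting dichotomized (2-year) survival of tumor cohorts from five
omics layers: somatic mutations, copy-number variation (CNV), mRNA and
miRNA expression, and DNA methylation. The scientific problem it
addresses is that mutation and CNV data are extremely sparse at the
variant level — two tumors rarely share the same variant — so useful
predictors only emerge after aggregation. The package provides the
aggregation methods, two feature-selection engines, and a leakage-free
evaluation protocol, and ships a synthetic cohort generator with planted
signal so every step can be tested end to end without access to
controlled patient data.

## Survival dichotomization

Patients who died before the horizon (default 730 days) are
nonsurvivors; patients who died at or after it, or who were alive with
follow-up of at least the horizon, are survivors. Patients alive at last
contact before the horizon are excluded — their 2-year status cannot be
ascertained. A death exactly on day 730 counts as survival by default
("died within two years" read strictly); the boundary is configurable
because sources rarely state it. Deaths from causes other than cancer
can optionally be excluded when the annotation supports it. Raising the
horizon can only move patients from labeled to excluded, never back —
the monotone data-loss property the test suite asserts.

## Mutation featurization

Four methods, all sharing the same variant input (MAF-like TSV with
1-based coordinates and VCF-style anchored indel alleles):

* **Gene level**: a gene scores 1 for a sample if it carries at least
  one protein-altering mutation (Missense, Nonsense, Frame-Shift,
  In-Frame, Splice-Site, Nonstop, Translation-Start-Site), 0 otherwise.
  The restriction is configurable because curation practices differ.
* **Gene set**: binary gene indicators are summed over curated gene
  sets (GMT/MSigDB format), yielding the number of mutated member
  genes. This rescues signal spread mutually exclusively across a
  pathway: no single gene is associated with outcome, but their union
  is. Summing binary indicators (not raw mutation counts) is the
  default, consistent with the gene-level binarization; a raw-count
  mode is available through `protein_altering_only = FALSE`.
* **Mutation catalogues**: fixed category schemes for single-base
  substitutions in trinucleotide context (SBS96), doublet substitutions
  (DBS78) and small indels (ID83). SBS variants are normalized to a
  pyrimidine reference base by reverse complement. Doublets are
  canonicalized to ten reference doublets; for the four palindromic
  references the alternate is collapsed with its reverse complement,
  choosing the lexicographically smaller representative (the scheme has
  exactly 78 categories and is strand-involution invariant; the
  representative choice is a labeling convention). Indels are binned by
  length, repeat-unit count (counting adjacent whole copies on both
  sides of the event) and, for non-repeat deletions, flanking
  microhomology — 12 + 12 + 24 + 24 + 11 = 83 categories following the
  COSMIC v3 convention. Each variant contributes to exactly one scheme,
  so catalogue totals conserve classifiable variant counts.
* **Signature exposures**: per-sample non-negative least squares
  attribution of an SBS96 catalogue to a supplied reference-signature
  matrix (probability columns). Plain NNLS is used — no exposure
  thresholding or bootstrapping — because it is deterministic,
  reproduces any catalogue inside the signatures' non-negative cone
  exactly, and its mixture-recovery error is directly measurable on
  simulated catalogues.

## CNV featurization

Segments arrive as (sample, chrom, start, end, segment mean) with the
segment mean on the log2(CN/2) scale, so 0 is the neutral diploid state.
`partition_segments` forms elementary intervals from all segment
breakpoints per chromosome, paints each sample's segment mean onto them,
drops intervals altered in fewer than two samples, and merges adjacent
intervals whose per-sample profiles agree in at least `frac_overlap`
(default 0.9) of samples, with length-weighted means on merge. The
merging rule is this package's concretization of "partial overlap"
region aggregation: it is defined precisely, oracle-tested against a
base-pair-resolution reference implementation, and at `frac_overlap = 1`
merges only intervals identical in every sample. No claim of
bit-compatibility with any other implementation is made.

Gene-level CNV assigns each gene the segment mean of the overlapping
altered region — deliberately also when the region covers only part of
the gene — with the largest-overlap region winning when several
overlap. Genes in one altered region therefore share values exactly,
which is why the correlation filter (below) matters downstream.
Gene-set aggregation of CNV uses the mean of signed segment means
(sum would conflate set size with amplitude; absolute values would
erase the gain/loss direction).

## Expression and methylation

Counts are filtered (feature kept iff any sample has ≥ 10 reads) and
normalized by median-of-ratios size factors: per-feature geometric means
over all-positive features, per-sample median of count/geomean ratios.
Only the size-factor component of that normalization family is
implemented because the pipeline consumes a normalized matrix, not
differential-expression tests. The estimator is scale-equivariant and is
cross-checked against an independent implementation in the test suite
(the two differ only in taking the median on the linear versus log
scale, which matters at the 4th decimal for even feature counts).
Methylation beta values pass through unchanged. PCA feature extraction
(prcomp, centered, not scaled) is provided with a deterministic sign
convention — the largest-magnitude loading of each component is made
positive.

## Feature selection

Constant features are removed first; then a greedy correlation filter:
among remaining pairs with |Pearson r| above the cutoff (default 0.9),
process in descending |r| and drop the member with the larger mean
absolute correlation against all remaining features, ties broken toward
the later column for determinism. The output provably contains no pair
above the cutoff and matches an exhaustive reference implementation on
small instances.

Two selection engines:

* **Lasso AUC profile**: L1-penalized logistic regression along a
  decreasing penalty path (standardized predictors), with
  stratified-fold cross-validated AUC recorded at every path point next
  to the nonzero-coefficient count on the full data. The profile is
  path-indexed (the model at "k features" is the path model with k
  nonzero coefficients, not a refit on the top k).
* **Shadow-feature (Boruta-style) ranking**: each run adds a permuted
  shadow copy of every undecided feature, fits a random forest (500
  trees by default) and uses the permutation-importance Z-score (mean
  decrease in accuracy over trees divided by its standard error). A
  feature scores a hit when it beats the best shadow. Two-sided binomial
  tests at success probability 0.5, Bonferroni-corrected over the
  currently undecided features at level alpha (default 0.01), promote to
  Confirmed or demote to Rejected; rejected features leave the model;
  undecided features at `max_runs` (default 10,000) are Tentative and
  reported as such, with mean importance over runs as the ranking
  statistic. One known limitation: decisions are invariant to feature
  order only up to random-number coupling; base R's single RNG stream
  does not permit the per-feature stream splitting that exact
  order-invariance would need.

## Evaluation

Nested cross-validation: a stratified outer 10-fold split estimates
performance; inside each outer training portion the classes are
balanced by down-sampling (minority kept in full, majority subsampled
without replacement to 30% by default — a 178/89 training imbalance
becomes 54/89); an inner leave-one-out loop scores each of 10 candidate
values of the forest's variables-per-split parameter by pooling all
leave-one-out predictions into a single AUC (single-sample folds admit
no per-fold ROC, so pooling is forced); the winner is refit on the
balanced training portion and applied to the untouched outer test fold.
Balancing happens strictly inside outer training folds — test folds
never influence balancing, tuning or fitting. The candidate grid is
evenly spaced on the square-root scale between 2 and the feature count,
so the conventional sqrt(p) default sits mid-grid. Outer predictions
pool into one ROC/AUC per repeat (rank-statistic AUC with midranks for
ties); the whole procedure repeats (default 100 times) with per-repeat
seeds derived from the master seed.

SHAP attributions use Monte-Carlo sampling of feature coalitions: per
explained sample and simulation, a random background row and feature
ordering are drawn and each feature's contribution is the prediction
change when it flips from background to explained value given its
predecessors already have — a chain that needs p + 1 model evaluations
per simulation. Positive values push toward the nonsurvivor class.
Attributions are computed by the outer-fold model that predicted each
sample and averaged over repeats.

# The synthetic cohort

The generator emulates the statistical shape of a lung-adenocarcinoma
multiomics cohort; its defaults are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| samples / nonsurvivor fraction | 267, 1/3 | the cohort shape the pipeline is designed around (89 nonsurvivors, 2:1 imbalance exercising the balancing path) |
| planted pathway | 4 genes, mutually exclusive, mutation probability 0.55 (nonsurvivor) vs 0.28 (survivor) | see the design note below |
| background mutation rate | 0.05 per gene | sparse gene-level matrix, as in real WES cohorts |
| expression | negative binomial, var = mu + mu^2 * 0.2; 5 planted genes at log2 fold change 1.5 | standard bulk RNA-seq count model; effect large enough for single-cohort recovery |
| methylation | Beta with concentration 30; 5 planted probes shifted by 0.2 | beta values in [0,1] with realistic within-group spread |
| CNV | 8 random segments/sample, CN in {0,1,3,4} on log2(CN/2) (CN 0 floored at 0.25, i.e. −3, to keep segment means finite); planted amplified region at gain probability 0.5 vs 0.2 | piecewise-constant segment structure with one recurrent class-biased event |
| censoring | 8% extra early-censored cases | exercises the exclusion logic without shrinking the labeled cohort |
| genome | one chromosome, 60 genes of 200 bp | compact fixtures; every coordinate-dependent path (context lookup, repeat counting, overlap) is exercised at full fidelity |

Background mutations never hit the planted pathway genes, so the
pathway's mutual exclusivity holds by construction, not approximately.
All randomness flows from a single seed through fixed per-section
offsets, so identical specs produce byte-identical bundles.

**Design note on the mutually exclusive pathway.** The pathway effect is
the one place where the planted design needs care. The property of
interest is that no single pathway gene is associated with outcome while
the pathway aggregate is. If per-gene "significance" were judged at an
uncorrected 0.05, that joint event is rare for *any* effect size: an
aggregate strong enough to be reliably significant forces per-gene
z-scores of roughly z_aggregate/sqrt(pathway size) above the
significance region too often (a design simulation bounds the joint
probability at about 0.25). The per-gene calls are therefore
Bonferroni-corrected across the full gene scan — exactly what a
genome-wide per-gene association analysis does in practice. At pathway
size 4 and probabilities 0.55/0.28, design simulation puts the aggregate
association at p < 0.05 in essentially every cohort draw while planted
per-gene tests pass the corrected threshold in only a few percent of
gene-by-cohort draws. These parameters were fixed by that design
computation before the test suite was written.

**What the generator does not emulate**: mutation hotspots and
signature-correlated positional biases, linkage between omics layers
beyond the shared class labels, batch effects, platform-specific missing
probes, and real gene/pathway topology. Passing tests therefore
demonstrate that the machinery is correct and calibrated — not that the
planted effect sizes match any real cohort's.

# Problem sizes in tests and the acceptance script

The inner leave-one-out loop is the expensive step (one forest fit per
candidate per training sample per outer fold per repeat), so
cross-validation-based checks run on reduced study sizes chosen once:
null-calibration cohorts of 80 samples with 20 features, tuning grids of
3 candidates, forests of 100 trees and 10–20 repeats; Boruta recovery
runs on the full 267-sample default cohort with 300 trees and a 300-run
cap (decisions for this feature count typically settle within ~60 runs;
the cap only limits how long Tentative features are pursued). The
reported AUCs are means over repeats of pooled outer-fold AUCs.

# Numerical and degenerate-input choices

* Missing values are `NA` end to end and never imputed; samples with
  missing features are dropped (and counted) before nested CV, since a
  forest cannot score them.
* Zero-variant samples yield all-zero catalogue rows, and all-zero
  catalogue rows yield zero exposures with zero reconstruction error.
* An empty segment list yields an empty partition; an empty feature
  matrix yields an empty Boruta result with zero runs.
* Penalty paths start at the data-derived maximal penalty (zero nonzero
  coefficients); path points are reported up to 100 nonzero features.
* All readers fail fast with 1-based line numbers (the header is
  line 1) naming the offending column or value.
* The pipeline runner hashes stage inputs and parameters; reruns with
  unchanged hashes skip the stage, and any stage error aborts the run
  naming the stage.
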