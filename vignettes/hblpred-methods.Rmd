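---
title: "Predicting bacterial hemoglobin-like proteins: models and methods"
author: "hblpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial hemoglobin-like proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hblpred)
```

## The problem

Bacterial hemoglobin-like (HbL) proteins share the globin fold but are
sparsely and inconsistently annotated. Three structural arrangements occur:
single-domain hemoglobins (sHb, the classical globin fold, e.g. the
*Vitreoscilla* hemoglobin), truncated hemoglobins (trHb, with shortened
helical structure), and chimeric flavohemoglobins (flavoHb), where the
globin domain is fused to reductase machinery. The flavohemoglobins
subdivide further by domain architecture: globin with only insignificant
FAD-domain similarity (`fg_FAD_insig`), globin plus a C-terminal cytochrome
reductase and FAD/NAD-binding FR-type domain (`fg_cyto_FAD_NAD`), and
globin plus an FAD/NAD-binding FR-type domain alone (`fg_FAD`).

`hblpred` predicts and classifies these proteins from sequence alone with
RBF-kernel support vector machines over composition-based feature
encodings, organised as a three-stage hierarchy:

1. **Stage 1** — HbL vs non-HbL (one binary SVM, decision threshold 0.0).
2. **Stage 2** — subfamily assignment (sHb / flavoHb / trHb), one-vs-rest
   within the HbL set.
3. **Stage 3** — five-way domain-subgroup assignment, one-vs-rest within
   the HbL set.

## Feature encodings

All encoders operate on validated sequences over the 20-letter alphabet in
alphabetical order `ACDEFGHIKLMNPQRSTVWY`.

* **AC** (20-dim): amino-acid composition, the fraction of each residue,
  `count(i) / L`.
* **DC** (400-dim): dipeptide composition over ordered residue pairs,
  `count(ab) / (L - 1)`. The denominator is the number of overlapping
  dipeptide windows actually present in the sequence (not the fixed 400),
  so the vector sums to 1; indexing is row-major, first residue slowest,
  both alphabetical — documented so saved models stay portable.
* **MM** (20-dim): the AC vector re-ordered along the fixed
  most-to-least-abundant residue order of the average HbL sequence,
  `ALEKIVGDPNFQRTMYSHWC`. This is a pure permutation of AC; since the RBF
  kernel is permutation-invariant, AC and MM models trained with identical
  hyperparameters are mathematically identical. Both encoders exist because
  both are established practice and their published working points differ;
  no attempt is made to manufacture a difference.
* **HYBRID** (420-dim): AC followed by DC.
* **PSSM** (400-dim): each row of a position-specific scoring matrix is
  min-max normalized, `(v - min) / (max - min)`, mapping the row minimum to
  0 and maximum to 1; a 20 x 20 accumulator then sums, for each query
  residue `a` and substitution column `b`, the normalized scores over all
  positions carrying `a`, and divides by the sequence length.

All composition features are kept as fractions in [0, 1], never
percentages; published gamma values are scale-dependent, so the scale is
fixed and documented here once. The grouping of the PSSM accumulator — by
query-sequence residue (rows) against all 20 substitution columns — is the
standard PSSM-400 construction; the transpose reading of the ambiguous
phrase "composition of occurrences of each type of amino acid" is
explicitly not used.

Two numerical conventions deserve note. A constant PSSM row would divide by
zero under min-max normalization; it maps to all zeros (rather than 0.5) to
preserve sparseness and determinism. And the compatibility formatter
`truncateDecimals()` floors rather than rounds, because the reference
normalization table prints `236/1433 = 0.16468...` as `0.1646`; full
floating precision is kept everywhere outside that formatter.

## The SVM core

Binary classifiers are soft-margin SVMs with the radial basis kernel
`K(x, y) = exp(-gamma * ||x - y||^2)` and box constraint C — the only
kernel used, since every published working point is a (gamma, C) pair. The
quadratic program is solved by libsvm (through \pkg{e1071}, tolerance 1e-3,
no feature scaling); the package stores support vectors, signed dual
coefficients and bias in its own [SVMModel-class] and evaluates the
decision function by its own kernel expansion, so saved models are
self-contained versioned JSON text and scores reproduce to ~1e-12 after a
round trip. A decision score exactly on the threshold classifies
*positive*: the published threshold convention ("cutoff 0.0") does not
specify the boundary, so the `>=` rule is fixed and documented.

Per-task default hyperparameters (`defaultParams()`) are the published
working points, e.g. gamma = 25, C = 400 for stage 1 with AC and gamma = 5,
C = 7 for the sHb task with PSSM features. They were tuned on a curated
UniProt/SwissProt snapshot that is not deposited; on other data they are
starting points, not optima.

## The hierarchy

The published system never states how the three one-vs-rest subfamily
outputs combine into a single call. This package adopts the arg-max of the
decision scores, with ties broken by the fixed task order (sHb, flavoHb,
trHb; analogously for the five domain tasks), and calls a sequence
*unclassified HbL* (subfamily `NA`) when all scores are negative. This is
consistent with observed confusions flipping between flavoHb and trHb
rather than falling out of the hierarchy. Sequences negative at stage 1
receive no subfamily or domain call at all (gating). Stage 3 runs all five
domain models on every stage-1-positive sequence rather than only within
the predicted subfamily — the flat choice, made because the serving
behaviour of the original system is unstated.

The `single_domain` and `trunc_domain` subgroup tasks have positive sets
identical to the sHb and trHb subfamily tasks (their published performance
rows coincide), so the registry shares those model objects instead of
retraining them, avoiding silent divergence.

## Evaluation protocol

Performance is measured by k-fold cross-validation (default k = 5): a
seeded shuffle with round-robin assignment yields folds whose sizes differ
by at most one; stratified assignment is the default because the smallest
class (sHb at desk scale) otherwise produces class-empty training folds.
Metrics follow the standard confusion-count definitions (ACC, SN, SP, FPR
as percentages; MCC in [-1, 1]); any metric with a zero denominator is
reported as `NA` with a warning, never silently as zero. Fold-accuracy
dispersion uses the sample standard deviation (n - 1); both the mean of
fold accuracies and the metrics of the pooled confusion counts are
reported, since published accuracy figures do not state which convention
they use. ROC curves sweep all distinct decision-score thresholds
descending and integrate by the trapezoidal rule, which makes the AUC equal
to the tie-corrected normalized Mann-Whitney statistic — an identity the
test suite asserts against an independent rank-based oracle.

## Dataset curation

`filterAnnotations()` removes records whose descriptions contain any of the
annotation keywords *fragment, isoform, potential, similarity, probable*
(case-insensitive substring on the description only; singular forms so
plurals also match). `reduceRedundancy()` applies a greedy CD-HIT-style
filter: records are visited longest-first (ties by id) and kept only if
their identity to every kept record is at most the cutoff (0.9
conventionally). No tool is named in the original protocol, so the
alignment is pinned down exactly: Needleman-Wunsch global alignment with
match = 1, mismatch = 0, linear gap -1, identity = matches divided by the
*shorter* sequence length. The shorter-length denominator is a documented
package choice — the original 90% filter does not state its denominator —
chosen as the more conservative convention (it never under-reports identity
relative to the alignment-length denominator).

## Synthetic data: what it emulates and what it does not

The generator (`generateDataset()`) draws sequences i.i.d. per residue from
class-specific probability profiles. The default profiles encode the
reported compositional structure of curated HbL datasets: HbL classes are
0.5% enriched in Ala/Glu/His, non-HbL in Ser/Thr, and lysine exceeds 8% in
sHb. Flavohemoglobin subgroup contrasts (G/Q, V/M, F/Y at +0.6%) and the
trHb arginine bias are synthetic choices that give each subgroup a
distinguishable composition. Length ranges: flavoHb 300-500 residues (the
documented range of the longest architecture), sHb 110-160 and trHb
100-140 (plausible globin lengths, not literature values), non-HbL
100-500. The `separation` parameter scales every profile's divergence from
the uniform baseline: 1 reproduces the stated biases, 0 is an exact
permutation null, and 8 is used as the "high separation" setting in the
separability benchmarks.

Because residues are drawn independently, the data contain the
composition-level signal the implemented encoders consume and *nothing
else*: no motifs, no phylogenetic correlation, no realistic PSI-BLAST
profile structure. Passing benchmarks on this data therefore demonstrates
that the pipeline is correct and can recover compositional class structure;
it does not certify accuracy on real proteins, where the published figures
came from a curated 333 + 337 sequence snapshot that is not deposited.
Synthetic PSSMs (`generatePSSM()`) place a signal-scaled high score on each
position's own residue column plus seeded integer noise — format-valid and
learnable, but not evolutionary profiles.

## Problem sizes

The bundled benchmarks run at desk scale, chosen to exercise every code
path with comfortable statistical margins: the metric oracle sweeps the
exhaustive confusion grid up to counts of 10; the AUC identity uses 200
random score sets; cross-validation benchmarks use a balanced 200 + 200
binary design at separation 8 (where pooled accuracy exceeds 95% and
permuted labels fall within 10 points of chance); the end-to-end hierarchy
trains on 200 sequences per generator class and evaluates subfamily
recovery (>= 95%) on 50 fresh sequences per class.

## Known limitations

* The published headline accuracies (86.14% AC, 90.20% PSSM, etc.) are not
  reproducible without the original dataset snapshot; this package
  reproduces the *method*, and its printed normalization example, exactly.
* PSI-BLAST itself is out of scope: PSSMs are parsed inputs (or synthetic
  fixtures), never computed from a database search.
* i.i.d. synthetic sequences cannot validate motif- or alignment-aware
  extensions; a future positional encoder would need a richer generator.
* MM and AC differ only by a feature permutation, so under an RBF kernel
  they are redundant encoders kept for interface fidelity.
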