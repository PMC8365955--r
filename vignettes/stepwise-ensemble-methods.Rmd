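---
title: "Step-wise stacked ensembles for hERG blockade: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-wise stacked ensembles for hERG blockade: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blockade of the hERG potassium channel (Kv11.1) by small molecules
prolongs the cardiac QT interval and is a standard cardiotoxicity
liability screened early in drug discovery. The classification task is
binary: a molecule is a *blocker* when its measured IC50 against hERG is
below 10 µM, a *non-blocker* otherwise. Input is a SMILES string; output
is a probability of blockade, thresholded at 0.5 (a probability greater
than or equal to 0.5 declares a blocker).

`hergstack` implements a stacked ("meta-ensemble") classifier over five
molecular views, trained *step-wise*: the first-stage (base) models and
the second-stage (meta) model are fitted on disjoint data partitions so
that the stacking stage never sees probabilities produced on molecules
the base models trained on. This is the core methodological idea the
package reproduces; everything else (featurization, metrics, diversity
analysis, synthetic data) is the machinery around it.

## The pipeline

1. **Standardization** (`standardize_molecule`): parse, keep the largest
   fragment (salt stripping), neutralize formal charges, canonicalize.
   Parsing and canonicalization are delegated to Open Babel through
   ChemmineOB. Duplicated canonical SMILES with consistent labels
   collapse to one record; molecules reported with both labels are
   removed outright (`reconcile_labels`).
2. **Splitting** (`stepwise_split`): a seeded shuffle followed by a
   contiguous 70/10/10/10 cut into base-train / base-valid / meta-train /
   meta-valid. No class stratification is applied. For cross-validated
   results, `consecutive_cv_folds` cuts the data into *k* consecutive
   parts and rotates the three held-out roles over the parts; the
   remaining *k* − 3 parts train the base models.
3. **Featurization**: five fixed-shape views per molecule (below).
4. **Individual prediction stage**: five neural base models, one per
   view, trained with Adam on binary cross-entropy; the epoch checkpoint
   with the best validation AUC is kept.
5. **Meta-ensemble stage**: base-model probabilities on the meta-train
   partition are concatenated column-wise into meta features; a small
   fully connected network is trained per feature combination; all
   2^5 − 1 = 31 member subsets are searched and the winner is the
   combination improving the most metrics over the best single-view
   baseline (ties broken by MCC, then by smaller combinations).

## The five molecular views

| view | shape | featurizer |
|------|-------|-----------|
| DESC | 995 | physicochemical descriptor panel, min–max normalized |
| MGF  | 50×65 nodes + 50×50 adjacency | molecular graph |
| MFP  | 1905 bits | 1024-bit ECFP2 + 881 substructure keys |
| SeV  | 97 token ids | SMILES token sequence |
| FPeV | 93 indices | on-bit positions of a 1024-bit radius-2 Morgan fingerprint |

**Descriptors (DESC).** The panel is computed in-package: an Open Babel
physicochemical block (H-bond acceptors/donors, logP, molar
refractivity, molecular weight, TPSA), constitutional counts (elements,
degrees, bonds, rings, rotatable bonds, charges), topological indices
(Wiener, Zagreb, Randić/chi, Balaban J, kappa shape, eccentricities),
2D autocorrelations (ATS/AATS/ATSC/Moran/Geary over atomic mass,
electronegativity, polarizability, van der Waals volume, degree and
H-count at topological lags 0–7) and Burden-matrix eigenvalue (BCUT)
descriptors. The implemented panel occupies roughly the first third of
the fixed 995-wide vector; the remaining slots are explicit zero padding
so the descriptor base model keeps the canonical input width. Constant
slots carry no information and normalize to 0. Conformer-dependent 3D
descriptors are deliberately not computed — the package does no 3D
embedding, so no descriptor can fail at embedding time. Normalization is
min–max, fitted on the base-training set only; held-out values are
clipped into [0, 1]; non-finite raw values become 0 *before*
normalization.

**Graphs (MGF).** Heavy-atom graphs parsed from canonical SMILES by the
package's own reader (elements, aromatic flags from lowercase notation,
formal charges, implicit hydrogens by the lowest-fitting-valence rule).
Atom features are 65-dimensional: a 43-element one-hot, degree (0–5),
total hydrogens (0–4), implicit valence (0–5), an aromaticity flag and a
formal-charge one-hot truncated to fit exactly 65 dimensions. The
adjacency matrix is raw 0/1 without self-loops; the graph-convolution
layer adds self-loops and applies the symmetric degree renormalization
internally. Molecules with more than 50 heavy atoms are dropped with a
logged count, never truncated — truncation would silently corrupt the
topology.

**Fingerprints (MFP, FPeV).** Morgan/extended-connectivity fingerprints
are computed in-package by deterministic neighborhood hashing on the
parsed graph; bits are therefore stable across platforms and invariant
to the SMILES writing order, but not bit-compatible with other
toolkits' hash functions (no downstream step requires bit
compatibility). The 1905-bit combined block concatenates the
diameter-2 (radius-1) 1024-bit fingerprint with an 881-bit
substructure-key block. For the key block no implementation of the
published 881-key definition exists in this stack, so the package ships
a documented stand-in: the published section-1 element-count keys and
section-3 bonded-pair keys are implemented faithfully, ring-count keys
are implemented in simplified form, and the residual width is filled
with hashed radius-2 circular keys. The fingerprint-index view lists
the sorted on-bit positions (1-based; 0 is the pad sentinel) of the
radius-2 1024-bit fingerprint, right-padded to length 93; molecules
with more on bits are truncated to the first 93 with a warning.

**Tokens (SeV).** The tokenizer treats bracket atoms, `Cl`, `Br` and
`%nn` ring closures as single tokens and every other character as its
own token. The vocabulary is frozen from the base-training corpus,
sorted lexicographically (C locale) for reproducibility, with index 0
reserved for padding. Unseen test-time tokens map to the pad index by
default (lenient mode) so inference never crashes; strict mode errors
instead. Sequences longer than 97 tokens are dropped, not truncated.

## Architectures and training

All base models are trained with Adam (learning rate 1e-4), batch size
32, 100 epochs in the reference configuration; the meta model with
learning rate 1e-3 and 300 epochs. The loss is binary cross-entropy on
a sigmoid output (implemented as logits + a numerically stable
log1p-exp loss). Hidden widths are reconstructions — the original
figures do not state them — and are configurable:

* **FCNND** 995 → 512 → 256 → 128 → 64 → 1, ReLU, kernel and bias L2
  0.01, dropout 0.5 on the middle hidden layers.
* **FCNNF** 1905 → 200 → 100 → 50 → 25 → 1, same family with smaller
  widths.
* **GCNN** two graph convolutions of 64 channels (ReLU, kernel L2 0.01)
  using the symmetric renormalized propagation rule with internal
  self-loops, gated attention pooling with 1024 channels (sigmoid gate ×
  linear transform, summed over real atoms; padded rows are masked out),
  a 1024-unit dense layer, sigmoid output. Pooling is a masked sum, so
  the output is invariant to atom reordering.
* **C1D** (SMILES and fingerprint-index variants) trainable embedding
  (vocabulary+1) × 200, three 1-D convolutions of 192 filters with
  kernels 10/5/3 (ReLU, valid padding), global max pooling, dense
  128 → 64 → 1.
* **FCNNM** (meta) input *k* (combination size) → 32 → 16 → 1.

The engine is a small matrix-based implementation written for this
package (dense, dropout, embedding, conv1d, graph convolution, gated
attention pooling; Adam; finite-difference-verified backpropagation).
Training is fully seeded: initialization, minibatch order and dropout
masks derive from the configuration seed, so a rerun reproduces the
loss trajectory bit for bit on the same BLAS. Model selection keeps the
best-validation-AUC epoch ("best base models"); final-epoch weights are
available by configuration.

The learning rate notation in the source material ("10e-4", "10e-3")
is read conventionally as 1e-4 and 1e-3. Dropout on FCNNF's middle
layers mirrors FCNND. The single-view (M1) meta rows feed the one base
probability to the meta model as a width-1 input — duplicating the
column would add no information.

## Metrics

`compute_classification_metrics` implements SEN, SPE, NPV, PPV, raw
accuracy, MCC and balanced accuracy from the confusion counts; AUC is
the tie-corrected Wilcoxon rank statistic (verified against exhaustive
pair enumeration in the tests). Any metric with a zero denominator is
reported as `NA` — the reporting convention of the comparison tables
this mirrors — rather than coerced to 0. Reports print both raw and
balanced accuracy: for the reconstructed external-test confusion
matrices the published "ACC" column is numerically the balanced
accuracy (e.g. 0.810 for the 30/14 set where raw accuracy is 0.818),
so both are emitted, clearly labeled.

## Diversity analysis

Tanimoto similarity |a∧b|/|a∨b| on 2048-bit radius-2 fingerprints, with
the convention that two all-zero fingerprints have similarity 1 and an
all-zero against anything else 0. Within-set diversity is the exact
mean over all unordered pairs (blocked matrix arithmetic, no sampling);
cross-set analysis reports each query molecule's maximum similarity to
a reference set. The 2-D projection is an exact (non-Barnes-Hut) t-SNE
written in-package — no t-SNE package is available in this stack — with
standard perplexity calibration, early exaggeration and adaptive gains;
it is seeded and intended for desk-scale set sizes (hundreds to a few
thousand molecules). Exact duplicates end up mutual nearest neighbors
at a small but nonzero separation: t-SNE's pairwise affinity is capped
near 1/2n, so coincident embedding of duplicates is not a property of
the method and is not asserted.

## The synthetic generator

`generate_synthetic_dataset` exists so every pipeline stage is testable
without downloading the original curated datasets. Molecules are
assembled from a grammar of chainable SMILES units (alkyl chains,
branches, carbonyls, ethers, amines, aromatic and saturated rings);
positives receive a planted pharmacophore-like motif — a basic tertiary
amine attached to a para-substituted chloroaromatic ring — at a random
position. Labels equal motif presence, then flip with the configured
noise rate. Chlorine occurs nowhere else in the grammar, and the
chlorine's radius-2 fingerprint environment never touches the
attachment point, so every motif occurrence sets the same designated
fingerprint bit; motif-free molecules whose hashed fingerprints collide
with that bit are regenerated (bounded retries). At zero noise a
single-bit rule on the designated bit therefore classifies perfectly —
the planted signal is recoverable from every feature view (chlorine
element counts, atom one-hots, tokens, fingerprint bits).

Defaults: n = 2000, positive fraction 0.5, noise 0, scaffold length 2–5
units, all molecules ≤ 50 heavy atoms and ≤ 97 tokens. What the
generator does *not* emulate: real hERG pharmacology, realistic
descriptor distributions, activity cliffs, or the class imbalance and
assay noise of curated bioactivity data. Tests passing on synthetic
data demonstrate that the pipeline's machinery works and can recover a
planted signal; they say nothing about predictive accuracy on real
molecules.

## Problem sizes and scaled-down optimization

The reference training configuration (100 base epochs at 1e-4) is the
default for real use. The package's own test and acceptance runs use
the same architectures at deliberately desk-scale sizes: n = 2000
synthetic molecules, 3 base epochs and 40 meta epochs at Adam 1e-3 —
a faster step compensating for the shorter schedule. The planted rule
is easy by construction, so these short schedules reach the
learning-recovery thresholds (every base AUC above 0.8; the selected
meta combination within 0.05 of the best single view) while keeping a
full five-model, 31-combination run in the minutes range on one CPU.
Noise-degradation checks train the fingerprint base model at noise
rates 0/0.25/0.5 on n = 600.

## Numerical choices and degenerate inputs

* Zero-denominator metrics → `NA`; single-class AUC → `NA` with warning.
* Descriptor normalization: constant columns → 0; held-out values
  clipped to [0, 1]; non-finite raw values → 0.
* Unparseable SMILES: skipped with counts when reading CSVs; an error
  naming the offending string for single-molecule calls.
* Oversize (>50 atoms) and overlength (>97 tokens) molecules are
  dropped with per-reason counts, keeping all five views aligned.
* Ring perception: a bond is a ring bond iff its endpoints stay
  connected after its removal; smallest-ring sizes come from the
  shortest alternative path. The ring count is the cyclomatic number.
* Hash arithmetic for fingerprints stays below 2^53 so results are
  exact in double precision and identical across platforms.
* The combination search tie-break (improved-metric count, then MCC,
  then smaller subset) reproduces the published winner on the published
  grid (see the meta-ensemble tests).

## Known limitations

* The descriptor panel is not the 995-descriptor Mordred list; values
  are not comparable descriptor-by-descriptor with runs of the original
  pipeline, and the padding slots are inert.
* The 881-key block is a documented stand-in, not bit-compatible with
  CACTVS/PubChem keys.
* Fingerprint bits differ from RDKit's Morgan bits (different hash);
  all within-package analyses are self-consistent.
* Training the reference configuration (100 epochs, five models, 31
  combinations, 10-fold consecutive CV) on the full curated dataset is
  a multi-hour single-CPU job; the package supports it but its own
  tests run the scaled-down schedule above.
* The SMILES parser covers the organic subset, bracket atoms, charges,
  ring closures (including `%nn`) and ignores stereochemistry; exotic
  inputs (polymers, reactions, isotopic bookkeeping) are out of scope.
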