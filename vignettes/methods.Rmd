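---
title: "Methods: biological-distance clustering and SMILES classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological-distance clustering and SMILES classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemclust)
```

# Overview

`chemclust` connects two views of a chemical: what it *does* (which proteins
it touches, directly and through the protein interaction network) and what it
*is* (its structure, written as a SMILES string).  The pipeline first groups
chemicals into functional clusters from interaction data alone, then trains
structure-only classifiers to place new compounds into those clusters --
useful exactly when a compound has no measured interactions yet.

# The biological distance

## Profiles

STITCH-style chemical-protein edges and STRING-style protein-protein edges
carry integer confidence scores in [0, 1000].  For each chemical $c$ the
package builds a sparse protein profile

$$ w_c(p) \;=\; \underbrace{\frac{s_{cp}}{1000}}_{\text{direct edge}}
\;+\; \lambda \sum_{q \,:\, (c,q)\ \text{direct}}
\frac{s_{cq}}{1000}\cdot\frac{s_{qp}}{1000}, $$

where the sum runs over one-step protein-protein neighbours $q$ of $p$ and
$\lambda$ (`propagation_weight`, default 0.5) sets how much shared pathway
context counts relative to shared direct targets.  Profiles are
L2-normalized, and the distance between two chemicals is one minus the
cosine of their profiles.

This distance is a documented *surrogate*: the original network-topology
distance used to build the reference clustering is published only by
citation, not by formula, so the package states its own concrete, exactly
testable definition with the same semantics (chemicals are close when they
bind the same proteins or proteins in the same neighbourhood).  It is
deliberately isolated behind `build_profiles()` /
`compute_distance_matrix()` so an alternative definition is a drop-in.

One consequence matters for reproducing the reference workflow: the
published threshold grid (0.001, 0.005, 0.01, 0.05, 0.1) is calibrated to
*that* distance's scale.  On the surrogate scale, planted synthetic fixtures
show within-cluster means near 0.2 and between-cluster means near 0.95, so
fixture-based tests cut the tree at 0.5.  The qualitative invariant that the
number of clusters is non-increasing in the threshold is asserted over the
published grid regardless of scale.

## Clustering, support, annotation

Hierarchical clustering (average linkage by default; single and complete
selectable) is cut at a fixed height; the linkage tree is retained so that
later stages can ask for the cophenetic distance between two clusters (the
height at which they first merge).  Clusters with support -- member count --
*strictly greater* than `min_support` (default 100, matching the reference
rule) survive; everything else lands in a discard list.  Each surviving
cluster is annotated with the union of its members' proteins at two score
cutoffs: a high-confidence Qcutoff (default 700) and a permissive Lcutoff
(default 400).  Lowering the cutoff can only grow the protein set; that
monotonicity is property-tested.

# Structure representations

Three encoders feed the four classifier families:

* **Morgan fingerprints** (`morgan_fingerprint()`): circular-environment
  hashing, radius 2, 1024 bits by default.  All hashing is
  order-independent, so every SMILES spelling of a molecule gives the same
  bits -- which is why augmentation is pointless for this encoder.
* **Character feature matrices** (`feature_matrix()`): one 42-entry column
  per character of the *canonical* SMILES.  The layout is 21 atom rows
  (13-way element one-hot, scaled degree, aromaticity, ring membership,
  scaled charge, scaled hydrogen count, two reserved rows) plus 21 symbol
  rows (one-hot over the non-atom character alphabet, with a single shared
  slot for ring-closure digits).  The published description delegates the
  exact layout to its source; this partition is the package's choice, kept
  behind one pair of constants so any alternative summing to 42 drops in.
* **Token sequences**: atom-wise tokenization (bracket atoms, `Cl`/`Br`,
  `%NN`, single characters; provably lossless) or learned pair encoding
  (`learn_spe()`), which greedily merges the most frequent adjacent token
  pair, ties broken lexicographically, until `max_merges` or
  `min_frequency` stops it.  Vocabularies reserve `<pad>`=0, `<unk>`=1,
  `<bos>`=2, `<eos>`=3; unseen tokens at prediction time map to `<unk>`
  rather than erroring, because scoring novel compounds is the point.

# SMILES enumeration and augmentation

A SMILES string is one depth-first traversal of the molecular graph; varying
the root atom and the order in which branches are visited yields many
equivalent spellings.  `enumerate_smiles()` generates that space exactly,
subject to one writer convention: matching ring-closure digits must sit at
the same parenthesis depth (a parenthesized branch never closes a ring
opened outside it).  That convention is what mainstream writers produce, and
with it the exhaustive count for aspirin is 144; without it the raw
traversal space is 304 strings.  The count is therefore sensitive to this
stated definition, which is why the definition is part of the contract and
cross-checked in the acceptance suite.  Above a safety cap (default 10,000
raw traversals) the function falls back to seeded random sampling without
replacement.

`classwise_augment()` uses enumeration to fight class imbalance: with
multiplier $k$, every class is grown toward $k \times$ (largest class size)
by adding variants of its members round-robin, never duplicating a string
within a class, and stopping early (with a warning) when a class's members
simply do not have enough distinct spellings.  $k = 0$ is the identity.
Augmentation is applied to training splits only; splits are made on source
compound ids, so no variant of a held-out compound can ever reach training.

# Classifiers

All four families share one contract: `train` on an encoded dataset with at
least two classes, `predict_proba` rows that are non-negative and sum to 1
in the fixed class order, deterministic refits for a fixed seed, and
serialization that round-trips to bit-identical predictions.  All are
trained with Adam on categorical cross-entropy, implemented in plain R
matrix code with hand-derived gradients (numerically verified during
development); no GPU framework is required.

* `dnn`: fully connected ReLU net over fingerprints; published widths
  4096/4096/1024 with dropout 0.4 are the documented defaults, desk-scale
  presets (64/64/32) ship for CPU testing.  Scale is configuration.
* `cnn`: three same-padded 1-D convolutions over the character axis,
  global max pooling, linear head.
* `rnn_seq2seq`: embedding into a 3-layer LSTM "perceiver", classifying
  from the last non-pad hidden state.  The optional interpreter network of
  the original design is omitted, matching the reference choice.
* `lm_finetune`: an AWD-LSTM-flavoured language model (DropConnect on
  recurrent matrices; when held-out loss stalls for `patience` epochs the
  optimizer switches to maintaining a Polyak average of the weights, an
  averaged-gradient-descent-style trigger) pretrained on next-token
  prediction, then fine-tuned with a concat-pooling head
  ([last, max, mean] over time), gradual unfreezing (one layer group per
  epoch, top down) and discriminative learning rates (factor 2.6 per
  group).  The unfreezing schedule and rate decay are not printed in the
  reference description; they follow the standard ULMFiT recipe and are
  configurable.

Determinism note: predictions are bit-stable for a fixed seed on fixed
hardware with the same BLAS; the conformance tests assert identical refit
and save/load predictions within one session.

# Study design

`make_splits()` produces a stratified 10% holdout plus 10-fold CV over the
rest (fold sizes within 1); `make_tvt()` the stratified 80/10/10 split.
Stratification is the default -- the reference text is silent, but small
clusters near the support threshold would otherwise be lost from folds.
`f1_scores()` reports macro (headline, robust to the imbalance the
augmentation corrects), micro, and per-class F1 with the 0-when-undefined
convention.  `randomization_test()` compares two models' fold scores with a
two-sided paired sign-flip test: exhaustive over all $2^n$ assignments when
$n \le 12$ (so the 10-fold all-positive case gives exactly $2/1024$),
Monte-Carlo with add-one smoothing above.  `select_cluster_subset()` mimics
the reference subset design -- half nearest-neighbour cophenetic pairs, half
max-min spread -- so the subset has both closely related and distant
clusters.  `predict_and_annotate()` produces the final report: top-k
clusters by softmax probability, Q/L protein sets for each, and the
cophenetic distance matrix between predicted clusters.

# The synthetic world

The fixture generators state one world and keep it fixed:

* proteins fall into equal communities; protein-protein edges follow a
  planted-partition model (intra 0.3, inter 0.01 by default);
* each chemical binds `chem_attach_count` proteins of its cluster's
  community with scores uniform in [700, 1000] plus a small number of
  off-community noise edges in [150, 400], mirroring the 0-1000 confidence
  convention;
* each cluster's molecules are a shared motif scaffold (benzene,
  cyclohexane, pyridine, an ester chain by default -- mutually
  distinguishable substructures) decorated with 0-3 substituents from
  {F, Cl, OC, N, CC} at hydrogen-bearing positions, keeping molecules under
  30 heavy atoms so exhaustive enumeration stays desk-scale.

What a green test establishes: the pipeline recovers planted structure that
is separable by construction, at desk scale, offline.  What it does not:
performance on real STITCH/STRING dumps (130k chemicals, GPU-scale
training), identifier conventions of real databases, 3D-derived SMILES, or
the reference study's absolute F1 numbers -- all explicitly out of scope.

# Numerical choices and limitations

* Aromaticity perception is pragmatic Hueckel: 5/6-membered rings of C, N,
  O, S with a consistent Kekule pattern and $4n+2$ pi electrons aromatize;
  macrocyclic or fused edge cases beyond the fixture chemistry are not
  claimed.  Stereochemistry (`/`, `\`, `@`) parses and is dropped.
* Canonical ranks come from Morgan-style iterative refinement with
  deterministic tie-breaking; atoms left tied are treated as symmetry
  equivalent.  Pathologically regular graphs where refinement under-splits
  are outside the supported molecule class.
* Duplicate interaction edges collapse to the maximum score; protein pairs
  are stored in lexicographic order; cluster ids are assigned by smallest
  member id so outputs are diff-stable.
* The exhaustive-enumeration safety cap (10,000 traversals), the UNK policy
  at inference, and the 1e-12 probability floor in cross-entropy are the
  only silent guards; everything else errors loudly.
* Desk-scale model presets trade accuracy for CPU time; the end-to-end
  acceptance check requires only that one architecture reaches macro-F1
  0.9 on the motif world, which the fingerprint DNN does comfortably.
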