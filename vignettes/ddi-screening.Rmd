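---
title: "Structure-based DDI type prediction and panel screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based DDI type prediction and panel screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiscreen)
```

## The problem

A drug–drug interaction (DDI) is a change in one drug's pharmacological
effect, or in adverse-event risk, caused by co-administration of another
drug. Many clinically important DDIs are metabolic: a CYP3A inhibitor slows
the clearance of a co-prescribed CYP3A substrate, raising its serum
concentration. `ddiscreen` predicts, from the two drugs' structures alone,
which of 113 catalogued DDI types an ordered pair is likely to exhibit, and
wraps that classifier in a screening workflow: evaluate query components
against a prescription-drug panel, summarize the calls, compare against
regulator reference lists, and propose same-mechanism alternatives with no
predicted interaction.

## Model

### Featurization

1. **Canonicalization.** SMILES are converted to OpenBabel canonical form,
   so any atom ordering of the same molecule maps to one representation.
   Salts and stereochemistry are kept as written; no tautomer or charge
   standardization is applied — the transformation between input and feature
   stays transparent.
2. **Circular fingerprints.** Each molecule becomes a binary vector of
   hashed atom-centred environments (ECFP-style), radius 2 and 2,048 bits by
   default — the de facto standard for structural similarity work. The
   radius-0 invariant is the element symbol alone, so radius-0 bits record
   which atom types are present; connectivity (bond orders, neighbour
   identity) enters at radius ≥ 1. Both parameters are configurable;
   fingerprints with different parameters refuse comparison.
3. **Structural similarity profile (SSP).** A drug's profile is its Tanimoto
   similarity to every drug in a fixed, ordered reference set (default: the
   training gold standard's drug universe). Two all-zero fingerprints have
   similarity 0 by convention (not NaN). The reference set carries a content
   digest; models refuse to predict when the stored reference no longer
   hashes to the digest recorded at training time.
4. **Reduction.** SSPs are mean-centred and projected onto the top-*k* PCA
   directions (*k* = 50 per drug, the dimension used throughout this model
   family; clamped automatically when the training set is too small to
   support it). Component signs follow a fixed convention — the
   largest-magnitude coordinate of each component is made positive — so
   serialized models are bit-stable across runs.

An ordered pair (A, B) is the concatenation of the two reduced profiles;
swapping the pair swaps the halves exactly.

### Classifier

The classifier is a feed-forward network with independent per-type sigmoid
outputs and per-type binary cross-entropy — a multi-label formulation,
because a single pair can carry several co-occurring DDI types, which a
softmax cannot express. Defaults, all exposed in `ddi_train_config()`:

| parameter | default | why |
|---|---|---|
| hidden layers | 2 × 64 ReLU units | capacity matched to desk-scale training sets (see below) |
| optimizer | Adam, lr 10⁻³, batch 64 | standard, stable at this scale |
| weight decay | 1.0 (decoupled) | resists memorization of label noise |
| epochs / patience | 150 / 25 | early stopping on a seeded 10% validation split |
| positive class weight | negatives/positives, capped at 100 | rare types still learn |
| call threshold | 0.5 | stored in the model so calls are reproducible |

Two design points deserve explanation:

* **Capacity and weight decay.** With a few thousand training pairs and
  noisy labels, a wide network (e.g. 2 × 256) interpolates the flipped
  labels: held-out recovery of the planted rules degrades the longer it
  trains. A 2 × 64 network with decoupled weight decay 1.0 recovers the
  planted rules near-perfectly and is insensitive to the training seed. The
  architecture remains pure configuration for users with larger corpora.
* **Order augmentation with masked labels.** Every gold pair is also
  presented in swapped order. Non-directional type labels transfer to the
  swapped copy unchanged; directional type labels do *not* — the gold
  standard records them in their stated orientation only, and treating the
  reversed orientation as negative would inject contradictory supervision.
  Those cells are therefore masked out of the loss for swapped copies.

### From scores to calls

`process_predictions()` applies the stored threshold to the score vectors of
both orientations. A directional type is called per orientation that clears
the threshold (each call renders its own sentence); a non-directional type
takes the maximum over orientations and is emitted once. Downstream, a DDI
is counted as a distinct (panel drug, query, type) triple — the only
convention under which "drugs flagged", "total DDIs" and "types per drug"
tallies stay jointly consistent; both orientations of a directional call
collapse into one triple.

### Sentence catalogue

The 113-type catalogue is data, not code: a CSV of (type_id, keyword,
template, directional). Fourteen entries carry curated keywords and
sentences (serum-concentration and metabolism types are directional;
mutual-activity types such as QTc prolongation are symmetric); the remaining
entries are marked provisional placeholders and can be replaced by a fuller
description table with the same schema. Inventing 99 authoritative sentences
would have created false ground truth, so the package does not.

## Synthetic data: what it emulates and what it does not

No licensed gold standard can ship with the package, so `synth_preset()`
generates the study conditions end-to-end:

* **Molecules** come from a small grammar (alkyl chains, optional phenyl /
  cyclohexyl / hydroxyl termini) with planted motifs — a tertiary amine or a
  carboxyl group — on a controlled fraction of molecules. Both motifs are
  detectable at fingerprint radius 2 by construction, so planted rules are
  learnable in principle; motif detection for labelling is structural (on
  the parsed connection table), not generation metadata.
* **Labels** follow planted rules: type 89 when drug A carries the amine,
  type 3 when A carries the carboxyl, type 53 when amine and carboxyl meet
  across the pair. Rules planting directional types fire in the recorded
  orientation only; rules planting symmetric types fire if either
  orientation satisfies them, matching the call conventions. Each
  (pair, rule) label is then flipped independently with probability 0.05 in
  the `default` preset; negatives are explicit rows. The clean pre-noise
  evaluation is retained (`truth_type_ids`) because recovery must be
  measured against the planted rule itself: against 5%-noisy labels even the
  Bayes-optimal classifier cannot exceed ≈ 0.89 F1, so the noisy labels are
  the training input, never the evaluation target.
* **Study sizes.** `default` uses 200 drugs and 2,000 pairs with 3 rules —
  large enough for stable recovery, small enough to train in seconds.
  `screen` adds a 160-drug/1,600-pair noise-free training set, two
  grammar-typical query molecules (one amine, one carboxyl), a 40-drug
  panel, an MoA table, and regulator-style reference lists, with every
  expected count computed by brute-force rule evaluation.

Passing these tests shows the pipeline recovers structure-determined
interaction rules from structure alone, propagates them through screening
arithmetic exactly, and is bit-reproducible. It does **not** show
performance on real pharmacology: real DDI labels are not a deterministic
function of two substructure flags, real chemistry is far more diverse than
the generator grammar, and class imbalance is harsher. The macro-F1 achieved
here is an upper bound on what identical code would achieve on real data.

## Alternative-drug proposals

`find_alternatives()` applies two criteria: a candidate must have **zero**
predicted DDIs against every query (it must not appear in the interacting
union), and must share at least one mechanism-of-action string with the
flagged drug after case/whitespace normalization. Multi-valued MoA cells
split on `|` and `;` (the Drug Repurposing Hub export dialect). Matching is
exact string equality — no ontology mapping or fuzzy matching, which
prevents silent false matches at the cost of missing synonym pairs; an
optional `within_class` filter narrows candidates to the flagged drug's
`drug_class`. Flagged drugs without annotation are reported separately.
Reference-list comparison uses the same normalization and reports the
interacting fraction over the full list to 0.1%.

## Numerical choices and degenerate inputs

* Tanimoto of two empty fingerprints is 0; PCA on a zero-variance matrix
  returns zero explained variance with a warning; `k` out of the feasible
  range `[1, min(n-1, m)]` is a configuration error.
* Environment hashing uses FNV-1a folded modulo the bit length; identical
  canonical structures always collide onto identical bits, and the test
  suite asserts order-invariance over re-written SMILES.
* Single-heavy-atom molecules (no bonds) are handled as a special case of
  the connection-table parser.
* All randomness — molecule generation, pair sampling, noise, weight
  initialization, validation split, batch order — flows from explicit
  integer seeds; two runs with the same inputs and seed produce
  byte-identical model bundles and screen tables. Model bundles are
  versioned text (JSON + CSV) and refuse to load if the stored reference
  set's digest no longer matches.

## Known limitations

* The 99 provisional catalogue sentences are placeholders, not curated
  pharmacology.
* No tautomer/charge standardization; isomeric SMILES are taken as given.
* MoA matching is string-exact; synonymous mechanism phrasings will not
  match.
* The classifier's defaults are tuned for desk-scale synthetic corpora;
  training on a real gold standard of 10⁵+ pairs would warrant a wider
  network, which is a configuration change, not a code change.
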