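# ddiscreen

Structure-based prediction and screening of drug–drug interaction (DDI)
types in R.

Co-administered drugs can change each other's pharmacology — a CYP3A
inhibitor such as ritonavir slows the metabolism of many co-prescribed
drugs, raising their serum concentrations and adverse-event risk. When a new
combination therapy reaches patients who already take other medicines,
clinicians need a fast, systematic way to flag which of those medicines may
interact and which same-mechanism substitutes would not. `ddiscreen`
provides that workflow for computational pharmacologists: it predicts, from
chemical structure alone, which of 113 catalogued DDI types an ordered drug
pair is likely to exhibit, renders each call as a human-readable sentence,
screens query drugs against a prescription-drug panel, and proposes
interaction-free alternatives that share a mechanism of action.

## Method

Each drug, given as SMILES, is canonicalized and encoded as a circular
(ECFP-style) binary fingerprint (radius 2, 2,048 bits by default). A drug's
raw feature is its **structural similarity profile (SSP)**: the vector of
Tanimoto similarities

T(A, B) = |A ∩ B| / |A ∪ B|

between its fingerprint and every fingerprint in a fixed reference set
(by default the training set's drug universe). SSPs are reduced by PCA to
*k* = 50 dimensions per drug; an ordered pair (A, B) is represented by the
concatenation `reduce(ssp(A)) ⊕ reduce(ssp(B))`. A multi-label feed-forward
network (independent per-type sigmoid outputs, weighted binary
cross-entropy, AdamW-style weight decay, seeded early stopping) maps the
pair feature to one score per DDI type; scores at or above the stored
threshold (0.5) become calls. Directional types (e.g. type 89, "the
decreased metabolism of a drug") are called separately per orientation;
symmetric types (e.g. type 53, "the increased QTc-prolonging activities")
take the maximum over both orientations and are emitted once. A DDI is
counted as a distinct (panel drug, query, type) triple.

Because no public gold standard ships with the package, a seeded synthetic
module generates molecules with planted, fingerprint-detectable motifs
(tertiary amine, carboxyl) and labels pairs by motif rules with controlled
noise — so the entire pipeline is validated against brute-force expected
answers. See `vignettes/ddi-screening.Rmd` for the full model description.

## Worked example

Train on a synthetic gold standard, screen a 40-drug panel against two query
components, and propose alternatives:

```r
library(ddiscreen)

p     <- synth_preset("screen", seed = 1)           # drugs, gold pairs, panel, MoA
model <- train_ddi_model(p$pairs, p$drugs, seed = 101)
model
#> <ddi_model> layers [100-64-64-113], 113 DDI types, threshold 0.50, seed 101
#>   reference: 160 drugs (digest 2819436d), k = 50

sr <- screen_panel(model, p$queries, p$panel)
sm <- summarize_screen(sr)
sm
#> <ddi_screen_summary> 64 DDIs over 25 interacting drugs (max 2 types per drug-query pair)
#>   Q-AMN: 25 interacting drugs
#>   Q-CBX: 14 interacting drugs

sr$records[1:2, c("type_id", "score", "sentence")]
#>  type_id     score                                                             sentence
#>        3 0.9997213 synthadrug-p0001 may increase the serum concentration of querinavir.
#>        3 0.9997050 querinavir may increase the serum concentration of synthadrug-p0001.

alt <- find_alternatives(sm, p$panel, p$moa_table)
head(alt$suggestions[, c("flagged_drug", "moa", "n_alternatives")], 2)
#>      flagged_drug                     moa n_alternatives
#>  synthadrug-p0001 calcium channel blocker              7
#>  synthadrug-p0002 calcium channel blocker              7

compare_reference_lists(sm, p$ref_lists$fda_like, p$panel)$fraction_pct
#> [1] 66.7
```

The 64 DDIs here are distinct (drug, query, type) triples; the two sentences
above are the two orientations of directional type 3 for the same pair. The
66.7% figure is the fraction of a regulator-style reference list predicted
to interact with at least one query — the same calculation used to compare a
screen against published interaction lists.

An externally produced prediction table (drug, query, type per row) can be
summarized without retraining via `as_screen_result()`.

A command-line interface wrapping these functions is installed at
`system.file("cli", "ddiscreen.R", package = "ddiscreen")` with subcommands
`synth`, `train`, `screen`, `report` and `alternatives`.

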