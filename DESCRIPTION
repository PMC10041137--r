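Package: ddiscreen
Title: Structure-Based Prediction and Screening of Drug-Drug Interaction Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interaction (DDI) types for ordered drug pairs from
    chemical structure alone. Drugs given as SMILES are canonicalized, encoded as
    circular (ECFP-style) fingerprints, and summarized as structural similarity
    profiles (Tanimoto similarity to a fixed reference set) which are reduced by
    principal component analysis and fed to a trainable multi-label feed-forward
    classifier over a 113-type DDI catalogue. Predictions are rendered as
    human-readable, direction-aware sentences. Includes a screening workflow that
    evaluates query drugs (e.g. the Paxlovid components nirmatrelvir and ritonavir)
    against a prescription-drug panel, summary analytics, comparison against
    regulator reference lists, and mechanism-of-action-based suggestion of
    interaction-free alternative drugs, plus a seeded synthetic-data generator with
    planted, fingerprint-detectable labelling rules for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
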