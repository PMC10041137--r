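# Shared fixtures, built in code. Heavier objects are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Drug table from named SMILES, bypassing file I/O.
drug_table <- function(smiles, ids = NULL, names_ = NULL) {
  ids <- ids %||% sprintf("T%03d", seq_along(smiles))
  df <- data.frame(drug_id = ids,
                   name = names_ %||% paste0("drug-", tolower(ids)),
                   smiles = unname(smiles), stringsAsFactors = FALSE)
  df$canonical_smiles <- canonicalize_smiles(df$smiles)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_drug_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A small trained model on the tiny synthetic preset, cached across tests.
tiny_model <- function() {
  if (is.null(.fixture_cache$tiny_model)) {
    p <- synth_preset("tiny", seed = 3)
    cfg <- ddi_train_config(hidden = c(32L, 32L), epochs = 40L, k = 20L)
    .fixture_cache$tiny_preset <- p
    .fixture_cache$tiny_model <- suppressWarnings(
      train_ddi_model(p$pairs, p$drugs, config = cfg, seed = 9))
  }
  .fixture_cache$tiny_model
}

tiny_preset <- function() {
  tiny_model()
  .fixture_cache$tiny_preset
}

# Minimal stand-in for process_predictions tests: only catalog + threshold
# are consulted.
model_stub <- function(threshold = 0.5) {
  list(catalog = load_catalog(), threshold = threshold)
}
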