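#' Training configuration for the DDI type classifier
#'
#' All model hyperparameters are explicit configuration: the classifier is a
#' feed-forward multi-label network (independent per-type sigmoid outputs,
#' binary cross-entropy per type), which can express the co-occurring DDI
#' types a single drug pair may carry.
#'
#' @param hidden integer vector of hidden layer widths (default two layers of
#'   64 rectified units, a capacity matched to desk-scale training sets; see
#'   the methods vignette for the rationale).
#' @param lr Adam learning rate.
#' @param weight_decay decoupled (AdamW-style) weight-decay coefficient;
#'   regularizes against memorizing label noise.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on the validation loss, in epochs.
#' @param val_fraction fraction of rows held out (seeded) for early stopping.
#' @param threshold call cutoff in (0, 1) applied to per-type scores; stored
#'   in the trained model so calls are reproducible.
#' @param k SSP reduction dimension per drug (pair features have length 2k);
#'   clamped to the PCA-feasible maximum for small inputs.
#' @param radius,n_bits fingerprint parameters.
#' @param pos_weight_cap cap on the per-type positive class weight
#'   (negatives/positives ratio).
#' @return a list of class `ddi_train_config`.
#' @export
ddi_train_config <- function(hidden = c(64L, 64L), lr = 1e-3, weight_decay = 1,
                             batch_size = 64L, epochs = 150L, patience = 25L,
                             val_fraction = 0.1, threshold = 0.5, k = 50L,
                             radius = 2L, n_bits = 2048L, pos_weight_cap = 100) {
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0,1)")
  structure(list(hidden = as.integer(hidden), lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 threshold = threshold, k = as.integer(k),
                 radius = as.integer(radius), n_bits = as.integer(n_bits),
                 pos_weight_cap = pos_weight_cap),
            class = "ddi_train_config")
}

parse_type_ids <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(integer(0))
  sort(unique(as.integer(strsplit(trimws(x), ";")[[1]])))
}

#' Read a gold-standard DDI pair table
#'
#' CSV with columns `drug_a_id`, `drug_b_id`, `type_ids` (';'-separated
#' integers; empty for explicit negative pairs).
#'
#' @param path CSV path.
#' @return data.frame of ordered pairs.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop_config("gold-standard table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  for (req in c("drug_a_id", "drug_b_id", "type_ids")) {
    if (!req %in% names(df)) stop_config("gold standard missing column '", req, "'")
  }
  df
}

# Reduced feature vector per drug id, memoized as a matrix.
reduced_matrix <- function(drugs, ref, reducer) {
  reduce_ssp(build_ssp_matrix(drugs, ref), reducer)
}

#' Assemble the feature vector for an ordered drug pair
#'
#' The pair feature is the concatenation `reduce(ssp(A)), reduce(ssp(B))` of
#' the two drugs' reduced structural similarity profiles; swapping the pair
#' swaps the two halves exactly.
#'
#' @param pair list or data.frame of two drug records (A, B).
#' @param ref a `ddi_reference`.
#' @param reducer an `ssp_reducer` fitted on SSPs against `ref`.
#' @return numeric vector of length `2 * reducer$k`.
#' @export
assemble_features <- function(pair, ref, reducer) {
  a <- pair[[1]]; b <- pair[[2]]
  if (is.data.frame(pair)) {
    a <- pair[1, , drop = FALSE]; b <- pair[2, , drop = FALSE]
  }
  c(reduce_ssp(build_ssp(a, ref), reducer),
    reduce_ssp(build_ssp(b, ref), reducer))
}

#' Train the multi-label DDI type classifier
#'
#' Builds the reference set (by default, the gold standard's drug universe),
#' fits the SSP reducer, assembles ordered pair features, and trains the
#' classifier. Each gold pair is augmented with its swapped order: the
#' swapped copy keeps labels of non-directional types and drops directional
#' ones, whose orientation is meaningful as recorded. Training is fully
#' seeded: identical inputs, config and seed give identical weights.
#'
#' @param pairs gold-standard data.frame (`drug_a_id`, `drug_b_id`,
#'   `type_ids`).
#' @param drugs drug table covering every referenced id.
#' @param catalog a `ddi_catalog` (default: bundled 113-type catalogue).
#' @param config a [ddi_train_config()].
#' @param seed integer seed controlling initialization, splits and batching.
#' @param reference optional pre-built `ddi_reference` to profile against.
#' @return an object of class `ddi_model`.
#' @export
train_ddi_model <- function(pairs, drugs, catalog = load_catalog(),
                            config = ddi_train_config(), seed = 1L,
                            reference = NULL) {
  used_ids <- unique(c(pairs$drug_a_id, pairs$drug_b_id))
  missing <- setdiff(used_ids, drugs$drug_id)
  if (length(missing) > 0) {
    stop_data("gold standard references unknown drug_id: ",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  labels <- lapply(pairs$type_ids, parse_type_ids)
  all_types <- sort(unique(unlist(labels)))
  if (length(all_types) == 0) stop_data("gold standard contains no labelled pairs")
  bad <- setdiff(all_types, catalog$entries$type_id)
  if (length(bad) > 0) stop_data("type_ids outside catalogue: ", paste(bad, collapse = ", "))
  if (length(all_types) == 1) {
    warning("gold standard contains a single DDI type (", all_types,
            "); training a degenerate one-type model")
  }

  set.seed(as.integer(seed))
  if (is.null(reference)) {
    reference <- reference_set(drugs, radius = config$radius, n_bits = config$n_bits)
  }
  ssp <- build_ssp_matrix(drugs, reference)
  k <- min(config$k, nrow(ssp) - 1L, ncol(ssp))
  if (k < config$k) {
    warning("k clamped from ", config$k, " to ", k, " (PCA-feasible maximum)")
  }
  reducer <- fit_reducer(ssp, k)
  red <- reduce_ssp(ssp, reducer)
  rownames(red) <- drugs$drug_id

  nc <- catalog_size(catalog)
  directional <- catalog$entries$directional
  n0 <- nrow(pairs)
  X <- matrix(0, 2 * n0, 2 * k)
  Y <- matrix(0, 2 * n0, nc)
  # Swapped-order copies carry order-adjusted labels: non-directional types
  # transfer as-is; directional labels are unknown for the reversed order,
  # so those cells are masked out of the loss rather than treated as negative.
  mask <- matrix(1, 2 * n0, nc)
  mask[(n0 + 1):(2 * n0), which(directional)] <- 0
  for (i in seq_len(n0)) {
    fa <- red[pairs$drug_a_id[i], ]; fb <- red[pairs$drug_b_id[i], ]
    X[i, ] <- c(fa, fb)
    X[n0 + i, ] <- c(fb, fa)
    for (t in labels[[i]]) {
      Y[i, t] <- 1
      if (!directional[t]) Y[n0 + i, t] <- 1
    }
  }

  pos <- colSums(Y); neg <- nrow(Y) - pos
  pos_weight <- ifelse(pos > 0, pmin(neg / pmax(pos, 1), config$pos_weight_cap), 1)

  fit <- mlp_train(X, Y, hidden = config$hidden, pos_weight = pos_weight,
                   lr = config$lr, batch_size = config$batch_size,
                   epochs = config$epochs, patience = config$patience,
                   val_fraction = config$val_fraction, mask = mask,
                   weight_decay = config$weight_decay %||% 0)

  structure(list(config = config, k = k, layer_sizes = fit$layer_sizes,
                 params = fit$params, threshold = config$threshold,
                 seed = as.integer(seed), reference = reference,
                 reference_digest = reference$digest, reducer = reducer,
                 catalog = catalog, catalog_size = nc,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch,
                 trained_types = all_types),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model> layers [%s], %d DDI types, threshold %.2f, seed %d\n",
              paste(x$layer_sizes, collapse = "-"), x$catalog_size,
              x$threshold, x$seed))
  cat(sprintf("  reference: %d drugs (digest %s), k = %d\n",
              length(x$reference$drug_ids), substr(x$reference_digest, 1, 8), x$k))
  invisible(x)
}

check_model_provenance <- function(model) {
  d <- reference_digest_of(model$reference$drug_ids, model$reference$smiles,
                           model$reference$radius, model$reference$n_bits)
  if (!identical(d, model$reference_digest)) {
    stop_comparability("reference digest mismatch: model expects ",
                       model$reference_digest, " but reference set hashes to ", d)
  }
  invisible(TRUE)
}

#' Predict per-type scores for one ordered drug pair
#'
#' A pure function of (model, a, b): returns one sigmoid score in \[0, 1\]
#' per catalogue type, in type-id order. Refuses to run if the model's stored
#' reference set does not hash to the digest recorded at training time.
#'
#' @param model a `ddi_model`.
#' @param a,b single-row drug data.frames (or SMILES strings).
#' @return named numeric vector, length `catalog_size`.
#' @export
predict_pair <- function(model, a, b) {
  check_model_provenance(model)
  x <- matrix(assemble_features(list(a, b), model$reference, model$reducer), nrow = 1)
  sc <- as.numeric(mlp_forward(model$params, x))
  names(sc) <- model$catalog$entries$type_id
  sc
}

# Score matrix for many ordered pairs given precomputed reduced features.
predict_scores_matrix <- function(model, feats) {
  mlp_forward(model$params, feats)
}

#' Turn raw ordered-pair scores into prediction records
#'
#' Applies the model threshold and the directionality convention: a
#' directional type is called separately for each order that clears the
#' threshold (two records with distinct sentences); a non-directional type
#' takes the maximum over both orders and is emitted once. Records are sorted
#' by descending score.
#'
#' @param scores_ab,scores_ba score vectors for orders (a,b) and (b,a) from
#'   [predict_pair()].
#' @param model a `ddi_model`.
#' @param a_id,b_id drug ids; `a` is the query in screening contexts.
#' @param a_name,b_name display names for sentence rendering.
#' @return data.frame with columns `query_id`, `partner_id`, `type_id`,
#'   `score`, `direction` (`"query_first"` / `"partner_first"`), `sentence`.
#' @export
process_predictions <- function(scores_ab, scores_ba, model,
                                a_id, b_id, a_name = a_id, b_name = b_id) {
  catalog <- model$catalog
  thr <- model$threshold
  out <- list()
  for (i in seq_len(nrow(catalog$entries))) {
    t <- catalog$entries$type_id[i]
    if (catalog$entries$directional[i]) {
      if (scores_ab[i] >= thr) {
        out[[length(out) + 1]] <- data.frame(
          query_id = a_id, partner_id = b_id, type_id = t,
          score = unname(scores_ab[i]), direction = "query_first",
          sentence = render_sentence(catalog, t, a_name, b_name),
          stringsAsFactors = FALSE)
      }
      if (scores_ba[i] >= thr) {
        out[[length(out) + 1]] <- data.frame(
          query_id = a_id, partner_id = b_id, type_id = t,
          score = unname(scores_ba[i]), direction = "partner_first",
          sentence = render_sentence(catalog, t, b_name, a_name),
          stringsAsFactors = FALSE)
      }
    } else {
      m <- max(scores_ab[i], scores_ba[i])
      if (m >= thr) {
        out[[length(out) + 1]] <- data.frame(
          query_id = a_id, partner_id = b_id, type_id = t,
          score = unname(m), direction = "query_first",
          sentence = render_sentence(catalog, t, a_name, b_name),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) == 0) empty_prediction_table() else do.call(rbind, out)
  res[order(-res$score, res$type_id), , drop = FALSE]
}

empty_prediction_table <- function() {
  data.frame(query_id = character(), partner_id = character(),
             type_id = integer(), score = numeric(), direction = character(),
             sentence = character(), stringsAsFactors = FALSE)
}

#' Save a trained model bundle
#'
#' Writes a versioned text-only directory: `model.json` (config, layer sizes,
#' threshold, seed, digests), `weights.json`, `reducer.json`,
#' `reference.json` and a copy of the catalogue CSV.
#'
#' @param model a `ddi_model`.
#' @param dir output directory (created if needed).
#' @export
save_ddi_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    format_version = 1L,
    config = unclass(model$config),
    k = model$k, layer_sizes = model$layer_sizes,
    threshold = model$threshold, seed = model$seed,
    reference_digest = model$reference_digest,
    catalog_size = model$catalog_size,
    trained_types = model$trained_types,
    val_loss = model$val_loss, best_epoch = model$best_epoch
  ), file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(W = model$params$W, b = model$params$b),
                       file.path(dir, "weights.json"), digits = NA)
  jsonlite::write_json(list(mean = model$reducer$mean,
                            components = model$reducer$components,
                            explained_variance = model$reducer$explained_variance,
                            k = model$reducer$k),
                       file.path(dir, "reducer.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(drug_ids = model$reference$drug_ids,
                            names = model$reference$names,
                            smiles = model$reference$smiles,
                            radius = model$reference$radius,
                            n_bits = model$reference$n_bits,
                            digest = model$reference$digest,
                            bits = lapply(model$reference$fingerprints, `[[`, "bits")),
                       file.path(dir, "reference.json"), auto_unbox = TRUE, digits = NA)
  write_catalog(model$catalog, file.path(dir, "catalog.csv"))
  invisible(dir)
}

#' Load a trained model bundle
#'
#' Recomputes the reference digest from the stored reference drugs and
#' refuses to load if it does not match the digest recorded at training time.
#'
#' @param dir bundle directory written by [save_ddi_model()].
#' @return a `ddi_model`.
#' @export
load_ddi_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  w <- jsonlite::fromJSON(file.path(dir, "weights.json"), simplifyMatrix = TRUE)
  red <- jsonlite::fromJSON(file.path(dir, "reducer.json"))
  rf <- jsonlite::fromJSON(file.path(dir, "reference.json"))
  catalog <- load_catalog(file.path(dir, "catalog.csv"))
  reference <- structure(list(
    drug_ids = rf$drug_ids, names = rf$names, smiles = rf$smiles,
    fingerprints = lapply(rf$bits, make_fingerprint, n_bits = rf$n_bits,
                          radius = rf$radius),
    radius = as.integer(rf$radius), n_bits = as.integer(rf$n_bits),
    digest = rf$digest), class = "ddi_reference")
  d <- reference_digest_of(reference$drug_ids, reference$smiles,
                           reference$radius, reference$n_bits)
  if (!identical(d, meta$reference_digest)) {
    stop_comparability("refusing to load model: stored reference digest ",
                       meta$reference_digest, " != recomputed ", d)
  }
  reducer <- structure(list(mean = red$mean,
                            components = matrix(unlist(red$components),
                                                nrow = red$k, byrow = FALSE),
                            explained_variance = red$explained_variance,
                            k = as.integer(red$k)), class = "ssp_reducer")
  cfg <- do.call(ddi_train_config, meta$config)
  structure(list(config = cfg, k = as.integer(meta$k),
                 layer_sizes = as.integer(meta$layer_sizes),
                 params = list(W = w$W, b = w$b),
                 threshold = meta$threshold, seed = as.integer(meta$seed),
                 reference = reference, reference_digest = meta$reference_digest,
                 reducer = reducer, catalog = catalog,
                 catalog_size = as.integer(meta$catalog_size),
                 val_loss = meta$val_loss, best_epoch = meta$best_epoch,
                 trained_types = meta$trained_types),
            class = "ddi_model")
}
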