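#' Screen query drugs against a prescription-drug panel
#'
#' Evaluates every (query, panel drug) pair in both orders with the trained
#' model and post-processes scores into prediction records. Self-pairs
#' (matching `drug_id`) are skipped; panel drugs whose structures fail to
#' parse are reported in the result, never silently dropped.
#'
#' @param model a `ddi_model`.
#' @param queries drug data.frame of query components (e.g. nirmatrelvir and
#'   ritonavir).
#' @param panel drug data.frame of panel drugs.
#' @return an object of class `ddi_screen`: `records` (prediction table),
#'   `panel_size`, `queries`, `panel_ids`, `failed` (id + reason).
#' @export
screen_panel <- function(model, queries, panel) {
  if (nrow(queries) == 0) stop_config("queries must be non-empty")
  check_model_provenance(model)
  if (nrow(panel) == 0) {
    warning("empty panel: returning empty screen result")
    return(structure(list(records = empty_prediction_table(), panel_size = 0L,
                          queries = character(), panel_ids = character(),
                          failed = data.frame(drug_id = character(),
                                              reason = character())),
                     class = "ddi_screen"))
  }

  reduce1 <- function(row) {
    tryCatch(reduce_ssp(build_ssp(row, model$reference), model$reducer),
             error = function(e) NULL)
  }
  qfeat <- lapply(seq_len(nrow(queries)), function(i) reduce1(queries[i, , drop = FALSE]))
  if (any(vapply(qfeat, is.null, TRUE))) {
    stop_structure("query drug failed structure parsing",
                   queries$drug_id[which(vapply(qfeat, is.null, TRUE))[1]])
  }
  pfeat <- lapply(seq_len(nrow(panel)), function(i) reduce1(panel[i, , drop = FALSE]))
  failed_idx <- which(vapply(pfeat, is.null, TRUE))
  failed <- data.frame(drug_id = panel$drug_id[failed_idx],
                       reason = rep("unparseable SMILES", length(failed_idx)),
                       stringsAsFactors = FALSE)

  recs <- list()
  for (qi in seq_len(nrow(queries))) {
    for (pi in setdiff(seq_len(nrow(panel)), failed_idx)) {
      if (queries$drug_id[qi] == panel$drug_id[pi]) next
      x_ab <- matrix(c(qfeat[[qi]], pfeat[[pi]]), nrow = 1)
      x_ba <- matrix(c(pfeat[[pi]], qfeat[[qi]]), nrow = 1)
      s_ab <- as.numeric(mlp_forward(model$params, x_ab))
      s_ba <- as.numeric(mlp_forward(model$params, x_ba))
      r <- process_predictions(s_ab, s_ba, model,
                               a_id = queries$drug_id[qi],
                               b_id = panel$drug_id[pi],
                               a_name = queries$name[qi],
                               b_name = panel$name[pi])
      if (nrow(r) > 0) recs[[length(recs) + 1]] <- r
    }
  }
  records <- if (length(recs) == 0) empty_prediction_table() else do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, panel_size = nrow(panel),
                 queries = queries$drug_id, panel_ids = panel$drug_id,
                 failed = failed),
            class = "ddi_screen")
}

#' @export
print.ddi_screen <- function(x, ...) {
  cat(sprintf("<ddi_screen> %d records; %d queries x %d panel drugs (%d failed parsing)\n",
              nrow(x$records), length(x$queries), x$panel_size, nrow(x$failed)))
  invisible(x)
}

#' Write / read a screen result table
#'
#' TSV with columns `query_id`, `partner_id`, `type_id`, `score`,
#' `direction`, `sentence`.
#'
#' @param result a `ddi_screen`.
#' @param path output TSV path.
#' @export
write_screen_tsv <- function(result, path) {
  utils::write.table(result$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a screen result from an external prediction table
#'
#' Ingestion adapter for externally produced prediction tables (e.g.
#' supplementary exports with one row per predicted interaction): columns are
#' mapped case-insensitively to `query_id`, `partner_id`, `type_id` and
#' optional `score`, `sentence`. This makes the summary layer usable on
#' predictions that were not produced by this package's model.
#'
#' @param records data.frame, or path to a TSV/CSV file.
#' @param queries optional character vector of query ids (default: unique
#'   `query_id` values).
#' @param panel_ids optional character vector of panel ids (default: unique
#'   `partner_id` values).
#' @return a `ddi_screen`.
#' @export
as_screen_result <- function(records, queries = NULL, panel_ids = NULL) {
  if (is.character(records) && length(records) == 1) {
    sep <- if (grepl("\\.csv$", records, ignore.case = TRUE)) "," else "\t"
    records <- utils::read.table(records, header = TRUE, sep = sep, quote = "\"",
                                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  lc <- tolower(names(records))
  for (req in c("query_id", "partner_id", "type_id")) {
    hit <- which(lc == req)
    if (length(hit) == 0) stop_config("prediction table missing column '", req, "'")
    names(records)[hit[1]] <- req
  }
  records$type_id <- as.integer(records$type_id)
  n <- nrow(records)
  if (!"score" %in% names(records)) records$score <- rep(NA_real_, n)
  if (!"direction" %in% names(records)) records$direction <- rep("query_first", n)
  if (!"sentence" %in% names(records)) records$sentence <- rep(NA_character_, n)
  queries <- queries %||% unique(records$query_id)
  panel_ids <- panel_ids %||% unique(records$partner_id)
  structure(list(records = records, panel_size = length(panel_ids),
                 queries = queries, panel_ids = panel_ids,
                 failed = data.frame(drug_id = character(), reason = character())),
            class = "ddi_screen")
}

#' Summarize a screen result
#'
#' A DDI is counted as a distinct (panel drug, query, type) triple, so a
#' directional type called in both orders for the same pair counts once.
#' Produces the per-drug distinct-type counts, per-type drug counts and
#' interacting-drug sets that screening figures are built from.
#'
#' @param result a `ddi_screen`.
#' @return an object of class `ddi_screen_summary` with elements
#'   `per_drug_type_counts` (partner_id, query_id, n_types),
#'   `per_type_drug_counts` (type_id, query_id, n_drugs),
#'   `interacting_by_query` (list of partner-id sets), `interacting_union`,
#'   `total_ddis`, `max_types_per_pair`.
#' @export
summarize_screen <- function(result) {
  r <- result$records
  if (nrow(r) == 0) {
    return(structure(list(
      per_drug_type_counts = data.frame(partner_id = character(),
                                        query_id = character(), n_types = integer()),
      per_type_drug_counts = data.frame(type_id = integer(),
                                        query_id = character(), n_drugs = integer()),
      interacting_by_query = stats::setNames(
        vector("list", length(result$queries)), result$queries),
      interacting_union = character(), total_ddis = 0L,
      max_types_per_pair = 0L), class = "ddi_screen_summary"))
  }
  triples <- unique(r[, c("partner_id", "query_id", "type_id")])
  per_drug <- stats::aggregate(type_id ~ partner_id + query_id, data = triples,
                               FUN = function(x) length(unique(x)))
  names(per_drug)[3] <- "n_types"
  per_type <- stats::aggregate(partner_id ~ type_id + query_id, data = triples,
                               FUN = function(x) length(unique(x)))
  names(per_type)[3] <- "n_drugs"
  by_query <- lapply(stats::setNames(nm = unique(c(result$queries, r$query_id))),
                     function(q) sort(unique(triples$partner_id[triples$query_id == q])))
  structure(list(per_drug_type_counts = per_drug,
                 per_type_drug_counts = per_type,
                 interacting_by_query = by_query,
                 interacting_union = sort(unique(triples$partner_id)),
                 total_ddis = nrow(triples),
                 max_types_per_pair = max(per_drug$n_types)),
            class = "ddi_screen_summary")
}

#' @export
print.ddi_screen_summary <- function(x, ...) {
  cat(sprintf("<ddi_screen_summary> %d DDIs over %d interacting drugs (max %d types per drug-query pair)\n",
              x$total_ddis, length(x$interacting_union), x$max_types_per_pair))
  for (q in names(x$interacting_by_query)) {
    cat(sprintf("  %s: %d interacting drugs\n", q, length(x$interacting_by_query[[q]])))
  }
  invisible(x)
}

#' Overlap of a reference drug list with the predicted interacting set
#'
#' Matches reference names to panel names case-insensitively after whitespace
#' normalization (no fuzzy matching) and reports how many are predicted to
#' interact with at least one query. The fraction is over the full reference
#' list, reported as a percentage to 0.1.
#'
#' @param summary a `ddi_screen_summary`.
#' @param ref_list character vector of reference drug names (e.g. a
#'   regulator's interacting-drug list).
#' @param panel panel drug data.frame (maps names to ids).
#' @return list with `n_ref`, `n_matched_to_panel`, `n_predicted_interacting`,
#'   `fraction_pct` (NA with `undefined = TRUE` when the list is empty), and
#'   `unmatched` names.
#' @export
compare_reference_lists <- function(summary, ref_list, panel) {
  n_ref <- length(ref_list)
  if (n_ref == 0) {
    return(list(n_ref = 0L, n_matched_to_panel = 0L, n_predicted_interacting = 0L,
                fraction_pct = NA_real_, undefined = TRUE, unmatched = character()))
  }
  panel_key <- norm_name(panel$name)
  ref_key <- norm_name(ref_list)
  idx <- match(ref_key, panel_key)
  matched_ids <- panel$drug_id[idx[!is.na(idx)]]
  n_int <- sum(matched_ids %in% summary$interacting_union)
  list(n_ref = n_ref,
       n_matched_to_panel = sum(!is.na(idx)),
       n_predicted_interacting = n_int,
       fraction_pct = round(100 * n_int / n_ref, 1),
       undefined = FALSE,
       unmatched = ref_list[is.na(idx)])
}

#' Write summary report tables
#'
#' Writes the per-drug and per-type count tables as TSV plus a JSON of
#' headline counts (and reference-list overlaps, if given).
#'
#' @param summary a `ddi_screen_summary`.
#' @param dir output directory.
#' @param overlaps optional named list of [compare_reference_lists()] outputs.
#' @export
write_screen_report <- function(summary, dir, overlaps = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(summary$per_drug_type_counts,
                     file.path(dir, "per_drug_type_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$per_type_drug_counts,
                     file.path(dir, "per_type_drug_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  headline <- list(
    total_ddis = summary$total_ddis,
    n_interacting_drugs = length(summary$interacting_union),
    max_types_per_pair = summary$max_types_per_pair,
    interacting_by_query = lapply(summary$interacting_by_query, length))
  if (!is.null(overlaps)) headline$reference_overlaps <- overlaps
  jsonlite::write_json(headline, file.path(dir, "headline_counts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
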