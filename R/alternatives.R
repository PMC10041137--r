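#' Read a mechanism-of-action annotation table
#'
#' CSV in the Drug Repurposing Hub export style: columns `name`, `moa` and
#' optional `target` (matched case-insensitively). Multi-valued MoA cells are
#' split on `|` and `;`.
#'
#' @param path CSV path.
#' @return data.frame with one row per (name, moa) after splitting.
#' @export
read_moa_table <- function(path) {
  if (!file.exists(path)) stop_config("MoA table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  lc <- tolower(names(df))
  for (req in c("name", "moa")) {
    hit <- which(lc == req)
    if (length(hit) == 0) stop_config("MoA table missing column '", req, "'")
    names(df)[hit[1]] <- req
  }
  split_moa_rows(df)
}

split_moa_rows <- function(df) {
  parts <- strsplit(as.character(df$moa), "[|;]")
  out <- data.frame(
    name = rep(df$name, lengths(parts)),
    moa = trimws(unlist(parts)),
    stringsAsFactors = FALSE)
  if ("target" %in% names(df)) out$target <- rep(df$target, lengths(parts))
  out <- out[nzchar(out$moa), , drop = FALSE]
  unique(out)
}

#' Suggest alternative drugs for each flagged panel drug
#'
#' Implements the two substitution criteria: an alternative (1) must have no
#' predicted DDI with any query component (it must not be in the interacting
#' union), and (2) must share at least one normalized mechanism-of-action
#' string with the flagged drug. Candidates are drawn from the panel only.
#' Flagged drugs with no MoA annotation are reported separately, not
#' silently dropped.
#'
#' @param summary a `ddi_screen_summary`.
#' @param panel panel drug data.frame.
#' @param moa_table MoA data.frame (from [read_moa_table()] or equivalent,
#'   columns `name`, `moa`).
#' @param within_class if `TRUE`, additionally require the candidate's
#'   `drug_class` to equal the flagged drug's (panel column `drug_class`).
#' @return list with `suggestions` (data.frame: `flagged_drug`, `moa`,
#'   `alternatives` ';'-joined, `n_alternatives`) and `unannotated`
#'   (character vector of flagged drug names without MoA rows).
#' @export
find_alternatives <- function(summary, panel, moa_table, within_class = FALSE) {
  flagged_ids <- intersect(summary$interacting_union, panel$drug_id)
  id2name <- stats::setNames(panel$name, panel$drug_id)
  flagged_names <- unname(id2name[flagged_ids])

  if (is.null(moa_table) || nrow(moa_table) == 0) {
    return(list(suggestions = empty_suggestion_table(),
                unannotated = sort(flagged_names)))
  }
  moa_table <- split_moa_rows(moa_table)
  moa_key <- norm_name(moa_table$name)
  moa_val <- norm_name(moa_table$moa)

  clean_ids <- setdiff(panel$drug_id, summary$interacting_union)
  clean_names <- unname(id2name[clean_ids])
  clean_key <- norm_name(clean_names)
  panel_class <- if ("drug_class" %in% names(panel)) {
    stats::setNames(norm_name(panel$drug_class), norm_name(panel$name))
  } else NULL

  sugg <- list(); unannotated <- character()
  for (i in seq_along(flagged_ids)) {
    fname <- flagged_names[i]
    moas <- unique(moa_val[moa_key == norm_name(fname)])
    if (length(moas) == 0) {
      unannotated <- c(unannotated, fname)
      next
    }
    for (m in moas) {
      cand_names <- unique(moa_table$name[moa_val == m])
      ok <- clean_names[clean_key %in% norm_name(cand_names)]
      ok <- setdiff(ok, fname)
      if (within_class && !is.null(panel_class)) {
        fc <- panel_class[[norm_name(fname)]]
        if (!is.null(fc) && !is.na(fc)) {
          ok <- ok[panel_class[norm_name(ok)] == fc & !is.na(panel_class[norm_name(ok)])]
        }
      }
      if (length(ok) > 0) {
        sugg[[length(sugg) + 1]] <- data.frame(
          flagged_drug = fname, moa = m,
          alternatives = paste(sort(ok), collapse = ";"),
          n_alternatives = length(ok), stringsAsFactors = FALSE)
      }
    }
  }
  suggestions <- if (length(sugg) == 0) empty_suggestion_table() else do.call(rbind, sugg)
  rownames(suggestions) <- NULL
  list(suggestions = suggestions, unannotated = sort(unique(unannotated)))
}

empty_suggestion_table <- function() {
  data.frame(flagged_drug = character(), moa = character(),
             alternatives = character(), n_alternatives = integer(),
             stringsAsFactors = FALSE)
}
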