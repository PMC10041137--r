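#' Canonicalize a SMILES string
#'
#' Converts a SMILES to its OpenBabel canonical form so that different atom
#' orderings of the same molecule map to one representation. Salts and
#' stereochemistry are retained as written; no standardization (tautomer,
#' charge) is applied.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where the input does not
#'   parse.
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a drug structure table
#'
#' Reads a CSV/TSV table with (at least) columns `drug_id`, `name`, `smiles`
#' (matched case-insensitively). Every row is validated: SMILES must parse and
#' canonicalize, names must be non-empty, and `drug_id` must be unique. Valid
#' rows are returned in input order with a `canonical_smiles` column added;
#' invalid rows are returned in a rejection report with a reason, never
#' silently dropped. Optional columns `drug_class`, `indication` and `moa` and
#' any extra columns are passed through.
#'
#' @param path path to the table.
#' @param format `"csv"` or `"tsv"`; defaults from the file extension.
#' @return a list with `drugs` (data.frame of accepted records) and `rejected`
#'   (data.frame with columns `row`, `drug_id`, `reason`).
#' @export
read_drug_table <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("drug table not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (nrow(df) == 0) {
    warning("empty drug table: ", path)
    return(list(drugs = empty_drug_table(), rejected = empty_rejection_table()))
  }
  validate_drug_table(df, where = path)
}

# Shared validation used by the file reader and by in-memory tables.
validate_drug_table <- function(df, where = "drug table") {
  lc <- tolower(names(df))
  for (req in c("drug_id", "name", "smiles")) {
    hit <- which(lc == req)
    if (length(hit) == 0) stop_config("missing required column '", req, "' in ", where)
    names(df)[hit[1]] <- req
  }
  df$drug_id <- as.character(df$drug_id)
  df$name <- as.character(df$name)
  df$smiles <- as.character(df$smiles)

  dup <- df$drug_id[duplicated(df$drug_id)]
  if (length(dup) > 0) {
    rows <- which(df$drug_id %in% dup)
    stop_config("duplicated drug_id (", paste(unique(dup), collapse = ", "),
                ") on rows ", paste(rows, collapse = ", "))
  }

  canon <- canonicalize_smiles(df$smiles)
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(canon)] <- "unparseable SMILES"
  reason[is.na(reason) & !nzchar(trimws(df$name))] <- "empty name"

  keep <- is.na(reason)
  drugs <- df[keep, , drop = FALSE]
  drugs$canonical_smiles <- canon[keep]
  rownames(drugs) <- NULL
  rejected <- data.frame(row = which(!keep),
                         drug_id = df$drug_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(drugs = drugs, rejected = rejected)
}

empty_drug_table <- function() {
  data.frame(drug_id = character(), name = character(), smiles = character(),
             canonical_smiles = character(), stringsAsFactors = FALSE)
}
empty_rejection_table <- function() {
  data.frame(row = integer(), drug_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Read drugs from an SDF file
#'
#' Maps each record's title line to `drug_id` (and `name`, unless a `name`
#' data field is present) and re-derives SMILES via OpenBabel.
#'
#' @param path path to an SDF file.
#' @return as [read_drug_table()].
#' @export
read_drug_sdf <- function(path) {
  if (!file.exists(path)) stop_config("SDF file not found: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  ids <- vapply(seq_along(sdf), function(i) ChemmineR::header(sdf[[i]])[["Molecule_Name"]], "")
  smi <- canonicalize_smiles(vapply(seq_along(sdf), function(i) {
    trimws(ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n"), "\n")))
  }, ""))
  df <- data.frame(drug_id = ids, name = ids, smiles = smi, stringsAsFactors = FALSE)
  validate_drug_table(df, where = path)
}

#' Write a rejection report
#'
#' @param rejected rejection data.frame from [read_drug_table()].
#' @param path output TSV path.
#' @export
write_rejection_report <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse a (canonical) SMILES into a connection table: element symbols plus a
# bond matrix (atom1, atom2, order). Hydrogens are implicit.
parse_molecule <- function(smiles, drug_id = NULL) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(c(mol = smiles))),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) stop_structure("unparseable SMILES", drug_id)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  if (length(elements) == 1 && elements[1] == "0") {
    # single-heavy-atom molecule: ChemmineR emits a degenerate block; take
    # the element straight from the canonical SMILES
    el <- regmatches(smiles, regexpr("[A-Z][a-z]?", smiles))
    if (length(el) == 0) stop_structure("unparseable SMILES", drug_id)
    return(list(elements = el, bonds = matrix(integer(0), ncol = 3)))
  }
  # bond-free molecules yield a degenerate placeholder block
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3 ||
               all(bb[, 1] == 0)) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}
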