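#' Load a DDI type catalogue
#'
#' The catalogue maps integer type ids to a short keyword, a directional
#' sentence template with slots `{A}` and `{B}`, and a directionality flag.
#' The bundled default (`system.file("extdata", "ddi_types.csv", package =
#' "ddiscreen")`) covers ids 1..113; fourteen entries carry curated keywords
#' and sentences, the remainder are marked provisional placeholders that can
#' be replaced by a fuller description table with the same schema.
#'
#' @param path CSV (or JSON array) with columns `type_id`, `keyword`,
#'   `template`, `directional`; defaults to the bundled catalogue.
#' @return an object of class `ddi_catalog`.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ddi_types.csv", package = "ddiscreen")
  }
  if (!file.exists(path)) stop_catalog("catalogue file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  for (req in c("type_id", "keyword", "template", "directional")) {
    if (!req %in% names(df)) stop_catalog("catalogue missing column '", req, "'")
  }
  df$type_id <- as.integer(df$type_id)
  df$directional <- as.logical(df$directional)
  dup <- unique(df$type_id[duplicated(df$type_id)])
  if (length(dup) > 0) {
    stop_catalog("duplicate type_id in catalogue: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(df$type_id)) || any(df$type_id < 1)) {
    stop_catalog("type_id must be a positive integer")
  }
  if (!setequal(df$type_id, seq_len(max(df$type_id)))) {
    stop_catalog("catalogue ids must cover a contiguous range 1..N")
  }
  for (i in seq_len(nrow(df))) {
    na <- count_slot(df$template[i], "A"); nb <- count_slot(df$template[i], "B")
    if (df$directional[i] && (na != 1 || nb != 1)) {
      stop_catalog("directional template for type ", df$type_id[i],
                   " must contain {A} and {B} exactly once")
    }
    if (!df$directional[i] && (na < 1 || nb < 1)) {
      stop_catalog("template for type ", df$type_id[i], " must contain {A} and {B}")
    }
  }
  df <- df[order(df$type_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(entries = df, source = path), class = "ddi_catalog")
}

count_slot <- function(template, slot) {
  lengths(regmatches(template, gregexpr(sprintf("\\{%s\\}", slot), template)))
}

#' Write a catalogue back to CSV
#'
#' Round-trips with [load_catalog()].
#'
#' @param catalog a `ddi_catalog`.
#' @param path output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog$entries, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ddi_catalog <- function(x, ...) {
  cat(sprintf("<ddi_catalog> %d DDI types (%d provisional) from %s\n",
              nrow(x$entries),
              sum(grepl("provisional", x$entries$keyword)),
              x$source))
  invisible(x)
}

catalog_size <- function(catalog) nrow(catalog$entries)

catalog_entry <- function(catalog, type_id) {
  i <- match(as.integer(type_id), catalog$entries$type_id)
  if (is.na(i)) stop_catalog("unknown DDI type_id: ", type_id)
  catalog$entries[i, , drop = FALSE]
}

is_directional <- function(catalog, type_id) catalog_entry(catalog, type_id)$directional

#' Render the human-readable sentence for a drug pair and DDI type
#'
#' Substitutes the two drug names into the type's sentence template. For
#' directional types, swapping the drugs changes the meaning (and always the
#' text); for non-directional types the sentence mentions both drugs but the
#' statement is symmetric.
#'
#' @param catalog a `ddi_catalog`.
#' @param type_id integer type id present in the catalogue.
#' @param drug_a,drug_b display names filling slots `{A}` and `{B}`.
#' @return the rendered sentence.
#' @export
render_sentence <- function(catalog, type_id, drug_a, drug_b) {
  e <- catalog_entry(catalog, type_id)
  s <- gsub("{A}", drug_a, e$template, fixed = TRUE)
  gsub("{B}", drug_b, s, fixed = TRUE)
}
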