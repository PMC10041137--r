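#' @keywords internal
"_PACKAGE"

# Content digest over a character vector, via md5 of a canonical one-line-per-
# element serialization. Used for reference-set provenance checks.
content_digest <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeLines(enc2utf8(as.character(x)), con, sep = "\n", useBytes = TRUE)
  close(con)
  unname(tools::md5sum(tf))
}

# FNV-1a 32-bit hash of a string, returned as a double in [0, 2^32).
# Implemented with 16-bit limb multiplication so every intermediate stays
# exactly representable in a double.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(errorCondition(paste0(...), class = c("ddi_config_error", "error")))
stop_structure <- function(msg, drug_id = NULL) {
  stop(errorCondition(
    if (is.null(drug_id)) msg else sprintf("%s [drug_id: %s]", msg, drug_id),
    class = c("ddi_structure_error", "error")
  ))
}
stop_comparability <- function(...) stop(errorCondition(paste0(...), class = c("ddi_comparability_error", "error")))
stop_catalog <- function(...) stop(errorCondition(paste0(...), class = c("ddi_catalog_error", "error")))
stop_data <- function(...) stop(errorCondition(paste0(...), class = c("ddi_data_error", "error")))

norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
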