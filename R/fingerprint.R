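#' Circular (ECFP-style) binary fingerprint
#'
#' Encodes a molecule as a fixed-length bit vector of hashed atom-centred
#' substructure environments. Each atom contributes one environment per radius
#' 0..`radius`: the radius-0 identifier is a hash of the atom's element
#' symbol, and each larger radius rehashes the atom's previous identifier
#' together with the (bond order, neighbour identifier) multiset, sorted so
#' the result is independent of atom numbering. Identifiers are folded into
#' `n_bits` positions. The SMILES is canonicalized first, so any atom ordering
#' of the same molecule yields identical bits.
#'
#' At radius 0 the bits therefore depend only on which atom types are present;
#' connectivity enters at radius >= 1.
#'
#' @param record a single-row drug data.frame (as returned by
#'   [read_drug_table()]) or a SMILES string.
#' @param radius non-negative integer neighbourhood radius (default 2, the
#'   ECFP4-equivalent choice).
#' @param n_bits fingerprint length, >= 64 (default 2048).
#' @return an object of class `bit_fingerprint`: list with `bits` (sorted
#'   integer positions of set bits, 1-based), `n_bits`, `radius`.
#' @export
fingerprint <- function(record, radius = 2L, n_bits = 2048L) {
  if (radius < 0) stop_config("radius must be >= 0")
  if (n_bits < 64) stop_config("n_bits must be >= 64")
  drug_id <- NULL
  if (is.data.frame(record)) {
    drug_id <- record$drug_id[1]
    smiles <- (record$canonical_smiles %||% record$smiles)[1]
  } else {
    smiles <- as.character(record)[1]
  }
  canon <- canonicalize_smiles(smiles)
  if (is.na(canon)) stop_structure("unparseable SMILES", drug_id)
  mol <- parse_molecule(canon, drug_id)
  bits <- ecfp_bits(mol, radius = as.integer(radius), n_bits = as.integer(n_bits))
  structure(list(bits = bits, n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "bit_fingerprint")
}

# Iterative Morgan-style environment hashing over a connection table.
ecfp_bits <- function(mol, radius, n_bits) {
  n <- length(mol$elements)
  if (n == 0) return(integer(0))
  nbr <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[i, 1]; b <- mol$bonds[i, 2]; o <- mol$bonds[i, 3]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  inv <- vapply(mol$elements, function(el) fnv1a(paste0("a:", el)), numeric(1),
                USE.NAMES = FALSE)
  env_ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        if (is.null(nbr[[i]])) {
          key <- sprintf("r%d:%.0f|", r, inv[i])
        } else {
          parts <- sprintf("%d:%.0f", nbr[[i]][, 2], inv[nbr[[i]][, 1]])
          key <- sprintf("r%d:%.0f|%s", r, inv[i], paste(sort(parts), collapse = ","))
        }
        fnv1a(key)
      }, numeric(1))
      env_ids <- c(env_ids, inv)
    }
  }
  sort(unique(as.integer(env_ids %% n_bits) + 1L))
}

#' @export
print.bit_fingerprint <- function(x, ...) {
  cat(sprintf("<bit_fingerprint> %d/%d bits set, radius %d\n",
              length(x$bits), x$n_bits, x$radius))
  invisible(x)
}

#' Build a fingerprint from explicit bit positions
#'
#' Mainly useful for tests and worked examples where the set bits are chosen
#' by hand.
#'
#' @param bits integer positions of set bits (1-based).
#' @param n_bits fingerprint length.
#' @param radius nominal radius tag.
#' @return a `bit_fingerprint`.
#' @export
make_fingerprint <- function(bits, n_bits, radius = 2L) {
  bits <- sort(unique(as.integer(bits)))
  stopifnot(all(bits >= 1), all(bits <= n_bits))
  structure(list(bits = bits, n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "bit_fingerprint")
}
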