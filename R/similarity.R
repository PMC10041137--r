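#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits. Defined as 0 when both
#' fingerprints are all-zero (a documented convention, avoiding NaN).
#' Fingerprints are comparable only if their `n_bits` and `radius` match.
#'
#' @param a,b `bit_fingerprint` objects.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits || a$radius != b$radius) {
    stop_comparability(sprintf(
      "fingerprints not comparable: n_bits %d/%d, radius %d/%d",
      a$n_bits, b$n_bits, a$radius, b$radius))
  }
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(a$bits) + length(b$bits) - ni
  if (nu == 0) return(0)
  ni / nu
}

#' Build a reference set for structural similarity profiles
#'
#' Fixes an ordered set of drugs and their fingerprints against which every
#' drug is profiled. The set carries a content digest (ids + canonical SMILES
#' + fingerprint parameters) used as provenance: models trained against one
#' reference refuse prediction with another.
#'
#' @param drugs drug data.frame (accepted rows of [read_drug_table()]).
#' @param radius,n_bits fingerprint parameters.
#' @return an object of class `ddi_reference`.
#' @export
reference_set <- function(drugs, radius = 2L, n_bits = 2048L) {
  if (nrow(drugs) < 2) stop_config("reference set needs >= 2 drugs")
  fps <- lapply(seq_len(nrow(drugs)), function(i)
    fingerprint(drugs[i, , drop = FALSE], radius = radius, n_bits = n_bits))
  structure(list(
    drug_ids = drugs$drug_id,
    names = drugs$name,
    smiles = drugs$canonical_smiles %||% canonicalize_smiles(drugs$smiles),
    fingerprints = fps,
    radius = as.integer(radius),
    n_bits = as.integer(n_bits),
    digest = reference_digest_of(drugs$drug_id,
                                 drugs$canonical_smiles %||% canonicalize_smiles(drugs$smiles),
                                 radius, n_bits)
  ), class = "ddi_reference")
}

reference_digest_of <- function(ids, smiles, radius, n_bits) {
  content_digest(c(sprintf("radius=%d;n_bits=%d", radius, n_bits),
                   paste(ids, smiles, sep = "\t")))
}

#' @export
print.ddi_reference <- function(x, ...) {
  cat(sprintf("<ddi_reference> %d drugs, radius %d, %d bits, digest %s\n",
              length(x$drug_ids), x$radius, x$n_bits, substr(x$digest, 1, 8)))
  invisible(x)
}

#' Structural similarity profile of one drug
#'
#' The SSP is the drug's vector of Tanimoto similarities to every reference
#' drug, in reference order. A drug that is itself reference entry j has
#' `values[j] == 1`.
#'
#' @param drug single-row drug data.frame or SMILES string.
#' @param ref a `ddi_reference`.
#' @return numeric vector of length `|ref|`, named by reference drug ids, with
#'   attribute `drug_id`.
#' @export
build_ssp <- function(drug, ref) {
  fp <- fingerprint(drug, radius = ref$radius, n_bits = ref$n_bits)
  v <- vapply(ref$fingerprints, function(rf) tanimoto(fp, rf), numeric(1))
  names(v) <- ref$drug_ids
  attr(v, "drug_id") <- if (is.data.frame(drug)) drug$drug_id[1] else NA_character_
  v
}

#' Structural similarity profile matrix for a drug table
#'
#' @param drugs drug data.frame.
#' @param ref a `ddi_reference`.
#' @return numeric matrix, one row per drug (rownames = drug ids), one column
#'   per reference drug.
#' @export
build_ssp_matrix <- function(drugs, ref) {
  m <- t(vapply(seq_len(nrow(drugs)), function(i)
    as.numeric(build_ssp(drugs[i, , drop = FALSE], ref)),
    numeric(length(ref$drug_ids))))
  dimnames(m) <- list(drugs$drug_id, ref$drug_ids)
  m
}

#' Fit a PCA reducer for SSP vectors
#'
#' Mean-centres the SSP matrix and extracts the top-`k` variance-maximizing
#' orthonormal directions. Component signs are fixed deterministically: each
#' component is flipped so its largest-magnitude coordinate is positive, which
#' makes serialized models stable across runs and platforms.
#'
#' @param ssp_matrix n x m numeric matrix (rows = drugs).
#' @param k target dimension, `1 <= k <= min(n - 1, m)`.
#' @return an object of class `ssp_reducer`: `mean` (length m), `components`
#'   (k x m orthonormal rows), `explained_variance` (length k, non-increasing),
#'   `k`.
#' @export
fit_reducer <- function(ssp_matrix, k) {
  n <- nrow(ssp_matrix); m <- ncol(ssp_matrix)
  if (n < 2) stop_config("need >= 2 rows to fit a reducer")
  kmax <- min(n - 1, m)
  if (k < 1 || k > kmax) stop_config("k must be in [1, ", kmax, "], got ", k)
  pc <- stats::prcomp(ssp_matrix, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])  # k x m
  ev <- pc$sdev[seq_len(k)]^2
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  if (all(ev < 1e-12)) warning("zero-variance input: explained variance is 0 for all components")
  structure(list(mean = as.numeric(pc$center), components = unname(comp),
                 explained_variance = as.numeric(ev), k = as.integer(k)),
            class = "ssp_reducer")
}

#' Project an SSP vector through a fitted reducer
#'
#' @param ssp numeric vector (length = reducer input dimension) or a matrix of
#'   row vectors.
#' @param reducer an `ssp_reducer`.
#' @return numeric vector of length `k` (or matrix with `k` columns).
#' @export
reduce_ssp <- function(ssp, reducer) {
  if (is.matrix(ssp)) {
    if (ncol(ssp) != length(reducer$mean)) {
      stop_comparability("SSP dimension ", ncol(ssp), " != reducer dimension ",
                         length(reducer$mean))
    }
    return(sweep(ssp, 2, reducer$mean) %*% t(reducer$components))
  }
  if (length(ssp) != length(reducer$mean)) {
    stop_comparability("SSP dimension ", length(ssp), " != reducer dimension ",
                       length(reducer$mean))
  }
  as.numeric(reducer$components %*% (as.numeric(ssp) - reducer$mean))
}
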