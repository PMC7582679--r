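## Fingerprints: a hashed circular substructure fingerprint (radius 2,
## ECFP4-style) implemented on the molecular graph, and OpenBabel's FP2
## linear-path fingerprint (paths up to length 7, 1024 bits).

#' Fingerprint configuration
#'
#' @param circular_bits Length of the circular fingerprint (default 2048).
#' @param circular_radius Neighborhood radius of the circular fingerprint
#'   (default 2, i.e. diameter 4).
#' @param path_type OpenBabel path fingerprint name (default `"FP2"`,
#'   1024 bits, linear paths up to 7 atoms).
#' @return A `fp_config` list.
#' @export
fp_config <- function(circular_bits = 2048L, circular_radius = 2L,
                      path_type = "FP2") {
  stopifnot(circular_bits >= 64, circular_radius >= 0)
  structure(list(circular_bits = as.integer(circular_bits),
                 circular_radius = as.integer(circular_radius),
                 path_type = path_type),
            class = "fp_config")
}

## Circular fingerprint of one molecule given its graph: iterated
## neighborhood hashing of per-atom invariants (atomic number, heavy degree,
## hydrogen count, formal charge, aromaticity, ring membership), folded onto
## a fixed-length bit vector.
morgan_bits <- function(graph, nbits = 2048L, radius = 2L) {
  n <- length(graph$element)
  z <- .atomic_numbers[graph$element]
  z[is.na(z)] <- 0
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(1L, z[i], graph$degree[i], graph$hcount[i], graph$charge[i],
                as.integer(graph$aromatic[i]), as.integer(graph$ring_atom[i])))
  }, numeric(1))
  features <- ids
  nbr <- lapply(seq_len(n), function(i) {
    sel <- graph$bonds$a1 == i | graph$bonds$a2 == i
    js <- ifelse(graph$bonds$a1[sel] == i, graph$bonds$a2[sel], graph$bonds$a1[sel])
    list(js = js, order = graph$bonds$order[sel])
  })
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      js <- nbr[[i]]$js
      if (length(js) == 0) return(hash_ints(c(r, ids[i])))
      o <- nbr[[i]]$order
      key <- order(o, ids[js])
      hash_ints(c(r, ids[i], as.numeric(rbind(o[key], ids[js][key]))))
    }, numeric(1))
    ids <- new_ids
    features <- c(features, ids)
  }
  bits <- logical(nbits)
  bits[unique(features %% nbits) + 1L] <- TRUE
  bits
}

#' Fingerprint a set of molecules
#'
#' Computes, for each canonical SMILES, the circular fingerprint and the
#' path (FP2) fingerprint.  Fingerprints are pure functions of the canonical
#' structure and deterministic across calls.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param config A [fp_config()].
#' @param ids Optional row names (e.g. compound ids).
#' @return A `fingerprint_set` list with logical matrices `circular`
#'   (n x circular_bits) and `path` (n x 1024), rows named by `ids`.
#' @export
fingerprint_set <- function(smiles, config = fp_config(), ids = NULL) {
  stopifnot(length(smiles) >= 1)
  ids <- ids %||% (names(smiles) %||% as.character(seq_along(smiles)))
  circ <- matrix(FALSE, nrow = length(smiles), ncol = config$circular_bits,
                 dimnames = list(ids, NULL))
  for (i in seq_along(smiles)) {
    circ[i, ] <- morgan_bits(mol_graph(smiles[i]), nbits = config$circular_bits,
                             radius = config$circular_radius)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, config$path_type))
  path <- methods::slot(fp, "fpma") > 0
  rownames(path) <- ids
  structure(list(circular = circ, path = path, config = config,
                 ids = ids),
            class = "fingerprint_set")
}

#' Fingerprint a standardized compound library
#'
#' @param library A standardized `compound_library`.
#' @param config A [fp_config()].
#' @return A `fingerprint_set` whose rows are named by `compound_id`.
#' @export
fingerprint_library <- function(library, config = fp_config()) {
  stopifnot(is.data.frame(library), "smiles_canonical" %in% names(library))
  if (anyNA(library$smiles_canonical)) {
    tf_input_error("library must be standardized before fingerprinting")
  }
  fingerprint_set(library$smiles_canonical, config = config,
                  ids = library$compound_id)
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are empty.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    tf_input_error(sprintf("fingerprint length mismatch: %d vs %d",
                           length(a), length(b)))
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto matrix between two fingerprint matrices
#'
#' @param A,B Logical matrices (rows = molecules) with equal column counts.
#' @return `nrow(A)` x `nrow(B)` matrix of Tanimoto coefficients.
#' @export
tanimoto_matrix <- function(A, B) {
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  if (is.vector(B)) B <- matrix(B, nrow = 1)
  if (ncol(A) != ncol(B)) {
    tf_input_error(sprintf("fingerprint length mismatch: %d vs %d",
                           ncol(A), ncol(B)))
  }
  Am <- matrix(as.numeric(A), nrow = nrow(A))
  Bm <- matrix(as.numeric(B), nrow = nrow(B))
  inter <- Am %*% t(Bm)
  na <- rowSums(Am)
  nb <- rowSums(Bm)
  union <- outer(na, nb, "+") - inter
  res <- ifelse(union == 0, 0, inter / union)
  dimnames(res) <- list(rownames(A), rownames(B))
  res
}
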