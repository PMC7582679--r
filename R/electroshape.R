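## Electroshape descriptors: atoms are lifted to 4D (x, y, z, scaled partial
## charge), five reference points are placed deterministically, and the
## first three distribution moments of the atom distances to each reference
## point form a 15-component, rotation/translation-invariant vector.

#' Embed a single 3D conformer with partial charges
#'
#' Generates one energy-minimized conformer with OpenBabel's deterministic
#' 3D builder and assigns iterative Gasteiger partial charges.  The builder
#' has no stochastic stage, so identical inputs give identical coordinates;
#' the `seed` argument is recorded for provenance.
#'
#' @param smiles A standardized SMILES string with at least one heavy atom.
#' @param seed Integer recorded with the conformer.
#' @return A `conformer` list with `xyz` (n x 3 matrix, all atoms including
#'   hydrogens), `charge`, `element` and `seed`; `NULL` if embedding fails
#'   (callers exclude such records from the 3D channel only).
#' @export
embed_conformer <- function(smiles, seed = 0L) {
  ## the "fast" builder level performs structure generation plus a short
  ## force-field cleanup without the stochastic rotor search, so repeated
  ## in-process calls give identical coordinates
  mol2 <- try(suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "MOL2", paste0(smiles, " m\n"),
    options = data.frame(names = c("gen3d", "partialcharge"),
                         args = c("fast", "gasteiger"), stringsAsFactors = FALSE)
  )), silent = TRUE)
  if (inherits(mol2, "try-error") || length(mol2) == 0 || !nzchar(mol2[[1]])) {
    return(NULL)
  }
  tmp <- tempfile(fileext = ".mol2")
  on.exit(unlink(tmp))
  writeLines(mol2[[1]], tmp)
  parsed <- try(suppressWarnings(bio3d::read.mol2(tmp)), silent = TRUE)
  if (inherits(parsed, "try-error") || nrow(parsed$atom) == 0) return(NULL)
  at <- parsed$atom
  structure(list(
    xyz = cbind(at$x, at$y, at$z),
    charge = at$charge,
    element = at$elena,
    seed = as.integer(seed)
  ), class = "conformer")
}

## Mean, standard deviation and cube-rooted third central moment of a
## distance distribution (population moments; the cube root preserves sign).
.moments3 <- function(d) {
  mu <- mean(d)
  v <- mean((d - mu)^2)
  m3 <- mean((d - mu)^3)
  c(mu, sqrt(v), sign(m3) * abs(m3)^(1 / 3))
}

#' Electroshape descriptor of a conformer
#'
#' Lifts atoms to 4D `(x, y, z, charge_scale * q)` and measures distance
#' distributions to five deterministic reference points: the 4D centroid,
#' the atom farthest from the centroid, the atom farthest from that atom,
#' and the centroid displaced by `+/- charge_scale` along the charge axis.
#' Three moments per reference point give 15 descriptors.  The 3D part is
#' invariant under rigid rotation and translation of the conformer.
#'
#' @param conformer A `conformer` from [embed_conformer()] (or any list with
#'   `xyz` and `charge`).
#' @param charge_scale Distance units per elementary charge (default 25).
#' @return Numeric vector of length 15 (an `electroshape` object); conformers
#'   with fewer than 3 atoms are computed but flagged with
#'   `attr(, "low_confidence")`.
#' @export
electroshape <- function(conformer, charge_scale = 25) {
  xyz <- conformer$xyz
  q <- conformer$charge %||% rep(0, nrow(xyz))
  pts <- cbind(xyz, charge_scale * q)
  n <- nrow(pts)
  centroid <- colMeans(pts)
  d_cent <- sqrt(colSums((t(pts) - centroid)^2))
  a1 <- which.max(d_cent)
  d_a1 <- sqrt(colSums((t(pts) - pts[a1, ])^2))
  a2 <- which.max(d_a1)
  c4 <- centroid + c(0, 0, 0, charge_scale)
  c5 <- centroid - c(0, 0, 0, charge_scale)
  refs <- rbind(centroid, pts[a1, ], pts[a2, ], c4, c5)
  v <- as.numeric(apply(refs, 1, function(r) {
    .moments3(sqrt(colSums((t(pts) - r)^2)))
  }))
  v <- structure(v, class = "electroshape")
  if (n < 3) attr(v, "low_confidence") <- TRUE
  v
}

#' 3D similarity of two electroshape vectors
#'
#' `1 / (1 + mean absolute difference)`: a bounded, strictly monotone
#' transform of the Manhattan distance between the two 15-component vectors.
#'
#' @param a,b Electroshape vectors.
#' @return Similarity in `(0, 1]`.
#' @export
similarity_3d <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  stopifnot(length(a) == 15, length(b) == 15)
  1 / (1 + mean(abs(a - b)))
}
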