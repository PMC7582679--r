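## Perception and enumeration of unspecified tetrahedral stereocenters.
##
## Strategy: candidate centers are located on the molecular graph (aliphatic
## carbons with four distinct substituents counting one implicit hydrogen at
## most), then each candidate is confirmed by asking the canonical SMILES
## writer itself: a chirality mark injected at a non-stereogenic atom is
## discarded during canonicalization, so the "@" and "@@" variants collapse
## to the same string if and only if the atom is not a genuine stereocenter.
## This delegates stereo perception to the same engine that writes the
## output, so enumerated isomers are guaranteed distinct and stable.

## Rewrite one atom token with a tetrahedral mark.
inject_stereo_token <- function(tok, hcount, mark) {
  if (startsWith(tok, "[")) {
    sub("^\\[([A-Z][a-z]?)", sprintf("[\\1%s", mark), tok)
  } else if (hcount == 1L) {
    sprintf("[%s%sH]", tok, mark)
  } else {
    sprintf("[%s%s]", tok, mark)
  }
}

## Rebuild a SMILES string with marks injected at the given token rows.
inject_stereo <- function(graph, token_rows, marks) {
  toks <- graph$tokens$text
  for (i in seq_along(token_rows)) {
    row <- token_rows[i]
    atom_idx <- match(row, graph$atom_token_rows)
    toks[row] <- inject_stereo_token(toks[row], graph$hcount[atom_idx], marks[i])
  }
  paste(toks, collapse = "")
}

## Locate unspecified tetrahedral centers in a (canonical) SMILES string.
## Returns a list with the molecular graph and the token rows of confirmed
## centers, so callers can re-use the graph for enumeration.
find_unspecified_centers <- function(smiles) {
  graph <- mol_graph(smiles)
  n_atoms <- length(graph$element)
  centers <- integer(0)
  for (a in seq_len(n_atoms)) {
    if (graph$element[a] != "C" || graph$aromatic[a] || graph$stereo_marked[a]) next
    if (!((graph$degree[a] == 4L && graph$hcount[a] == 0L) ||
          (graph$degree[a] == 3L && graph$hcount[a] == 1L))) next
    inc <- graph$bonds$order[graph$bonds$a1 == a | graph$bonds$a2 == a]
    if (any(inc != 1L)) next
    row <- graph$atom_token_rows[a]
    s1 <- ob_canonical(inject_stereo(graph, row, "@"))
    s2 <- ob_canonical(inject_stereo(graph, row, "@@"))
    if (!is.na(s1) && !is.na(s2) && s1 != s2) centers <- c(centers, row)
  }
  list(graph = graph, center_token_rows = centers)
}

#' Count unspecified tetrahedral stereocenters
#'
#' Counts the tetrahedral carbon centers of a molecule that are stereogenic
#' but carry no chirality mark in the given SMILES.  Perception is delegated
#' to the canonical SMILES writer (a mark injected at a non-stereogenic atom
#' does not survive canonicalization).
#'
#' @param smiles Character vector of (preferably canonical) SMILES strings.
#' @return Integer vector of unspecified-center counts.
#' @export
count_unspecified_centers <- function(smiles) {
  vapply(smiles, function(s) length(find_unspecified_centers(s)$center_token_rows),
         integer(1), USE.NAMES = FALSE)
}

#' Enumerate stereoisomers over unspecified tetrahedral centers
#'
#' Expands every library record with `k` unspecified tetrahedral centers into
#' the distinct fully specified stereoisomers obtained from all `2^k`
#' chirality assignments (symmetric assignments, e.g. in meso forms, collapse
#' during canonicalization).  Records with more than `max_centers` unspecified
#' centers are passed through unexpanded and flagged, never silently
#' exploded.  Records with no unspecified centers are returned unchanged.
#'
#' @param library A `compound_library` data frame from [standardize_library()].
#' @param max_centers Cap on enumerable centers per record (default 6, i.e.
#'   at most 64 isomers).
#' @return A `compound_library` data frame in which `parent_id` points at the
#'   pre-expansion record and `n_unspecified_centers` is 0 for every expanded
#'   record; an additional logical column `stereo_overflow` marks records
#'   passed through because they exceeded `max_centers`.
#' @export
enumerate_stereoisomers <- function(library, max_centers = 6L) {
  stopifnot(is.data.frame(library), "smiles_canonical" %in% names(library))
  out <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    rec <- library[i, , drop = FALSE]
    rec$stereo_overflow <- FALSE
    k <- rec$n_unspecified_centers
    if (is.na(k) || k == 0L) {
      out[[i]] <- rec
      next
    }
    fc <- find_unspecified_centers(rec$smiles_canonical)
    rows <- fc$center_token_rows
    k <- length(rows)
    if (k == 0L) {
      rec$n_unspecified_centers <- 0L
      out[[i]] <- rec
      next
    }
    if (k > max_centers) {
      message(sprintf(
        "compound '%s' has %d unspecified centers (> max_centers = %d); passed through unexpanded",
        rec$compound_id, k, max_centers))
      rec$stereo_overflow <- TRUE
      out[[i]] <- rec
      next
    }
    combos <- expand.grid(rep(list(c("@", "@@")), k), stringsAsFactors = FALSE)
    iso <- vapply(seq_len(nrow(combos)), function(j) {
      ob_canonical(inject_stereo(fc$graph, rows, as.character(combos[j, ])))
    }, character(1))
    iso <- unique(iso[!is.na(iso)])
    if (length(iso) == 0) {
      rec$stereo_overflow <- TRUE
      out[[i]] <- rec
      next
    }
    kids <- rec[rep(1L, length(iso)), , drop = FALSE]
    kids$compound_id <- if (length(iso) == 1) rec$compound_id else
      paste0(rec$compound_id, "_s", seq_along(iso))
    kids$parent_id <- rec$compound_id
    kids$smiles_canonical <- iso
    kids$n_unspecified_centers <- 0L
    out[[i]] <- kids
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- unique(c("compound_library", class(res)))
  attr(res, "rejects") <- attr(library, "rejects")
  res
}
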