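## Loading, standardizing and writing compound libraries (the "chemical
## space").  A library is a plain data frame with one row per compound and a
## "rejects" attribute collecting unparseable inputs.

new_compound_library <- function(df, rejects = NULL) {
  rejects <- rejects %||% data.frame(row = integer(0), reason = character(0),
                                     stringsAsFactors = FALSE)
  class(df) <- unique(c("compound_library", class(df)))
  attr(df, "rejects") <- rejects
  df
}

#' Rejected input entries of a library
#'
#' @param library A `compound_library`.
#' @return Data frame with columns `row` and `reason`.
#' @export
library_rejects <- function(library) {
  attr(library, "rejects") %||%
    data.frame(row = integer(0), reason = character(0), stringsAsFactors = FALSE)
}

#' Load a compound library
#'
#' Reads a compound library from a SMILES CSV (columns `compound_id,smiles`
#' and optionally `name`, `source`) or an SDF (V2000) file.  Entries whose
#' structure cannot be parsed are collected into a rejects report (see
#' [library_rejects()]), never silently dropped.
#'
#' @param path Input file.
#' @param format `"smiles-csv"` or `"sdf"`.
#' @return A `compound_library` data frame with columns `compound_id`,
#'   `name`, `smiles_input`, `smiles_canonical` (filled by
#'   [standardize_library()]), `parent_id`, `n_unspecified_centers`, `source`.
#' @export
load_library <- function(path, format = c("smiles-csv", "sdf")) {
  format <- match.arg(format)
  stopifnot_file(path)
  if (format == "smiles-csv") {
    raw <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
    need <- c("compound_id", "smiles")
    if (!all(need %in% names(raw))) {
      tf_input_error(sprintf("library CSV '%s' must have columns %s",
                             path, paste(need, collapse = ", ")))
    }
    ids <- as.character(raw$compound_id)
    nm <- if ("name" %in% names(raw)) as.character(raw$name) else ids
    src <- if ("source" %in% names(raw)) as.character(raw$source) else "unknown"
    smi <- as.character(raw$smiles)
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdf)
    smi_all <- rep(NA_character_, length(sdf))
    if (any(valid)) {
      conv <- suppressWarnings(ChemmineR::sdf2smiles(sdf[which(valid)]))
      smi_all[which(valid)] <- unlist(methods::slot(conv, "smilist"), use.names = FALSE)
    }
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | !nzchar(ids)] <- paste0("mol_", which(is.na(ids) | !nzchar(ids)))
    nm <- ids
    src <- "unknown"
    smi <- smi_all
  }

  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    tf_input_error(sprintf("duplicate compound_id values in '%s': %s",
                           path, paste(dup, collapse = ", ")))
  }

  canon_probe <- ob_canonical(smi)
  bad <- which(is.na(canon_probe))
  rejects <- data.frame(row = bad,
                        reason = sprintf("unparseable structure for compound_id '%s'", ids[bad]),
                        stringsAsFactors = FALSE)
  keep <- setdiff(seq_along(ids), bad)
  if (length(keep) == 0) {
    tf_input_error(sprintf("no parseable records in '%s'", path))
  }
  df <- data.frame(
    compound_id = ids[keep],
    name = nm[keep],
    smiles_input = smi[keep],
    smiles_canonical = NA_character_,
    parent_id = ids[keep],
    n_unspecified_centers = NA_integer_,
    source = (if (length(src) == 1) rep(src, length(keep)) else src[keep]),
    stringsAsFactors = FALSE
  )
  ok_src <- c("natural", "semisynthetic", "synthetic", "unknown")
  df$source[!(df$source %in% ok_src)] <- "unknown"
  new_compound_library(df, rejects)
}

## Standardize one structure: keep the largest covalently bonded fragment,
## neutralize charges where chemically possible, canonicalize, and count
## unspecified tetrahedral centers.
standardize_smiles <- function(smiles, count_centers = TRUE) {
  canon <- ob_canonical(smiles)
  if (is.na(canon)) {
    return(list(ok = FALSE, reason = "unparseable structure"))
  }
  frags <- strsplit(canon, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1) {
    heavy <- vapply(frags, count_heavy_atoms, numeric(1))
    best <- which(heavy == max(heavy))
    if (length(best) > 1) {
      mw <- vapply(frags[best], ob_molweight, numeric(1))
      best <- best[order(-mw, frags[best])][1]
    }
    canon <- frags[best]
  }
  canon <- ob_canonical(canon, options = data.frame(names = "neutralize", args = "",
                                                    stringsAsFactors = FALSE))
  if (is.na(canon) || count_heavy_atoms(canon) == 0) {
    return(list(ok = FALSE, reason = "no atoms left after salt stripping"))
  }
  n_centers <- if (count_centers) count_unspecified_centers(canon) else NA_integer_
  list(ok = TRUE, smiles_canonical = canon, n_unspecified_centers = n_centers)
}

#' Standardize a compound library
#'
#' Computes canonical SMILES for every record after salt stripping (largest
#' fragment by heavy-atom count; ties broken by molecular weight, then
#' lexicographically) and charge neutralization, and counts unspecified
#' tetrahedral stereocenters.  Records that fail standardization move to the
#' rejects report.
#'
#' @param library A `compound_library` from [load_library()], or any data
#'   frame with `compound_id` and `smiles_input` columns.
#' @param count_centers Count unspecified stereocenters (default `TRUE`; the
#'   count requires extra canonicalization passes).
#' @return The standardized `compound_library`.
#' @export
standardize_library <- function(library, count_centers = TRUE) {
  stopifnot(is.data.frame(library), all(c("compound_id", "smiles_input") %in% names(library)))
  rejects <- library_rejects(library)
  keep <- logical(nrow(library))
  for (i in seq_len(nrow(library))) {
    std <- standardize_smiles(library$smiles_input[i], count_centers = count_centers)
    if (!std$ok) {
      rejects <- rbind(rejects, data.frame(
        row = i, reason = sprintf("%s for compound_id '%s'", std$reason,
                                  library$compound_id[i]),
        stringsAsFactors = FALSE))
      next
    }
    library$smiles_canonical[i] <- std$smiles_canonical
    library$n_unspecified_centers[i] <- std$n_unspecified_centers
    keep[i] <- TRUE
  }
  if (!any(keep)) tf_input_error("no records survived standardization")
  new_compound_library(library[keep, , drop = FALSE], rejects)
}

#' Write a compound library
#'
#' Writes the shared CSV dialect (`compound_id,smiles,name,source`) or an SDF
#' file.  The `smiles` column holds the canonical SMILES when present,
#' otherwise the input SMILES.
#'
#' @param library A `compound_library`.
#' @param path Output file.
#' @param format `"smiles-csv"` or `"sdf"`.
#' @export
write_library <- function(library, path, format = c("smiles-csv", "sdf")) {
  format <- match.arg(format)
  smi <- ifelse(is.na(library$smiles_canonical), library$smiles_input,
                library$smiles_canonical)
  if (format == "smiles-csv") {
    df <- data.frame(compound_id = library$compound_id, smiles = smi,
                     name = library$name, source = library$source,
                     stringsAsFactors = FALSE)
    write_csv_atomic(df, path)
  } else {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, library$compound_id)))
    write_atomic(function(tmp) suppressWarnings(ChemmineR::write.SDF(sdf, tmp, cid = TRUE)), path)
  }
  invisible(path)
}

#' Write the rejects report of a library
#'
#' @param library A `compound_library`.
#' @param path Output CSV (`row,reason`).
#' @export
write_rejects <- function(library, path) {
  write_csv_atomic(library_rejects(library), path)
  invisible(path)
}
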