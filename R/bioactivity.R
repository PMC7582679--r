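## The "known biological space": compounds are resolved to database
## identifiers, active single-protein assay records are collected, genes are
## annotated with protein entries and pathways, and interactions are
## aggregated with integer weights (one unit per supporting assay record).
##
## Backends implement four lookups behind a generic interface: a local
## fixture backend reading four CSV tables (used by all tests), and a thin
## REST client for the live public services (integration use only; never
## exercised by the test suite).

#' Mining backend lookups
#'
#' Generic interface implemented by [fixture_backend()] and
#' [pubchem_backend()]: resolve a canonical SMILES to a compound identifier,
#' list active assays (with gene annotations) for a compound, translate a
#' gene name to a protein entry, and list pathways of a protein entry.
#' Lookups are memoized per backend session, so repeated identical queries
#' return identical answers.
#'
#' @param backend A backend object.
#' @param smiles,compound_id,gene,protein_entry Query values.
#' @return `resolve_compound`: a compound id or `NA`;
#'   `fetch_active_interactions`: data frame `assay_id,gene_name` (only
#'   active assays mapped to exactly one protein); `gene_to_protein`: a
#'   protein entry name or `NA`; `protein_pathways`: character vector of
#'   pathway names (possibly empty).
#' @name mining_backend
NULL

#' @rdname mining_backend
#' @export
resolve_compound <- function(backend, smiles) UseMethod("resolve_compound")

#' @rdname mining_backend
#' @export
fetch_active_interactions <- function(backend, compound_id) UseMethod("fetch_active_interactions")

#' @rdname mining_backend
#' @export
gene_to_protein <- function(backend, gene) UseMethod("gene_to_protein")

#' @rdname mining_backend
#' @export
protein_pathways <- function(backend, protein_entry) UseMethod("protein_pathways")

#' Local fixture mining backend
#'
#' Reads the four fixture tables emulating the public record chain:
#' `compounds.csv` (`smiles_canonical,cid`), `assays.csv`
#' (`cid,aid,activity_flag,gene_names` with semicolon-separated gene lists),
#' `proteins.csv` (`gene,protein_entry`) and `pathways.csv`
#' (`protein_entry,pathway`).
#'
#' @param dir Directory containing the four CSVs.
#' @return A `fixture_backend`.
#' @export
fixture_backend <- function(dir) {
  paths <- file.path(dir, c("compounds.csv", "assays.csv", "proteins.csv", "pathways.csv"))
  for (p in paths) stopifnot_file(p)
  structure(list(
    compounds = read.csv(paths[1], stringsAsFactors = FALSE),
    assays = read.csv(paths[2], stringsAsFactors = FALSE),
    proteins = read.csv(paths[3], stringsAsFactors = FALSE),
    pathways = read.csv(paths[4], stringsAsFactors = FALSE)
  ), class = c("fixture_backend", "mining_backend"))
}

#' @export
resolve_compound.fixture_backend <- function(backend, smiles) {
  hit <- backend$compounds$cid[backend$compounds$smiles_canonical == smiles]
  if (length(hit) == 0) NA_character_ else as.character(hit[1])
}

#' @export
fetch_active_interactions.fixture_backend <- function(backend, compound_id) {
  a <- backend$assays[as.character(backend$assays$cid) == as.character(compound_id), , drop = FALSE]
  a <- a[tolower(a$activity_flag) == "active", , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(assay_id = character(0), gene_name = character(0),
                      stringsAsFactors = FALSE))
  }
  genes <- strsplit(as.character(a$gene_names), ";", fixed = TRUE)
  single <- vapply(genes, function(g) length(g[nzchar(trimws(g))]) == 1L, logical(1))
  a <- a[single, , drop = FALSE]
  data.frame(assay_id = as.character(a$aid),
             gene_name = toupper(trimws(unlist(genes[single]))),
             stringsAsFactors = FALSE)
}

#' @export
gene_to_protein.fixture_backend <- function(backend, gene) {
  hit <- backend$proteins$protein_entry[toupper(backend$proteins$gene) == toupper(gene)]
  if (length(hit) == 0) NA_character_ else as.character(hit[1])
}

#' @export
protein_pathways.fixture_backend <- function(backend, protein_entry) {
  if (is.na(protein_entry)) return(character(0))
  as.character(backend$pathways$pathway[backend$pathways$protein_entry == protein_entry])
}

#' Live REST mining backend
#'
#' Thin client for the public compound/bioactivity, protein and pathway
#' REST services, with a fixed request-rate limit and retry-with-backoff
#' policy.  Intended for interactive integration runs on a networked
#' machine; the test suite exclusively uses [fixture_backend()].
#'
#' @param rate_limit Maximum requests per second (default 5).
#' @param retries Retry attempts with exponential backoff (default 3).
#' @return A `pubchem_backend`.
#' @export
pubchem_backend <- function(rate_limit = 5, retries = 3) {
  structure(list(
    rate_limit = rate_limit, retries = retries,
    min_interval = 1 / rate_limit,
    cache = new.env(parent = emptyenv()),
    last_request = new.env(parent = emptyenv())
  ), class = c("pubchem_backend", "mining_backend"))
}

.rest_get <- function(backend, url) {
  key <- paste0("u:", url)
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  last <- backend$last_request$t %||% 0
  wait <- backend$min_interval - (as.numeric(Sys.time()) - last)
  if (wait > 0) Sys.sleep(wait)
  res <- NULL
  for (attempt in seq_len(backend$retries)) {
    backend$last_request$t <- as.numeric(Sys.time())
    res <- try(jsonlite::fromJSON(url), silent = TRUE)
    if (!inherits(res, "try-error")) break
    Sys.sleep(2^(attempt - 1))
  }
  if (inherits(res, "try-error")) res <- NULL
  backend$cache[[key]] <- res
  res
}

#' @export
resolve_compound.pubchem_backend <- function(backend, smiles) {
  res <- .rest_get(backend, paste0(
    "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/smiles/",
    utils::URLencode(smiles, reserved = TRUE), "/cids/JSON"))
  cid <- res$IdentifierList$CID[1]
  if (is.null(cid) || is.na(cid)) NA_character_ else as.character(cid)
}

#' @export
fetch_active_interactions.pubchem_backend <- function(backend, compound_id) {
  res <- .rest_get(backend, paste0(
    "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/cid/", compound_id,
    "/assaysummary/JSON"))
  empty <- data.frame(assay_id = character(0), gene_name = character(0),
                      stringsAsFactors = FALSE)
  tab <- res$Table
  if (is.null(tab)) return(empty)
  cols <- tab$Columns$Column
  rows <- tab$Row$Cell
  if (is.null(cols) || is.null(rows)) return(empty)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  df <- df[df[["Activity Outcome"]] %in% "Active", , drop = FALSE]
  genes <- strsplit(df[["Target GeneID"]] %||% df[["Target GeneSymbol"]] %||% "", ";")
  single <- vapply(genes, function(g) length(g[nzchar(g)]) == 1L, logical(1))
  df <- df[single, , drop = FALSE]
  data.frame(assay_id = as.character(df$AID),
             gene_name = toupper(unlist(genes[single])),
             stringsAsFactors = FALSE)
}

#' @export
gene_to_protein.pubchem_backend <- function(backend, gene) {
  res <- .rest_get(backend, paste0(
    "https://rest.uniprot.org/uniprotkb/search?query=gene_exact:", gene,
    "+AND+organism_id:9606&fields=id&format=json&size=1"))
  entry <- res$results$uniProtkbId[1]
  if (is.null(entry) || is.na(entry)) NA_character_ else as.character(entry)
}

#' @export
protein_pathways.pubchem_backend <- function(backend, protein_entry) {
  res <- .rest_get(backend, paste0(
    "https://reactome.org/ContentService/data/mapping/UniProt/", protein_entry,
    "/pathways?species=9606"))
  if (is.null(res) || length(res) == 0) return(character(0))
  as.character(res$displayName)
}

#' Build the known biological space
#'
#' Resolves every library compound, collects its active single-protein assay
#' records, and aggregates them into weighted compound-target interactions
#' (`weight` = number of distinct supporting assay ids).  Interactions of a
#' stereo-expanded record are also attributed to its parent compound, since
#' known activity is subtracted at the compound level.  Compounds that do not
#' resolve never abort the run; they are listed in `resolution_failures`.
#'
#' @param library A standardized `compound_library`.
#' @param backend A mining backend.
#' @param roll_up_parents Attribute interactions of stereoisomers to their
#'   parent record as well (default `TRUE`).
#' @return A `known_space` with `records` (data frame `compound_id`,
#'   `target_id`, `weight`, `assay_ids`, `protein_entry`, `pathways`) and
#'   `resolution_failures`.
#' @export
build_known_space <- function(library, backend, roll_up_parents = TRUE) {
  stopifnot(is.data.frame(library), "smiles_canonical" %in% names(library))
  failures <- character(0)
  triples <- list()
  for (i in seq_len(nrow(library))) {
    cid <- resolve_compound(backend, library$smiles_canonical[i])
    if (is.na(cid)) {
      failures <- c(failures, library$compound_id[i])
      next
    }
    hits <- fetch_active_interactions(backend, cid)
    if (nrow(hits) == 0) next
    owners <- unique(c(library$compound_id[i],
                       if (roll_up_parents) library$parent_id[i] else NULL))
    for (owner in owners) {
      triples[[length(triples) + 1L]] <- data.frame(
        compound_id = owner, target_id = hits$gene_name, assay_id = hits$assay_id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(triples) == 0) {
    if (length(failures) == nrow(library)) {
      tf_input_error("no compound of the library could be resolved by the backend")
    }
    records <- data.frame(compound_id = character(0), target_id = character(0),
                          weight = integer(0), assay_ids = character(0),
                          protein_entry = character(0), pathways = character(0),
                          stringsAsFactors = FALSE)
  } else {
    flat <- unique(do.call(rbind, triples))
    key <- paste(flat$compound_id, flat$target_id, sep = "\r")
    records <- do.call(rbind, lapply(split(flat, key), function(g) {
      aids <- sort(unique(g$assay_id))
      data.frame(compound_id = g$compound_id[1], target_id = g$target_id[1],
                 weight = length(aids), assay_ids = paste(aids, collapse = ";"),
                 protein_entry = NA_character_, pathways = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    records <- records[order(records$compound_id, records$target_id), , drop = FALSE]
    rownames(records) <- NULL
  }
  space <- structure(list(records = records, resolution_failures = failures),
                     class = "known_space")
  annotate_known_space(space, backend)
}

#' Annotate a known space with protein entries and pathways
#'
#' Missing mappings leave fields absent (reported with a message) and never
#' drop an interaction.
#'
#' @param space A `known_space`.
#' @param backend A mining backend.
#' @return The annotated `known_space`.
#' @export
annotate_known_space <- function(space, backend) {
  rec <- space$records
  if (nrow(rec) == 0) return(space)
  genes <- unique(rec$target_id)
  entries <- setNames(vapply(genes, function(g) gene_to_protein(backend, g),
                             character(1)), genes)
  missing <- genes[is.na(entries)]
  if (length(missing)) {
    message(sprintf("no protein entry for gene(s): %s", paste(missing, collapse = ", ")))
  }
  rec$protein_entry <- unname(entries[rec$target_id])
  rec$pathways <- vapply(rec$protein_entry, function(pe) {
    pw <- if (is.na(pe)) character(0) else protein_pathways(backend, pe)
    if (length(pw) == 0) NA_character_ else paste(pw, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  space$records <- rec
  space
}

#' Pathway annotation table of a known space
#'
#' @param space An annotated `known_space`.
#' @return Data frame `target_id,pathway`, one row per (target, pathway).
#' @export
known_space_pathways <- function(space) {
  rec <- space$records
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    if (is.na(rec$pathways[i])) return(NULL)
    data.frame(target_id = rec$target_id[i],
               pathway = strsplit(rec$pathways[i], ";", fixed = TRUE)[[1]],
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows)) %||%
    data.frame(target_id = character(0), pathway = character(0))
  if (is.null(out)) {
    out <- data.frame(target_id = character(0), pathway = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Export a known space as a SIF network
#'
#' Writes one line per interaction (`compound_id<TAB>binds<TAB>target_id`),
#' a companion edge-attribute CSV (`compound_id,target_id,weight`) and a
#' known-space CSV of the same columns.
#'
#' @param space A `known_space`.
#' @param path Output SIF file; the edge-attribute file is written next to
#'   it with suffix `_edges.csv`.
#' @return Invisibly, the SIF path.
#' @export
export_sif <- function(space, path) {
  rec <- space$records
  write_atomic(function(tmp) {
    lines <- if (nrow(rec) == 0) character(0) else
      paste(rec$compound_id, "binds", rec$target_id, sep = "\t")
    writeLines(lines, tmp)
  }, path)
  edge_path <- sub("\\.sif$", "", path)
  edge_path <- paste0(edge_path, "_edges.csv")
  write_csv_atomic(rec[, c("compound_id", "target_id", "weight"), drop = FALSE], edge_path)
  invisible(path)
}

#' Re-import a SIF export
#'
#' Inverse of [export_sif()]: reads the SIF and its edge-attribute file back
#' into a bare `known_space` (weights from the edge file; no annotations).
#'
#' @param path The SIF file written by [export_sif()].
#' @return A `known_space`.
#' @export
read_sif <- function(path) {
  stopifnot_file(path)
  edge_path <- paste0(sub("\\.sif$", "", path), "_edges.csv")
  stopifnot_file(edge_path)
  edges <- read.csv(edge_path, stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sif <- if (length(lines) == 0) {
    data.frame(compound_id = character(0), target_id = character(0))
  } else {
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(compound_id = parts[, 1], target_id = parts[, 3],
               stringsAsFactors = FALSE)
  }
  if (nrow(sif) != nrow(edges)) {
    tf_input_error(sprintf("SIF '%s' and edge table disagree on interaction count", path))
  }
  rec <- edges
  rec$assay_ids <- rep(NA_character_, nrow(rec))
  rec$protein_entry <- rep(NA_character_, nrow(rec))
  rec$pathways <- rep(NA_character_, nrow(rec))
  rec <- rec[order(rec$compound_id, rec$target_id),
             c("compound_id", "target_id", "weight", "assay_ids", "protein_entry", "pathways")]
  rownames(rec) <- NULL
  structure(list(records = rec, resolution_failures = character(0)),
            class = "known_space")
}

#' Write the known-space interaction table
#'
#' @param space A `known_space`.
#' @param path Output CSV (`compound_id,target_id,weight`).
#' @export
write_known_space <- function(space, path) {
  write_csv_atomic(space$records[, c("compound_id", "target_id", "weight"), drop = FALSE], path)
  invisible(path)
}
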