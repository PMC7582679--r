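## Ingestion of prediction matrices from methods the package does not
## re-implement (pharmacophore-database screens, saved web-server downloads)
## and normalization into a common sparse form.

#' Construct a prediction matrix
#'
#' @param entries Data frame with columns `compound_id`, `target_id`,
#'   `score`; no duplicate (compound, target) keys.
#' @param method_name Name of the originating method.
#' @param fit_semantics `"lower_better"` (e.g. E-values), `"higher_better"`
#'   (probabilities, fit scores) or `"boolean"`.
#' @param is_anchor Whether this is the anchor method whose hit is mandatory
#'   for consensus eligibility (exactly one anchor per consensus run).
#' @return A `prediction_matrix`.
#' @export
prediction_matrix <- function(entries, method_name,
                              fit_semantics = c("lower_better", "higher_better", "boolean"),
                              is_anchor = FALSE) {
  fit_semantics <- match.arg(fit_semantics)
  entries <- data.frame(compound_id = as.character(entries$compound_id),
                        target_id = toupper(as.character(entries$target_id)),
                        score = as.numeric(entries$score),
                        stringsAsFactors = FALSE)
  key <- paste(entries$compound_id, entries$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    conflicting <- vapply(unique(dups), function(k) {
      length(unique(entries$score[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      tf_input_error(sprintf(
        "conflicting duplicate entries in matrix '%s': %s", method_name,
        paste(gsub("\r", "/", unique(dups)[conflicting]), collapse = ", ")))
    }
    warning(sprintf("matrix '%s': deduplicated %d repeated entries with equal scores",
                    method_name, sum(duplicated(key))))
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(method_name = method_name, entries = entries,
                 fit_semantics = fit_semantics, is_anchor = is_anchor),
            class = "prediction_matrix")
}

#' Read a prediction matrix from CSV
#'
#' Wide layout: first column `compound_id`, one column per target label,
#' cells hold scores; blank or `nan` cells mean "no prediction" and create
#' no entry.  Long layout: columns `compound_id,target_id,score`.
#'
#' @param path CSV file.
#' @param layout `"wide"` or `"long"`.
#' @inheritParams prediction_matrix
#' @return A `prediction_matrix`.
#' @export
read_prediction_matrix <- function(path, layout = c("wide", "long"), method_name,
                                   fit_semantics = c("lower_better", "higher_better", "boolean"),
                                   is_anchor = FALSE) {
  layout <- match.arg(layout)
  fit_semantics <- match.arg(fit_semantics)
  stopifnot_file(path)
  if (layout == "long") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("compound_id", "target_id", "score") %in% names(df))) {
      tf_input_error(sprintf("long matrix '%s' must have columns compound_id,target_id,score", path))
    }
    df$score <- suppressWarnings(as.numeric(df$score))
    df <- df[!is.na(df$score), , drop = FALSE]
  } else {
    wide <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(wide)[1] != "compound_id") {
      tf_input_error(sprintf("wide matrix '%s' must have 'compound_id' as its first column", path))
    }
    targets <- names(wide)[-1]
    rows <- lapply(targets, function(tg) {
      sc <- suppressWarnings(as.numeric(wide[[tg]]))
      keep <- !is.na(sc)
      data.frame(compound_id = wide$compound_id[keep], target_id = tg,
                 score = sc[keep], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$compound_id, df$target_id), , drop = FALSE]
  }
  prediction_matrix(df, method_name, fit_semantics, is_anchor)
}

#' Binarize a scored prediction matrix
#'
#' Keeps entries at or better than the cutoff (`<= cutoff` for lower-better
#' scores, `>= cutoff` for higher-better) and switches the matrix to boolean
#' semantics.  Binarization never creates entries and is idempotent on its
#' surviving set.
#'
#' @param matrix A scored `prediction_matrix`.
#' @param cutoff Numeric cutoff; required before a matrix enters consensus.
#' @return A boolean `prediction_matrix`.
#' @export
binarize <- function(matrix, cutoff) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  if (matrix$fit_semantics == "boolean") {
    tf_config_error(sprintf("matrix '%s' is already boolean", matrix$method_name))
  }
  if (missing(cutoff) || is.null(cutoff) || is.na(cutoff)) {
    tf_config_error(sprintf("a binarization cutoff is required for matrix '%s'",
                            matrix$method_name))
  }
  keep <- if (matrix$fit_semantics == "lower_better") {
    matrix$entries$score <= cutoff
  } else {
    matrix$entries$score >= cutoff
  }
  out <- matrix
  out$entries <- matrix$entries[keep, , drop = FALSE]
  rownames(out$entries) <- NULL
  out$score_semantics <- matrix$fit_semantics  # retained for score-ordered rankings
  out$fit_semantics <- "boolean"
  out
}

#' Read a target alias table
#'
#' @param path CSV with columns `label,target_id`.
#' @return Named character vector mapping uppercase labels to canonical
#'   uppercase target ids.
#' @export
read_alias_table <- function(path) {
  stopifnot_file(path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "target_id") %in% names(df))) {
    tf_input_error(sprintf("alias table '%s' must have columns label,target_id", path))
  }
  setNames(toupper(df$target_id), toupper(df$label))
}

#' Harmonize target labels across prediction matrices
#'
#' Maps every target label through the alias table to its canonical
#' gene-symbol-like id (case-insensitive, stored uppercase); labels absent
#' from the table map to themselves only if already canonical, otherwise the
#' full list of unmapped labels is a hard error.  Entries of one method that
#' collapse onto the same canonical target merge by best score.
#'
#' @param matrices List of `prediction_matrix` objects.
#' @param aliases Named vector from [read_alias_table()] (label -> target_id).
#' @return List of harmonized matrices.
#' @export
harmonize_targets <- function(matrices, aliases) {
  canonical <- unique(unname(aliases))
  all_labels <- unique(toupper(unlist(lapply(matrices, function(m) m$entries$target_id))))
  unmapped <- setdiff(all_labels, c(names(aliases), canonical))
  if (length(unmapped)) {
    tf_input_error(sprintf("unmapped target labels: %s",
                           paste(sort(unmapped), collapse = ", ")))
  }
  lapply(matrices, function(m) {
    lab <- toupper(m$entries$target_id)
    mapped <- ifelse(lab %in% names(aliases), unname(aliases[lab]), lab)
    e <- m$entries
    e$target_id <- mapped
    key <- paste(e$compound_id, e$target_id, sep = "\r")
    if (anyDuplicated(key)) {
      pick <- switch(m$fit_semantics,
                     lower_better = function(s) min(s),
                     higher_better = function(s) max(s),
                     boolean = function(s) max(s))
      e <- do.call(rbind, lapply(split(e, key), function(g) {
        g$score[1] <- pick(g$score)
        g[1, , drop = FALSE]
      }))
      e <- e[order(e$compound_id, e$target_id), , drop = FALSE]
      rownames(e) <- NULL
    }
    out <- m
    out$entries <- e
    out
  })
}
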