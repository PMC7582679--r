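## Consensus scoring and target selection.  Boolean prediction matrices from
## all channels are overlaid; each asserted (compound, target) pair receives
## a consensus score CS equal to the number of methods asserting it (the
## anchor method counts).  Known interactions are subtracted, targets are
## ranked by prediction frequency across the library, and candidates are
## assessed by the four selection criteria: high-CS hits on the assay panel
## (I), library-wide frequency ranks (II), pathway consistency plus novelty
## (III) and assay availability (IV).

#' Assemble the predicted biological space
#'
#' Overlays binarized, harmonized prediction matrices into one consensus
#' record per asserted (compound, target) pair.
#'
#' @param matrices List of boolean `prediction_matrix` objects, exactly one
#'   of which has `is_anchor = TRUE`.
#' @param min_cs Minimum consensus score for eligibility (default 2).
#' @return Data frame (`consensus_records`) with columns `compound_id`,
#'   `target_id`, `methods` (semicolon-joined), `cs`, `anchor_hit`,
#'   `eligible` (`anchor_hit & cs >= min_cs`).
#' @export
assemble_predicted_space <- function(matrices, min_cs = 2L) {
  if (!length(matrices)) tf_input_error("no prediction matrices supplied")
  non_bool <- vapply(matrices, function(m) m$fit_semantics != "boolean", logical(1))
  if (any(non_bool)) {
    tf_config_error(sprintf("matrices must be binarized before consensus: %s",
                            paste(vapply(matrices[non_bool], `[[`, character(1),
                                         "method_name"), collapse = ", ")))
  }
  n_anchor <- sum(vapply(matrices, `[[`, logical(1), "is_anchor"))
  if (n_anchor != 1) {
    tf_config_error(sprintf("exactly one anchor matrix required, found %d", n_anchor))
  }
  anchor_name <- matrices[[which(vapply(matrices, `[[`, logical(1), "is_anchor"))]]$method_name
  long <- do.call(rbind, lapply(matrices, function(m) {
    if (nrow(m$entries) == 0) return(NULL)
    data.frame(compound_id = m$entries$compound_id,
               target_id = m$entries$target_id,
               method = m$method_name, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) {
    return(structure(data.frame(compound_id = character(0), target_id = character(0),
                                methods = character(0), cs = integer(0),
                                anchor_hit = logical(0), eligible = logical(0),
                                stringsAsFactors = FALSE),
                     anchor_method = anchor_name, min_cs = as.integer(min_cs),
                     class = c("consensus_records", "data.frame")))
  }
  key <- paste(long$compound_id, long$target_id, sep = "\r")
  recs <- do.call(rbind, lapply(split(long, key), function(g) {
    methods <- sort(unique(g$method))
    data.frame(compound_id = g$compound_id[1], target_id = g$target_id[1],
               methods = paste(methods, collapse = ";"),
               cs = length(methods),
               anchor_hit = anchor_name %in% methods,
               stringsAsFactors = FALSE)
  }))
  recs$eligible <- recs$anchor_hit & recs$cs >= min_cs
  recs <- recs[order(recs$compound_id, recs$target_id), , drop = FALSE]
  rownames(recs) <- NULL
  structure(recs, anchor_method = anchor_name, min_cs = as.integer(min_cs),
            class = c("consensus_records", "data.frame"))
}

#' Subtract the known space from consensus records
#'
#' Removes every record whose (compound, target) pair — or whose parent
#' compound's pair — appears in the known space.  Idempotent; the number of
#' removed records is reported with a message.
#'
#' @param records `consensus_records` from [assemble_predicted_space()].
#' @param known A `known_space`.
#' @param parent_map Optional named vector `compound_id -> parent_id` for
#'   parent-level subtraction of stereo-expanded records.
#' @return The reduced `consensus_records`.
#' @export
subtract_known <- function(records, known, parent_map = NULL) {
  kn <- paste(known$records$compound_id, known$records$target_id, sep = "\r")
  own <- paste(records$compound_id, records$target_id, sep = "\r")
  hit <- own %in% kn
  if (!is.null(parent_map)) {
    parents <- unname(parent_map[records$compound_id])
    parents[is.na(parents)] <- records$compound_id[is.na(parents)]
    hit <- hit | paste(parents, records$target_id, sep = "\r") %in% kn
  }
  message(sprintf("subtract_known: removed %d of %d predicted interactions",
                  sum(hit), length(hit)))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$anchor_method <- attr(records, "anchor_method")
  attributes(out)$min_cs <- attr(records, "min_cs")
  out
}

#' Selection criterion I: high-consensus hits on the assay panel
#'
#' Eligible records (anchor hit required) of the panel compounds with
#' `cs >= min_cs`, grouped by target.
#'
#' @param records Subtracted `consensus_records`.
#' @param panel Character vector of panel compound ids.
#' @param min_cs Consensus-score floor (default 2).
#' @return Named list (by target) of data frames `compound_id,cs`.
#' @export
criterion_I <- function(records, panel, min_cs = 2L) {
  if (!length(panel)) tf_input_error("criterion_I requires a non-empty panel")
  sel <- records[records$eligible & records$compound_id %in% panel &
                   records$cs >= min_cs, , drop = FALSE]
  lapply(split(sel[, c("compound_id", "cs")], sel$target_id), function(d) {
    d <- d[order(d$compound_id), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Selection criterion II: library-wide target frequency ranking
#'
#' For each consensus-score level, counts the library compounds with an
#' eligible record at or above that level per target and ranks targets by
#' descending frequency.  Tied targets share the lower rank number and are
#' ordered lexicographically for display.
#'
#' @param records Subtracted `consensus_records` over the full library.
#' @param cs_levels Integer vector of consensus-score levels (default 2:3).
#' @return Data frame `cs_level,rank,target_id,frequency`.
#' @export
criterion_II <- function(records, cs_levels = c(2L, 3L)) {
  out <- lapply(cs_levels, function(lv) {
    sel <- records[records$eligible & records$cs >= lv, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    freq <- vapply(split(sel$compound_id, sel$target_id),
                   function(x) length(unique(x)), numeric(1))
    df <- data.frame(cs_level = lv, target_id = names(freq),
                     frequency = as.integer(freq), stringsAsFactors = FALSE)
    df$rank <- as.integer(rank(-df$frequency, ties.method = "min"))
    df[order(df$rank, df$target_id), c("cs_level", "rank", "target_id", "frequency")]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cs_level = integer(0), rank = integer(0),
                      target_id = character(0), frequency = integer(0))
  }
  rownames(res) <- NULL
  res
}

#' Selection criterion III: pathway consistency and novelty
#'
#' For each candidate target: `novelty` is `TRUE` when no panel compound has
#' a known interaction with the target, and `related_targets` lists the
#' other predicted or known targets sharing at least one pathway name.
#'
#' @param records Subtracted `consensus_records`.
#' @param known A `known_space`.
#' @param pathway_annotations Data frame `target_id,pathway`.
#' @param panel Panel compound ids (default: all compounds in `records`).
#' @param candidates Targets to assess (default: all targets with an
#'   eligible record).
#' @return Data frame `target_id,novelty,related_targets` (semicolon-joined).
#' @export
criterion_III <- function(records, known, pathway_annotations,
                          panel = unique(records$compound_id),
                          candidates = unique(records$target_id[records$eligible])) {
  if (nrow(pathway_annotations) == 0) {
    message("criterion_III: no pathway annotations available; evidence lists are empty")
  }
  known_pairs <- known$records[, c("compound_id", "target_id"), drop = FALSE]
  universe <- unique(c(records$target_id, known$records$target_id))
  pw_by_target <- split(pathway_annotations$pathway, pathway_annotations$target_id)
  out <- do.call(rbind, lapply(sort(candidates), function(tg) {
    nov <- !any(known_pairs$target_id == tg & known_pairs$compound_id %in% panel)
    own_pw <- pw_by_target[[tg]] %||% character(0)
    related <- if (length(own_pw)) {
      others <- setdiff(universe, tg)
      others[vapply(others, function(o) {
        length(intersect(own_pw, pw_by_target[[o]] %||% character(0))) > 0
      }, logical(1))]
    } else character(0)
    data.frame(target_id = tg, novelty = nov,
               related_targets = paste(sort(related), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Selection report over criteria I-IV
#'
#' Assembles, per candidate target, the panel hits (criterion I), the
#' frequency ranks per consensus-score level (criterion II), pathway
#' consistency and novelty (criterion III) and assay availability
#' (criterion IV, a configuration table), plus a final `selected` flag:
#' assay available, novel, and supported by criterion I or ranked in the
#' top `rank_cutoff` of criterion II.
#'
#' @param records Subtracted `consensus_records`.
#' @param known A `known_space`.
#' @param pathway_annotations Data frame `target_id,pathway`.
#' @param panel Panel compound ids.
#' @param assay_availability Data frame `target_id,assay_available`.
#' @param min_cs,cs_levels,rank_cutoff Tuning of criteria I and II.
#' @return Data frame, one row per candidate target.
#' @export
selection_report <- function(records, known, pathway_annotations, panel,
                             assay_availability, min_cs = 2L,
                             cs_levels = c(2L, 3L), rank_cutoff = 10L) {
  ci <- criterion_I(records, panel, min_cs = min_cs)
  cii <- criterion_II(records, cs_levels = cs_levels)
  candidates <- sort(unique(c(names(ci), cii$target_id)))
  ciii <- criterion_III(records, known, pathway_annotations, panel = panel,
                        candidates = candidates)
  avail <- setNames(as.logical(assay_availability$assay_available),
                    toupper(assay_availability$target_id))
  rows <- lapply(candidates, function(tg) {
    hits <- ci[[tg]]
    hits_str <- if (is.null(hits)) "" else
      paste(sprintf("%s (CS=%d)", hits$compound_id, hits$cs), collapse = ";")
    ranks <- cii[cii$target_id == tg, , drop = FALSE]
    ranks_str <- if (nrow(ranks) == 0) "" else
      paste(sprintf("rank %d (CS>=%d, n=%d)", ranks$rank, ranks$cs_level,
                    ranks$frequency), collapse = ";")
    c3 <- ciii[ciii$target_id == tg, , drop = FALSE]
    availability <- isTRUE(unname(avail[tg]))
    best_rank <- if (nrow(ranks)) min(ranks$rank) else Inf
    data.frame(
      target_id = tg,
      criterion_I_hits = hits_str,
      criterion_II_ranks = ranks_str,
      criterion_III_related = c3$related_targets,
      novelty = c3$novelty,
      assay_available = availability,
      selected = availability && c3$novelty &&
        (!is.null(hits) || best_rank <= rank_cutoff),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrichment of known interactions in prediction rankings
#'
#' Recovery test run without known-space subtraction: every ranking (each
#' scored method's own ordering, and the consensus ordering by descending
#' consensus score) is truncated at `top_k`, and the enrichment factor is
#' the fraction of known pairs recovered in the head divided by the
#' expectation under a uniformly random ranking of the same prediction
#' universe (`top_k / universe size`).  The universe is the set of pairs
#' asserted by at least one loaded method.
#'
#' @param records Unsubtracted `consensus_records`.
#' @param matrices The scored (pre-binarization) `prediction_matrix` list.
#' @param known A non-empty `known_space`.
#' @param top_k Ranking head size.
#' @return Data frame `method,ef,recovered,top_k,n_known,universe`; the
#'   consensus row has method `"consensus"`.
#' @export
enrichment <- function(records, matrices, known, top_k) {
  if (nrow(known$records) == 0) {
    tf_input_error("enrichment requires a non-empty known space")
  }
  known_keys <- unique(paste(known$records$compound_id, known$records$target_id,
                             sep = "\r"))
  universe_keys <- unique(c(
    unlist(lapply(matrices, function(m) {
      paste(m$entries$compound_id, m$entries$target_id, sep = "\r")
    })),
    paste(records$compound_id, records$target_id, sep = "\r")
  ))
  universe <- length(universe_keys)
  n_known_in_universe <- sum(known_keys %in% universe_keys)
  if (n_known_in_universe == 0) {
    tf_input_error("no known pair lies inside the prediction universe")
  }
  ef_of <- function(ordered_keys) {
    head_keys <- utils::head(ordered_keys, top_k)
    recovered <- sum(known_keys %in% head_keys)
    frac <- recovered / n_known_in_universe
    rand <- min(top_k, universe) / universe
    c(ef = frac / rand, recovered = recovered)
  }
  rows <- lapply(matrices, function(m) {
    e <- m$entries
    sem <- if (m$fit_semantics == "boolean") m$score_semantics %||% "higher_better" else
      m$fit_semantics
    ord <- switch(sem,
                  lower_better = order(e$score, e$compound_id, e$target_id),
                  order(-e$score, e$compound_id, e$target_id))
    r <- ef_of(paste(e$compound_id[ord], e$target_id[ord], sep = "\r"))
    data.frame(method = m$method_name, ef = r[["ef"]],
               recovered = as.integer(r[["recovered"]]), stringsAsFactors = FALSE)
  })
  ordc <- order(-records$cs, records$compound_id, records$target_id)
  rc <- ef_of(paste(records$compound_id[ordc], records$target_id[ordc], sep = "\r"))
  rows[[length(rows) + 1L]] <- data.frame(method = "consensus", ef = rc[["ef"]],
                                          recovered = as.integer(rc[["recovered"]]),
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$top_k <- as.integer(top_k)
  out$n_known <- as.integer(n_known_in_universe)
  out$universe <- as.integer(universe)
  rownames(out) <- NULL
  out
}

#' Write consensus records to CSV
#'
#' @param records `consensus_records`.
#' @param path Output CSV
#'   (`compound_id,target_id,cs,anchor_hit,methods,eligible`).
#' @export
write_consensus <- function(records, path) {
  df <- records[, c("compound_id", "target_id", "cs", "anchor_hit", "methods",
                    "eligible"), drop = FALSE]
  write_csv_atomic(df, path)
  invisible(path)
}
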