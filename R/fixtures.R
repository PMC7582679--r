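## Seeded synthetic fixtures: a scaffold-decorated compound class with
## planted true targets, reference ligand sets, bioactivity tables for the
## fixture mining backend, and noisy external prediction matrices.  All
## generators are pure functions of the fixture specification, so identical
## specs give byte-identical files.

## Substituent grammar: each slot takes one decoration written directly
## after an in-ring atom.  The glycoside-like fragment deliberately carries
## no stereo marks, mimicking natural-product curation gaps.
.dhc_template <- "O=C(C{RC}Cc2ccc{R1}c{R2}c2)c1c(O)cc{R3}cc1O"
.dhc_subs <- list(
  R1 = c("", "(O)", "(OC)", "(OC3OC(CO)C(O)C(O)C3O)"),
  R2 = c("", "(O)", "(OC)", "(OC3OC(CO)C(O)C(O)C3O)"),
  R3 = c("", "(O)", "(OC)", "(OC3OC(CO)C(O)C(O)C3O)"),
  RC = c("", "", "", "(O)", "(C)")
)

.decoy_templates <- c(
  "O=C1CC{A}C(C{B})CC1",
  "c1cc{A}ccc1-c1cc{B}ccc1",
  "c1cc{A}ccc1N1CC{B}NCC1",
  "O=C(N{A}C)c1cc{B}ccc1",
  "c1cc{A}ccc1OCC{B}N(C)C",
  "C{A}C1CCc2cc{B}ccc2C1",
  "c1cc{A}ccc1S(=O)(=O)NC{B}",
  "c1cc{A}ccc1C(=O)OC{B}C",
  "C{A}N1CCC(c2cc{B}ccc2)CC1",
  "O=C(OC{A})C1CC{B}CN1C"
)
.decoy_subs <- c("", "(C)", "(O)", "(OC)", "(N)", "(Cl)", "(CC)")

fill_template <- function(template, subs) {
  for (nm in names(subs)) {
    template <- gsub(paste0("{", nm, "}"), subs[[nm]], template, fixed = TRUE)
  }
  template
}

#' Synthetic fixture specification
#'
#' Defines the study conditions emulated by the fixture generators: a
#' scaffold-decorated compound class, reference target ligand sets with
#' controlled internal similarity, a sparse known-interaction table and
#' noisy external prediction channels.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param n_compounds Library size (default 60).
#' @param n_targets Total reference targets (default 50).
#' @param n_planted_targets Targets genuinely matching the library's
#'   scaffold (default 5).
#' @param ligands_per_target Known ligands per reference set (default 8).
#' @param intra_set_similarity `"high"`, `"medium"` or `"low"`: how uniform
#'   each decoy set's scaffold is.
#' @param known_fraction Fraction of planted truths also exposed in the
#'   fixture bioactivity tables (default 0.4).
#' @param noise_rate Probability that a simulated method asserts a decoy
#'   pair (default 0.02).
#' @param miss_rate Probability that a simulated method misses a true pair
#'   (default 0.1).
#' @param n_panel Compounds designated as the assay panel (default 10).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_compounds = 60L, n_targets = 50L,
                         n_planted_targets = 5L, ligands_per_target = 8L,
                         intra_set_similarity = c("high", "medium", "low"),
                         known_fraction = 0.4, noise_rate = 0.02,
                         miss_rate = 0.1, n_panel = 10L) {
  intra_set_similarity <- match.arg(intra_set_similarity)
  stopifnot(n_planted_targets <= n_targets, known_fraction >= 0, known_fraction <= 1)
  structure(list(
    seed = as.integer(seed), n_compounds = as.integer(n_compounds),
    scaffold = fill_template(.dhc_template, list(R1 = "", R2 = "", R3 = "", RC = "")),
    template = .dhc_template, substituent_grammar = .dhc_subs,
    n_targets = as.integer(n_targets),
    n_planted_targets = as.integer(n_planted_targets),
    ligands_per_target = as.integer(ligands_per_target),
    intra_set_similarity = intra_set_similarity,
    known_fraction = known_fraction, noise_rate = noise_rate,
    miss_rate = miss_rate, n_panel = as.integer(n_panel)
  ), class = "fixture_spec")
}

## Draw n distinct valid decorated molecules from a template grammar.
## `first_bare = TRUE` puts the undecorated scaffold first.
.decorate <- function(template, grammar, n, first_bare = FALSE) {
  combos <- expand.grid(grammar, stringsAsFactors = FALSE)
  bare <- vapply(names(grammar), function(x) "", character(1))
  ord <- sample.int(nrow(combos))
  smiles <- character(0)
  seen <- character(0)
  if (first_bare) {
    s <- ob_canonical(fill_template(template, as.list(bare)))
    smiles <- fill_template(template, as.list(bare))
    seen <- s
  }
  for (i in ord) {
    if (length(smiles) >= n) break
    cand <- fill_template(template, as.list(combos[i, , drop = FALSE]))
    canon <- ob_canonical(cand)
    if (is.na(canon) || canon %in% seen) next
    smiles <- c(smiles, cand)
    seen <- c(seen, canon)
  }
  if (length(smiles) < n) {
    tf_input_error(sprintf(
      "substituent grammar can only produce %d distinct molecules (requested %d)",
      length(smiles), n))
  }
  smiles[seq_len(n)]
}

#' Generate the fixture compound library
#'
#' `n_compounds` distinct molecules sharing the scaffold; the first entry is
#' the bare scaffold itself.
#'
#' @param spec A [fixture_spec()].
#' @return Data frame `compound_id,smiles,name,source`.
#' @export
generate_library <- function(spec) {
  smiles <- with_seed(spec$seed, {
    .decorate(spec$template, spec$substituent_grammar, spec$n_compounds,
              first_bare = TRUE)
  })
  data.frame(
    compound_id = sprintf("CPD%03d", seq_along(smiles)),
    smiles = smiles,
    name = sprintf("fixture compound %d", seq_along(smiles)),
    source = "synthetic",
    stringsAsFactors = FALSE
  )
}

#' Generate reference ligand sets and the planted-truth table
#'
#' Planted targets receive ligand sets drawn from the library's own scaffold
#' grammar (so library compounds genuinely resemble them); decoy targets
#' receive ligands decorated on unrelated scaffolds.  Every (library
#' compound, planted target) pair is a genuine truth.
#'
#' @param spec A [fixture_spec()].
#' @param library Data frame from [generate_library()].
#' @return List with `reference` (`target_id,smiles`) and `truth`
#'   (`compound_id,target_id`).
#' @export
generate_reference_sets <- function(spec, library) {
  with_seed(spec$seed + 1L, {
    planted <- sprintf("TP%02d", seq_len(spec$n_planted_targets))
    decoys <- sprintf("TD%02d", seq_len(spec$n_targets - spec$n_planted_targets))
    mix <- switch(spec$intra_set_similarity, high = 1L, medium = 2L, low = 4L)
    ref_rows <- list()
    for (tg in planted) {
      smi <- .decorate(spec$template, spec$substituent_grammar,
                       spec$ligands_per_target)
      ref_rows[[tg]] <- data.frame(target_id = tg, smiles = smi,
                                   stringsAsFactors = FALSE)
    }
    for (k in seq_along(decoys)) {
      ## `mix` scaffolds per decoy set controls its internal similarity
      scaffs <- .decoy_templates[1 + (k - 1 + seq_len(mix) - 1) %% length(.decoy_templates)]
      per <- ceiling(spec$ligands_per_target / mix)
      smi <- unlist(lapply(scaffs, function(tpl) {
        .decorate(tpl, list(A = .decoy_subs, B = .decoy_subs), per)
      }))[seq_len(spec$ligands_per_target)]
      ref_rows[[decoys[k]]] <- data.frame(target_id = decoys[k], smiles = smi,
                                          stringsAsFactors = FALSE)
    }
    reference <- do.call(rbind, ref_rows)
    rownames(reference) <- NULL
    truth <- expand.grid(compound_id = library$compound_id, target_id = planted,
                         stringsAsFactors = FALSE)
    truth <- truth[order(truth$compound_id, truth$target_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(reference = reference, truth = truth)
  })
}

#' Generate the four fixture-backend tables
#'
#' Exposes a `known_fraction` subset of the truths as active single-protein
#' assay records (1-4 records per pair, drawn seeded, giving the interaction
#' weights) plus distractor assays that violate the single-protein rule or
#' carry an inactive flag, to exercise the mining filters.  Planted targets
#' share one pathway so pathway-consistency evidence is non-trivial.
#'
#' @param spec A [fixture_spec()].
#' @param library Data frame from [generate_library()].
#' @param truth Truth table from [generate_reference_sets()].
#' @return List of data frames `compounds`, `assays`, `proteins`,
#'   `pathways`, plus `exposed` (the truth subset behind the assay records).
#' @export
generate_backend_tables <- function(spec, library, truth) {
  with_seed(spec$seed + 2L, {
    canon <- vapply(library$smiles, function(s) standardize_smiles(s)$smiles_canonical,
                    character(1), USE.NAMES = FALSE)
    compounds <- data.frame(smiles_canonical = canon,
                            cid = sprintf("C%04d", seq_len(nrow(library))),
                            stringsAsFactors = FALSE)
    cid_of <- setNames(compounds$cid, library$compound_id)

    n_exposed <- round(spec$known_fraction * nrow(truth))
    exposed <- truth[sample.int(nrow(truth), n_exposed), , drop = FALSE]
    exposed <- exposed[order(exposed$compound_id, exposed$target_id), , drop = FALSE]
    rownames(exposed) <- NULL

    aid_counter <- 0L
    assay_rows <- list()
    next_aid <- function() {
      aid_counter <<- aid_counter + 1L
      sprintf("AID%05d", aid_counter)
    }
    for (i in seq_len(nrow(exposed))) {
      n_rec <- sample(1:4, 1)
      for (j in seq_len(n_rec)) {
        assay_rows[[length(assay_rows) + 1L]] <- data.frame(
          cid = unname(cid_of[exposed$compound_id[i]]), aid = next_aid(),
          activity_flag = "active", gene_names = exposed$target_id[i],
          stringsAsFactors = FALSE)
      }
    }
    ## distractors: multi-protein assays and inactive records must be ignored
    all_targets <- sort(unique(c(truth$target_id,
                                 sprintf("TD%02d", seq_len(spec$n_targets - spec$n_planted_targets)))))
    distract_cids <- sample(compounds$cid, min(10, nrow(compounds)))
    for (cid in distract_cids) {
      g2 <- sample(all_targets, 2)
      assay_rows[[length(assay_rows) + 1L]] <- data.frame(
        cid = cid, aid = next_aid(), activity_flag = "active",
        gene_names = paste(g2, collapse = ";"), stringsAsFactors = FALSE)
      assay_rows[[length(assay_rows) + 1L]] <- data.frame(
        cid = cid, aid = next_aid(), activity_flag = "inactive",
        gene_names = sample(all_targets, 1), stringsAsFactors = FALSE)
    }
    assays <- do.call(rbind, assay_rows) %||%
      data.frame(cid = character(0), aid = character(0),
                 activity_flag = character(0), gene_names = character(0))

    proteins <- data.frame(gene = all_targets,
                           protein_entry = paste0(all_targets, "_HUMAN"),
                           stringsAsFactors = FALSE)
    pathway_pool <- c("steroid metabolism", "arachidonic acid metabolism",
                      "glycolysis", "xenobiotic clearance", "neurotransmission",
                      "cell cycle control")
    planted <- sort(unique(truth$target_id))
    pathways <- rbind(
      data.frame(protein_entry = paste0(planted, "_HUMAN"),
                 pathway = "dihydrochalcone response", stringsAsFactors = FALSE),
      data.frame(protein_entry = paste0(all_targets, "_HUMAN"),
                 pathway = pathway_pool[1 + (seq_along(all_targets) - 1) %% length(pathway_pool)],
                 stringsAsFactors = FALSE)
    )
    list(compounds = compounds, assays = assays, proteins = proteins,
         pathways = pathways, exposed = exposed)
  })
}

#' Generate noisy external prediction matrices
#'
#' Simulates the anchor pharmacophore channel and two fallible servers: each
#' method asserts a true pair with probability `1 - miss_rate` and a decoy
#' pair with probability `noise_rate`, with independent seeded noise per
#' method.
#'
#' @param spec A [fixture_spec()].
#' @param library Data frame from [generate_library()].
#' @param truth Truth table from [generate_reference_sets()].
#' @return Named list of scored `prediction_matrix` objects; the `phdb`
#'   matrix is the anchor.
#' @export
generate_method_noise <- function(spec, library, truth) {
  all_targets <- sort(unique(c(truth$target_id,
                               sprintf("TD%02d", seq_len(spec$n_targets - spec$n_planted_targets)))))
  grid <- expand.grid(compound_id = library$compound_id, target_id = all_targets,
                      stringsAsFactors = FALSE)
  truth_key <- paste(truth$compound_id, truth$target_id, sep = "\r")
  grid$is_truth <- paste(grid$compound_id, grid$target_id, sep = "\r") %in% truth_key

  methods <- list(
    list(name = "phdb", semantics = "higher_better", anchor = TRUE,
         score = function(n) runif(n, 0.5, 1)),
    list(name = "server_a", semantics = "lower_better", anchor = FALSE,
         score = function(n) 10^-runif(n, 6, 30)),
    list(name = "server_b", semantics = "higher_better", anchor = FALSE,
         score = function(n) runif(n, 0.5, 1))
  )
  out <- list()
  for (k in seq_along(methods)) {
    m <- methods[[k]]
    entries <- with_seed(spec$seed + 10L + k, {
      p_emit <- ifelse(grid$is_truth, 1 - spec$miss_rate, spec$noise_rate)
      emit <- runif(nrow(grid)) < p_emit
      e <- grid[emit, c("compound_id", "target_id"), drop = FALSE]
      e$score <- m$score(nrow(e))
      e
    })
    out[[m$name]] <- prediction_matrix(entries, m$name, m$semantics,
                                       is_anchor = m$anchor)
  }
  out
}

#' Generate a diverse decoy molecule pool
#'
#' Draws decorated molecules from all decoy scaffolds in rotation; used as
#' the random-ensemble pool for background calibration.
#'
#' @param n Pool size.
#' @param seed Integer seed.
#' @return Character vector of SMILES.
#' @export
generate_decoy_pool <- function(n, seed = 7L) {
  with_seed(seed, {
    per <- ceiling(n / length(.decoy_templates))
    smi <- unlist(lapply(.decoy_templates, function(tpl) {
      .decorate(tpl, list(A = .decoy_subs, B = .decoy_subs), per)
    }))
    smi[seq_len(n)]
  })
}

#' Write a complete fixture set to a directory
#'
#' Emits the library CSV, the reference-set CSV, the planted-truth CSV, the
#' four backend tables (under `backend/`), one long-layout CSV per simulated
#' method matrix (under `matrices/`) and the spec echoed as JSON.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
generate_fixture_set <- function(spec, dir) {
  dir.create(file.path(dir, "backend"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  library_df <- generate_library(spec)
  refs <- generate_reference_sets(spec, library_df)
  backend <- generate_backend_tables(spec, library_df, refs$truth)
  matrices <- generate_method_noise(spec, library_df, refs$truth)

  write_csv_atomic(library_df, file.path(dir, "library.csv"))
  write_csv_atomic(refs$reference, file.path(dir, "reference_sets.csv"))
  write_csv_atomic(refs$truth, file.path(dir, "truth.csv"))
  write_csv_atomic(backend$exposed, file.path(dir, "exposed_truth.csv"))
  for (nm in c("compounds", "assays", "proteins", "pathways")) {
    write_csv_atomic(backend[[nm]], file.path(dir, "backend", paste0(nm, ".csv")))
  }
  for (nm in names(matrices)) {
    write_csv_atomic(matrices[[nm]]$entries, file.path(dir, "matrices", paste0(nm, ".csv")))
  }
  spec_json <- spec
  write_atomic(function(tmp) {
    jsonlite::write_json(unclass(spec_json), tmp, auto_unbox = TRUE, digits = NA)
  }, file.path(dir, "fixture_spec.json"))
  invisible(list(spec = spec, library = library_df, reference = refs$reference,
                 truth = refs$truth, backend = backend, matrices = matrices,
                 dir = dir))
}
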