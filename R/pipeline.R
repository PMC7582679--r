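## Pipeline orchestration: the workflow stages (Data Preparation -> Virtual
## Screening -> Bioactivity Mining -> Scoring and Selecting) as composable,
## deterministic commands over one run configuration.  Every stage writes
## its outputs atomically plus a manifest listing inputs, outputs, seeds and
## content hashes; re-running a stage with identical config and inputs gives
## byte-identical primary outputs.

#' Build a run configuration
#'
#' Defaults are merged under any values supplied in `overrides` (a list or a
#' YAML file path).  The effective configuration is echoed verbatim into the
#' output directory by every stage.
#'
#' @param overrides Named list of settings, or path to a YAML file.
#' @param outdir Output directory (default `"tarfish_run"`).
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(overrides = list(), outdir = "tarfish_run", seed = 1L) {
  if (is.character(overrides)) {
    stopifnot_file(overrides)
    overrides <- yaml::read_yaml(overrides) %||% list()
  }
  if (!is.list(overrides)) tf_config_error("config overrides must be a list or YAML path")
  defaults <- list(
    outdir = outdir,
    seed = as.integer(seed),
    library = NULL,                   # compound CSV; simulate fills this in
    library_format = "smiles-csv",
    reference_sets = NULL,
    backend_dir = NULL,
    matrices = NULL,                  # list of matrix channel descriptions
    expand_stereo = FALSE,
    max_centers = 6L,
    fingerprint = list(circular_bits = 2048L, circular_radius = 2L, path_type = "FP2"),
    ensemble = list(threshold = 0.57, e_cutoff = 1e-5,
                    n_decoys = 120L, n_samples = 80L,
                    set_sizes = list(c(1, 4), c(1, 8), c(2, 8), c(4, 8), c(8, 8))),
    min_cs = 2L,
    cs_levels = c(2L, 3L),
    top_k = NULL,                     # enrichment head; default |known|
    panel = NULL,                     # panel compound ids; default first 10
    assay_table = NULL,
    assay_availability = NULL,
    fixture = list()                  # fixture_spec overrides for `simulate`
  )
  cfg <- utils::modifyList(defaults, overrides)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

.stage_producers <- c(
  library = "simulate", reference_sets = "simulate", backend_dir = "simulate",
  matrices = "simulate",
  library_std = "fingerprint", fingerprints = "fingerprint",
  background = "calibrate", sea_predictions = "predict",
  known_space = "mine", consensus = "consensus", ranking = "consensus"
)

.stage_path <- function(config, what) {
  file.path(config$outdir, switch(what,
    library_std = "library_std.csv",
    rejects = "rejects.csv",
    fingerprints = "fingerprints.rds",
    background = "background.json",
    sea_predictions = "sea_predictions.csv",
    known_space = "known_space.csv",
    sif = "known_space.sif",
    consensus = "consensus.csv",
    ranking = "ranking.csv",
    enrichment = "enrichment.csv",
    report = "report.json",
    assay_calls = "assay_calls.csv",
    config = "config_echo.json",
    what))
}

.need_input <- function(path, what, config) {
  if (is.null(path) || !file.exists(path)) {
    producer <- .stage_producers[[what]] %||% "an upstream stage"
    tf_input_error(sprintf(
      "missing input '%s' (%s); run stage '%s' first or point the config at an existing file",
      what, path %||% "<unset>", producer))
  }
  path
}

.write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
  )
  path <- file.path(config$outdir, sprintf("manifest_%s.json", gsub("-", "_", stage)))
  write_atomic(function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
  path
}

.echo_config <- function(config) {
  write_atomic(function(tmp) {
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }, .stage_path(config, "config"))
}

## Default fixture-derived paths when `simulate` has run in this outdir.
.resolve_fixture_defaults <- function(config) {
  fdir <- file.path(config$outdir, "fixtures")
  if (is.null(config$library) && file.exists(file.path(fdir, "library.csv"))) {
    config$library <- file.path(fdir, "library.csv")
  }
  if (is.null(config$reference_sets) && file.exists(file.path(fdir, "reference_sets.csv"))) {
    config$reference_sets <- file.path(fdir, "reference_sets.csv")
  }
  if (is.null(config$backend_dir) && dir.exists(file.path(fdir, "backend"))) {
    config$backend_dir <- file.path(fdir, "backend")
  }
  if (is.null(config$matrices) && dir.exists(file.path(fdir, "matrices"))) {
    config$matrices <- list(
      list(path = file.path(fdir, "matrices", "phdb.csv"), layout = "long",
           method_name = "phdb", fit_semantics = "higher_better",
           is_anchor = TRUE, cutoff = 1e-12),
      list(path = file.path(fdir, "matrices", "server_a.csv"), layout = "long",
           method_name = "server_a", fit_semantics = "lower_better",
           is_anchor = FALSE, cutoff = 1e-4),
      list(path = file.path(fdir, "matrices", "server_b.csv"), layout = "long",
           method_name = "server_b", fit_semantics = "higher_better",
           is_anchor = FALSE, cutoff = 0.5)
    )
  }
  config
}

.load_channel_matrices <- function(config, binarized = TRUE) {
  if (is.null(config$matrices) || !length(config$matrices)) {
    tf_input_error("missing input 'matrices'; run stage 'simulate' first or configure matrix channels")
  }
  mats <- lapply(config$matrices, function(ch) {
    .need_input(ch$path, "matrices", config)
    m <- read_prediction_matrix(ch$path, layout = ch$layout %||% "long",
                                method_name = ch$method_name,
                                fit_semantics = ch$fit_semantics,
                                is_anchor = isTRUE(ch$is_anchor))
    if (binarized && m$fit_semantics != "boolean") m <- binarize(m, ch$cutoff)
    m
  })
  names(mats) <- vapply(mats, `[[`, character(1), "method_name")
  mats
}

.sea_channel <- function(config, binarized = TRUE) {
  path <- .stage_path(config, "sea_predictions")
  .need_input(path, "sea_predictions", config)
  preds <- read.csv(path, stringsAsFactors = FALSE)
  m <- prediction_matrix(
    data.frame(compound_id = preds$query_id, target_id = preds$target_id,
               score = preds$e_value, stringsAsFactors = FALSE),
    method_name = "sea", fit_semantics = "lower_better")
  if (binarized) binarize(m, config$ensemble$e_cutoff) else m
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (emit the synthetic fixture set), `fingerprint` (load,
#' standardize, optionally stereo-expand and fingerprint the library),
#' `calibrate` (fit the random-ensemble background), `predict` (run the
#' similarity-ensemble channel), `mine` (build and export the known
#' biological space), `consensus` (binarize channels, assemble, subtract,
#' rank, measure enrichment), `report` (selection criteria I-IV) and
#' `classify-assays` (activity calls from a percent-inhibition table).
#' Missing inputs name the stage that produces them.
#'
#' @param stage Stage name.
#' @param config A [run_config()].
#' @return Invisibly, the list of primary output paths of the stage.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "fingerprint", "calibrate", "predict",
                              "mine", "consensus", "report", "classify-assays"))
  if (!inherits(config, "run_config")) tf_config_error("config must be a run_config object")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  config <- .resolve_fixture_defaults(config)
  .echo_config(config)
  outputs <- switch(stage,
    "simulate" = {
      spec <- do.call(fixture_spec, utils::modifyList(list(seed = config$seed),
                                                      config$fixture))
      res <- generate_fixture_set(spec, file.path(config$outdir, "fixtures"))
      list.files(res$dir, recursive = TRUE, full.names = TRUE)
    },
    "fingerprint" = {
      .need_input(config$library, "library", config)
      lib <- load_library(config$library, format = config$library_format)
      lib <- standardize_library(lib, count_centers = TRUE)
      if (isTRUE(config$expand_stereo)) {
        lib <- enumerate_stereoisomers(lib, max_centers = config$max_centers)
      }
      fpc <- do.call(fp_config, config$fingerprint)
      fps <- fingerprint_library(lib, fpc)
      out_lib <- .stage_path(config, "library_std")
      out_rej <- .stage_path(config, "rejects")
      out_fp <- .stage_path(config, "fingerprints")
      write_csv_atomic(as.data.frame(lib), out_lib)
      write_rejects(lib, out_rej)
      write_atomic(function(tmp) saveRDS(fps, tmp, version = 2), out_fp)
      c(out_lib, out_rej, out_fp)
    },
    "calibrate" = {
      fpc <- do.call(fp_config, config$fingerprint)
      decoys <- ob_canonical(generate_decoy_pool(config$ensemble$n_decoys,
                                                 seed = config$seed + 7L))
      dfps <- fingerprint_set(decoys, config = fpc)
      bg <- fit_background(dfps$circular, config$ensemble$set_sizes,
                           threshold = config$ensemble$threshold,
                           n_samples = config$ensemble$n_samples,
                           seed = config$seed)
      out <- .stage_path(config, "background")
      write_background_model(bg, out)
      out
    },
    "predict" = {
      fps <- readRDS(.need_input(.stage_path(config, "fingerprints"),
                                 "fingerprints", config))
      bg <- read_background_model(.need_input(.stage_path(config, "background"),
                                              "background", config))
      .need_input(config$reference_sets, "reference_sets", config)
      fpc <- do.call(fp_config, config$fingerprint)
      sets <- read_reference_sets(config$reference_sets, config = fpc)
      preds <- predict_library_targets(fps, sets, bg,
                                       e_cutoff = config$ensemble$e_cutoff)
      out <- .stage_path(config, "sea_predictions")
      write_csv_atomic(preds, out)
      out
    },
    "mine" = {
      lib_path <- .need_input(.stage_path(config, "library_std"), "library_std", config)
      lib <- read.csv(lib_path, stringsAsFactors = FALSE)
      .need_input(file.path(config$backend_dir %||% "", "compounds.csv"),
                  "backend_dir", config)
      backend <- fixture_backend(config$backend_dir)
      space <- build_known_space(lib, backend)
      out_csv <- .stage_path(config, "known_space")
      out_sif <- .stage_path(config, "sif")
      write_known_space(space, out_csv)
      export_sif(space, out_sif)
      write_csv_atomic(known_space_pathways(space),
                       file.path(config$outdir, "pathway_annotations.csv"))
      c(out_csv, out_sif)
    },
    "consensus" = {
      mats <- .load_channel_matrices(config, binarized = TRUE)
      mats$sea <- .sea_channel(config)
      known <- read_sif(.need_input(.stage_path(config, "sif"), "known_space", config))
      recs <- assemble_predicted_space(mats, min_cs = config$min_cs)
      ## enrichment is a recovery test: binarized assertions define the
      ## universe, each channel's surviving entries keep their score order.
      ## The default head size is the number of consensus-supported pairs:
      ## a head smaller than the scale of the true interaction set measures
      ## mostly sampling noise.
      ef <- enrichment(recs, mats, known,
                       top_k = config$top_k %||% max(sum(recs$cs >= config$min_cs), 1L))
      recs_sub <- subtract_known(recs, known)
      rk <- criterion_II(recs_sub, cs_levels = config$cs_levels)
      out_cons <- .stage_path(config, "consensus")
      out_rank <- .stage_path(config, "ranking")
      out_ef <- .stage_path(config, "enrichment")
      write_consensus(recs_sub, out_cons)
      write_csv_atomic(rk, out_rank)
      write_csv_atomic(ef, out_ef)
      c(out_cons, out_rank, out_ef)
    },
    "report" = {
      cons_path <- .need_input(.stage_path(config, "consensus"), "consensus", config)
      cons <- read.csv(cons_path, stringsAsFactors = FALSE)
      recs <- structure(cons, class = c("consensus_records", "data.frame"))
      known <- read_sif(.need_input(.stage_path(config, "sif"), "known_space", config))
      pw_path <- file.path(config$outdir, "pathway_annotations.csv")
      pw <- if (file.exists(pw_path)) read.csv(pw_path, stringsAsFactors = FALSE) else
        data.frame(target_id = character(0), pathway = character(0))
      panel <- config$panel %||% utils::head(sort(unique(recs$compound_id)), 10)
      avail <- if (!is.null(config$assay_availability)) {
        read.csv(.need_input(config$assay_availability, "assay_availability", config),
                 stringsAsFactors = FALSE)
      } else {
        data.frame(target_id = sort(unique(recs$target_id)), assay_available = TRUE,
                   stringsAsFactors = FALSE)
      }
      rep <- selection_report(recs, known, pw, panel, avail,
                              min_cs = config$min_cs, cs_levels = config$cs_levels)
      out <- .stage_path(config, "report")
      write_atomic(function(tmp) {
        jsonlite::write_json(rep, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }, out)
      out
    },
    "classify-assays" = {
      .need_input(config$assay_table, "assay_table", config)
      tab <- read.csv(config$assay_table, stringsAsFactors = FALSE)
      calls <- classify_assay_results(tab)
      out <- .stage_path(config, "assay_calls")
      write_csv_atomic(as.data.frame(calls), out)
      out
    }
  )
  inputs <- switch(stage,
    "simulate" = character(0),
    "fingerprint" = config$library,
    "calibrate" = character(0),
    "predict" = c(.stage_path(config, "fingerprints"),
                  .stage_path(config, "background"), config$reference_sets),
    "mine" = c(.stage_path(config, "library_std"),
               file.path(config$backend_dir, "compounds.csv")),
    "consensus" = c(vapply(config$matrices, `[[`, character(1), "path"),
                    .stage_path(config, "sea_predictions"), .stage_path(config, "sif")),
    "report" = c(.stage_path(config, "consensus"), .stage_path(config, "sif")),
    "classify-assays" = config$assay_table
  )
  .write_manifest(config, stage, as.list(inputs), as.list(outputs))
  invisible(outputs)
}

#' Run the full pipeline chain
#'
#' Convenience wrapper executing `simulate` (optional), `fingerprint`,
#' `calibrate`, `predict`, `mine` and `consensus` in order.
#'
#' @param config A [run_config()].
#' @param simulate Start from the synthetic fixture set (default `TRUE`).
#' @return Invisibly, the config actually used.
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  stages <- c(if (simulate) "simulate", "fingerprint", "calibrate", "predict",
              "mine", "consensus")
  for (s in stages) run_stage(s, config)
  invisible(config)
}
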