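## Similarity-ensemble target prediction.  A protein target is described by
## the fingerprints of its known ligands; a query ensemble scores against it
## by summing all pairwise Tanimoto coefficients at or above a threshold
## (the raw score).  Raw scores are standardized with a background model
## fitted on random ligand ensembles (mean linear in the set-size product,
## standard deviation a power law), and z-scores are converted to BLAST-style
## E-values through the upper tail of a standard Gumbel law.

#' Construct a target ligand set
#'
#' @param target_id Gene-symbol-like identifier (stored uppercase).
#' @param fps Logical fingerprint matrix, one ligand per row.
#' @param display_name Free-text name (defaults to `target_id`).
#' @return A `target_ligand_set`.
#' @export
target_ligand_set <- function(target_id, fps, display_name = target_id) {
  if (is.vector(fps)) fps <- matrix(fps, nrow = 1)
  stopifnot(nrow(fps) >= 1)
  structure(list(target_id = toupper(target_id), display_name = display_name,
                 ligand_fps = fps, n_ligands = nrow(fps)),
            class = "target_ligand_set")
}

#' Read reference target ligand sets
#'
#' Reads a CSV with columns `target_id,smiles` (one known ligand per row),
#' standardizes the ligands and fingerprints them.
#'
#' @param path CSV file.
#' @param config A [fp_config()].
#' @param kind Which fingerprint feeds the ensemble: `"circular"` (default)
#'   or `"path"`.
#' @return Named list of `target_ligand_set` objects.
#' @export
read_reference_sets <- function(path, config = fp_config(), kind = c("circular", "path")) {
  kind <- match.arg(kind)
  stopifnot_file(path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("target_id", "smiles") %in% names(df))) {
    tf_input_error(sprintf("reference set CSV '%s' must have columns target_id,smiles", path))
  }
  canon <- ob_canonical(df$smiles)
  if (anyNA(canon)) {
    tf_input_error(sprintf("unparseable ligand SMILES in '%s' (rows %s)", path,
                           paste(which(is.na(canon)), collapse = ", ")))
  }
  fps <- fingerprint_set(canon, config = config,
                         ids = paste0(df$target_id, "_", seq_along(canon)))
  mat <- if (kind == "circular") fps$circular else fps$path
  sets <- lapply(split(seq_len(nrow(df)), toupper(df$target_id)), function(rows) {
    target_ligand_set(toupper(df$target_id[rows[1]]), mat[rows, , drop = FALSE])
  })
  sets[order(names(sets))]
}

#' Ensemble raw score
#'
#' Sum of all pairwise query-ligand Tanimoto coefficients at or above the
#' threshold, plus the single largest pairwise coefficient.
#'
#' @param query_fps Logical fingerprint matrix of the query ensemble.
#' @param target A `target_ligand_set` (or a fingerprint matrix).
#' @param threshold Tanimoto cutoff in `[0, 1]`.
#' @return List with elements `raw` and `max_tc`.
#' @export
raw_score <- function(query_fps, target, threshold) {
  tfp <- if (inherits(target, "target_ligand_set")) target$ligand_fps else target
  if (is.vector(query_fps)) query_fps <- matrix(query_fps, nrow = 1)
  if (is.vector(tfp)) tfp <- matrix(tfp, nrow = 1)
  if (nrow(query_fps) == 0 || nrow(tfp) == 0) {
    tf_input_error("raw_score requires non-empty query and target sets")
  }
  tc <- tanimoto_matrix(query_fps, tfp)
  list(raw = sum(tc[tc >= threshold]), max_tc = max(tc))
}

## Draw two disjoint random ensembles from the decoy pool and score them.
.sample_raw <- function(decoy_fps, n, m, threshold) {
  idx <- sample.int(nrow(decoy_fps), n + m)
  raw_score(decoy_fps[idx[seq_len(n)], , drop = FALSE],
            decoy_fps[idx[n + seq_len(m)], , drop = FALSE],
            threshold)$raw
}

#' Fit the random-ensemble background model
#'
#' Draws, for each requested set-size pair, `n_samples` pairs of disjoint
#' random ensembles from a decoy fingerprint pool, computes their raw scores,
#' and fits the mean raw score as a linear function of the set-size product
#' `n*m` and the standard deviation as a power law `a * (n*m)^b`.  Size pairs
#' whose empirical standard deviation is zero are excluded from the power-law
#' fit; if all are zero the standard deviation falls back to a tiny positive
#' floor with a warning, preserving the positive-sd invariant.
#'
#' @param decoy_fps Logical fingerprint matrix of the decoy pool.
#' @param set_sizes List of `c(n, m)` integer pairs.
#' @param threshold Tanimoto cutoff shared with [raw_score()].
#' @param n_samples Random draws per size pair (>= 50).
#' @param seed Integer seed; refits under the same seed and inputs are
#'   bit-identical.
#' @return A `background_model` with elements `tanimoto_threshold`,
#'   `mean_coeffs` (intercept, slope on `n*m`), `sd_coeffs` (`a`, `b`),
#'   `n_random_samples`, `seed`, and the fitted `nm_range`.
#' @export
fit_background <- function(decoy_fps, set_sizes, threshold, n_samples = 100L,
                           seed = 1L) {
  if (n_samples < 50) tf_config_error("n_samples must be >= 50 per size pair")
  max_need <- max(vapply(set_sizes, sum, numeric(1)))
  if (nrow(decoy_fps) < max_need) {
    tf_input_error(sprintf(
      "decoy pool (%d) smaller than largest sampled set-size sum (%d)",
      nrow(decoy_fps), max_need))
  }
  draws <- with_seed(seed, {
    do.call(rbind, lapply(set_sizes, function(sz) {
      raws <- vapply(seq_len(n_samples), function(i) {
        .sample_raw(decoy_fps, sz[1], sz[2], threshold)
      }, numeric(1))
      data.frame(nm = sz[1] * sz[2], raw = raws)
    }))
  })
  stats_by_nm <- do.call(rbind, lapply(split(draws, draws$nm), function(d) {
    data.frame(nm = d$nm[1], mean = mean(d$raw), sd = sd(d$raw))
  }))

  if (nrow(stats_by_nm) >= 2) {
    mfit <- lm(raw ~ nm, data = draws)
    mean_coeffs <- unname(coef(mfit))
  } else {
    mean_coeffs <- c(mean(draws$raw), 0)
  }

  pos <- stats_by_nm[stats_by_nm$sd > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    warning("degenerate background: all size pairs have zero raw-score spread; ",
            "using a minimal positive standard deviation")
    sd_coeffs <- c(1e-8, 0)
  } else if (nrow(pos) == 1) {
    sd_coeffs <- c(pos$sd[1], 0)
  } else {
    sfit <- lm(log(sd) ~ log(nm), data = pos)
    sd_coeffs <- c(exp(unname(coef(sfit)[1])), unname(coef(sfit)[2]))
  }

  bg <- structure(list(
    tanimoto_threshold = threshold,
    mean_coeffs = mean_coeffs,
    sd_coeffs = sd_coeffs,
    n_random_samples = as.integer(n_samples),
    seed = as.integer(seed),
    nm_range = range(stats_by_nm$nm),
    size_stats = stats_by_nm
  ), class = "background_model")

  nm_grid <- seq(bg$nm_range[1], bg$nm_range[2], length.out = 32)
  if (any(bg_sd(bg, nm_grid) <= 0)) {
    tf_computation_error(paste0(
      "degenerate background fit: non-positive sd prediction in [",
      bg$nm_range[1], ", ", bg$nm_range[2], "]; sd coefficients ",
      paste(signif(sd_coeffs, 4), collapse = ", ")))
  }
  bg
}

bg_mean <- function(bg, nm) bg$mean_coeffs[1] + bg$mean_coeffs[2] * nm
bg_sd <- function(bg, nm) bg$sd_coeffs[1] * nm^bg$sd_coeffs[2]

#' Background z-score of a raw score
#'
#' @param raw Raw score from [raw_score()].
#' @param n,m Query and target set sizes.
#' @param bg A `background_model`.
#' @return `(raw - mean(n*m)) / sd(n*m)`; extrapolation beyond the fitted
#'   size range is allowed but reported with a message.
#' @export
z_score <- function(raw, n, m, bg) {
  nm <- n * m
  out_of_range <- nm < bg$nm_range[1] | nm > bg$nm_range[2]
  if (any(out_of_range)) {
    message(sprintf("z_score: extrapolating background beyond fitted range [%s, %s] (nm = %s)",
                    bg$nm_range[1], bg$nm_range[2],
                    paste(unique(nm[out_of_range]), collapse = ", ")))
  }
  (raw - bg_mean(bg, nm)) / bg_sd(bg, nm)
}

#' Extreme-value E-value of a z-score
#'
#' Converts a z-score into the expected number of equal-or-better scores
#' among `n_comparisons` independent comparisons, using the upper-tail
#' probability of the standard Gumbel law matched to zero mean and unit
#' variance: `p(z) = 1 - exp(-exp(-(z*pi/sqrt(6) + gamma)))` with `gamma` the
#' Euler-Mascheroni constant.  The result is clamped to `[0, n_comparisons]`.
#'
#' @param z Numeric vector of z-scores.
#' @param n_comparisons Number of reference targets screened (>= 1).
#' @return Numeric vector of E-values.
#' @export
e_value <- function(z, n_comparisons) {
  if (any(n_comparisons < 1)) tf_config_error("n_comparisons must be >= 1")
  gamma <- -digamma(1)
  p <- 1 - exp(-exp(-(z * pi / sqrt(6) + gamma)))
  pmin(pmax(n_comparisons * p, 0), n_comparisons)
}

#' Predict targets for a query ensemble
#'
#' Scores the query fingerprints against every reference ligand set,
#' standardizes with the background model and assigns E-values with
#' `n_comparisons` equal to the number of reference targets.  A target is
#' flagged `predicted` when its E-value is at or below `e_cutoff`.
#'
#' @param query_fps Logical fingerprint matrix (a single compound is a
#'   one-row matrix).
#' @param references List of `target_ligand_set` objects sharing the query's
#'   fingerprint kind and length.
#' @param bg A `background_model` fitted on decoys of the same fingerprint
#'   kind and length.
#' @param e_cutoff Per-channel inclusion cutoff (default `1e-5`).
#' @param query_id Identifier written to the output.
#' @return Data frame with one row per reference target, columns `query_id`,
#'   `target_id`, `raw`, `z`, `e_value`, `max_tc`, `predicted`, sorted by
#'   ascending E-value (ties: descending `max_tc`, then `target_id`).
#' @export
predict_targets <- function(query_fps, references, bg, e_cutoff = 1e-5,
                            query_id = "query") {
  if (is.vector(query_fps)) query_fps <- matrix(query_fps, nrow = 1)
  ncol_ref <- vapply(references, function(r) ncol(r$ligand_fps), numeric(1))
  if (any(ncol_ref != ncol(query_fps))) {
    tf_input_error("fingerprint kind/length mismatch between query and reference sets")
  }
  rows <- lapply(references, function(ref) {
    rs <- raw_score(query_fps, ref, bg$tanimoto_threshold)
    z <- suppressMessages(z_score(rs$raw, nrow(query_fps), ref$n_ligands, bg))
    data.frame(query_id = query_id, target_id = ref$target_id,
               raw = rs$raw, z = z,
               e_value = e_value(z, length(references)),
               max_tc = rs$max_tc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$predicted <- out$e_value <= e_cutoff
  out <- out[order(out$e_value, -out$max_tc, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict targets for every compound of a fingerprinted library
#'
#' Runs [predict_targets()] with each library compound as a one-member query
#' ensemble and stacks the results; this is the similarity-ensemble channel
#' of the consensus workflow (and, pointed at its own reference sets, the
#' SuperPred-style channel).
#'
#' @param fps A `fingerprint_set` from [fingerprint_library()].
#' @param references,bg,e_cutoff See [predict_targets()].
#' @param kind Fingerprint kind to use (default `"circular"`).
#' @return Long data frame of per-compound predictions.
#' @export
predict_library_targets <- function(fps, references, bg, e_cutoff = 1e-5,
                                    kind = c("circular", "path")) {
  kind <- match.arg(kind)
  mat <- if (kind == "circular") fps$circular else fps$path
  out <- lapply(rownames(mat), function(id) {
    predict_targets(mat[id, , drop = FALSE], references, bg,
                    e_cutoff = e_cutoff, query_id = id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Save / load a background model as JSON
#'
#' @param bg A `background_model`.
#' @param path JSON file path.
#' @return `read_background_model` returns the `background_model`.
#' @export
write_background_model <- function(bg, path) {
  payload <- list(
    tanimoto_threshold = bg$tanimoto_threshold,
    mean_coeffs = bg$mean_coeffs,
    sd_coeffs = bg$sd_coeffs,
    n_random_samples = bg$n_random_samples,
    seed = bg$seed,
    nm_range = bg$nm_range
  )
  write_atomic(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  stopifnot_file(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    tanimoto_threshold = x$tanimoto_threshold,
    mean_coeffs = as.numeric(x$mean_coeffs),
    sd_coeffs = as.numeric(x$sd_coeffs),
    n_random_samples = as.integer(x$n_random_samples),
    seed = as.integer(x$seed),
    nm_range = as.numeric(x$nm_range),
    size_stats = NULL
  ), class = "background_model")
}
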