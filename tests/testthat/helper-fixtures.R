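# Shared helpers: tiny in-code fixtures so no test needs stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal un-standardized library data frame in the package's column layout.
make_library <- function(ids, smiles, source = "unknown") {
  df <- data.frame(
    compound_id = ids, name = ids, smiles_input = smiles,
    smiles_canonical = NA_character_, parent_id = ids,
    n_unspecified_centers = NA_integer_, source = source,
    stringsAsFactors = FALSE
  )
  class(df) <- c("compound_library", class(df))
  df
}

write_temp_csv <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# Hand-crafted bit-set fingerprints over a small universe.
bitvec <- function(on, n = 32) {
  v <- logical(n)
  v[on] <- TRUE
  v
}

# Brute-force ensemble raw score: the independent double-loop oracle.
brute_raw <- function(Q, T, threshold) {
  raw <- 0
  mx <- 0
  for (i in seq_len(nrow(Q))) {
    for (j in seq_len(nrow(T))) {
      tc <- sum(Q[i, ] & T[j, ]) / max(1, sum(Q[i, ] | T[j, ]))
      if (sum(Q[i, ] | T[j, ]) == 0) tc <- 0
      mx <- max(mx, tc)
      if (tc >= threshold) raw <- raw + tc
    }
  }
  list(raw = raw, max_tc = mx)
}

# Random logical fingerprint matrix.
random_fps <- function(n, bits = 64, density = 0.25) {
  matrix(runif(n * bits) < density, nrow = n)
}

# Small fixture-backend directory built in code.
write_backend_dir <- function(compounds, assays, proteins, pathways,
                              dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(compounds, file.path(dir, "compounds.csv"), row.names = FALSE)
  write.csv(assays, file.path(dir, "assays.csv"), row.names = FALSE)
  write.csv(proteins, file.path(dir, "proteins.csv"), row.names = FALSE)
  write.csv(pathways, file.path(dir, "pathways.csv"), row.names = FALSE)
  dir
}

# Boolean prediction matrix from a compact pair list.
bool_matrix <- function(method, pairs, is_anchor = FALSE) {
  entries <- data.frame(
    compound_id = vapply(pairs, `[[`, character(1), 1),
    target_id = vapply(pairs, `[[`, character(1), 2),
    score = 1, stringsAsFactors = FALSE
  )
  m <- prediction_matrix(entries, method, "higher_better", is_anchor = is_anchor)
  m$fit_semantics <- "boolean"
  m
}
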