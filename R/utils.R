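#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm plogis predict rbinom runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so the CLI can map failures to exit codes.
tf_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "tf_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

tf_input_error <- function(msg) tf_stop(msg, "tf_input_error")
tf_config_error <- function(msg) tf_stop(msg, "tf_config_error")
tf_computation_error <- function(msg) tf_stop(msg, "tf_computation_error")

## Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic 31-bit integer hash of an integer vector.  Used for the
## circular-fingerprint feature identifiers; exact double arithmetic is safe
## because 2147483647 * 31 + x < 2^53.
hash_ints <- function(x) {
  h <- 17
  for (v in as.numeric(x)) {
    h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  }
  h
}

## Atomic file write: write to a sibling temp file, then rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp.", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    tf_computation_error(sprintf("could not move temporary file onto '%s'", path))
  }
  invisible(path)
}

## Write a CSV deterministically (no row names, no quoting surprises).
write_csv_atomic <- function(df, path) {
  write_atomic(function(tmp) {
    write.csv(df, tmp, row.names = FALSE, quote = TRUE)
  }, path)
}

stopifnot_file <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    tf_input_error(sprintf("file not found: '%s'", paste(path, collapse = ", ")))
  }
  invisible(path)
}
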