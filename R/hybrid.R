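## Hybrid 2D/3D target prediction: per target, the best path-fingerprint
## Tanimoto (s2D) and best electroshape similarity (s3D) to the target's
## ligands are fused by a logistic model into a binding probability.

#' Train the hybrid logistic model
#'
#' Maximum-likelihood logistic regression of a binary label on
#' `(s2D, s3D)`.  Under complete separation the fit falls back to a
#' ridge-penalized iteratively reweighted least squares fit (penalty 1e-4 on
#' the non-intercept coefficients), reported via a message.  A 2D-only
#' fallback model is trained alongside for queries whose 3D descriptor is
#' unavailable.
#'
#' @param labeled_pairs Data frame with numeric columns `s2d`, `s3d` and a
#'   0/1 (or logical) column `label`; both classes must be present and at
#'   least 20 rows supplied.
#' @param seed Integer recorded with the model; the fit itself is
#'   deterministic given the input order.
#' @param decision_threshold Probability cutoff for the `predicted` flag.
#' @return A `hybrid_model` with coefficients `beta0`, `beta1`, `beta2`,
#'   the 2D-only fallback coefficients, the threshold and the seed.
#' @export
train_hybrid <- function(labeled_pairs, seed = 0L, decision_threshold = 0.5) {
  df <- data.frame(s2d = as.numeric(labeled_pairs$s2d),
                   s3d = as.numeric(labeled_pairs$s3d),
                   label = as.integer(as.logical(labeled_pairs$label)))
  if (nrow(df) < 20) tf_input_error("train_hybrid needs at least 20 labeled pairs")
  if (length(unique(df$label)) < 2) {
    tf_input_error("train_hybrid needs both classes present")
  }
  fit2 <- .fit_logistic(cbind(1, df$s2d, df$s3d), df$label)
  fit1 <- .fit_logistic(cbind(1, df$s2d), df$label)
  structure(list(
    beta0 = fit2$beta[1], beta1 = fit2$beta[2], beta2 = fit2$beta[3],
    fallback_beta = fit1$beta,
    ridge = fit2$ridge || fit1$ridge,
    decision_threshold = decision_threshold,
    train_seed = as.integer(seed),
    descriptor_config = list(path_type = "FP2", charge_scale = 25,
                             set_similarity = "max")
  ), class = "hybrid_model")
}

## Logistic fit via glm; on (quasi-)separation, ridge-penalized IRLS.
.fit_logistic <- function(X, y, penalty = 1e-4) {
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- fit$coefficients
  separated <- !fit$converged || any(abs(beta) > 25) || anyNA(beta)
  if (!separated) {
    return(list(beta = unname(beta), ridge = FALSE))
  }
  message("complete separation detected; falling back to ridge-penalized logistic fit")
  p <- ncol(X)
  pen <- diag(c(0, rep(penalty, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(beta = drop(beta), ridge = TRUE)
}

#' Hybrid prediction for one query compound
#'
#' For each reference target, `s2D` is the maximum path-fingerprint Tanimoto
#' between the query and the target's ligands and `s3D` the maximum
#' electroshape similarity; the model maps them to a probability.  When the
#' query's 3D descriptor (or a target's) is missing, the 2D-only fallback
#' model is used for that row and the event is reported with a message.
#'
#' @param query_path_fp Logical path-fingerprint vector of the query.
#' @param query_es Electroshape vector of the query, or `NULL` if 3D
#'   embedding failed.
#' @param references List of targets, each a list with `target_id`,
#'   `path_fps` (matrix) and `es` (list of electroshape vectors, possibly
#'   empty).
#' @param model A `hybrid_model`.
#' @return Data frame with `target_id`, `s2d`, `s3d`, `probability`,
#'   `predicted`, sorted by descending probability.
#' @export
predict_hybrid <- function(query_path_fp, query_es, references, model) {
  rows <- lapply(references, function(ref) {
    s2 <- max(tanimoto_matrix(matrix(query_path_fp, nrow = 1), ref$path_fps))
    has3d <- !is.null(query_es) && length(ref$es %||% list()) > 0
    if (has3d) {
      s3 <- max(vapply(ref$es, function(e) similarity_3d(query_es, e), numeric(1)))
      p <- plogis(model$beta0 + model$beta1 * s2 + model$beta2 * s3)
    } else {
      message(sprintf("no 3D descriptors for target '%s'; using 2D-only fallback model",
                      ref$target_id))
      s3 <- NA_real_
      p <- plogis(drop(model$fallback_beta %*% c(1, s2)))
    }
    data.frame(target_id = ref$target_id, s2d = s2, s3d = s3,
               probability = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$predicted <- out$probability >= model$decision_threshold
  out <- out[order(-out$probability, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a hybrid model as JSON
#'
#' @param model A `hybrid_model`.
#' @param path JSON file path.
#' @return `read_hybrid_model` returns the `hybrid_model`.
#' @export
write_hybrid_model <- function(model, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(unclass(model), tmp, auto_unbox = TRUE, digits = NA)
  }, path)
  invisible(path)
}

#' @rdname write_hybrid_model
#' @export
read_hybrid_model <- function(path) {
  stopifnot_file(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fallback_beta <- as.numeric(x$fallback_beta)
  structure(x, class = "hybrid_model")
}
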