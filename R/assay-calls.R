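## Classification of percent-inhibition assay readouts into activity calls.
## A measurement is an unambiguous "active" only when the mean inhibition is
## at least 30%, positive, and the relative standard deviation
## (100 * sd / |mean|) is at most 20%; negative means, sub-threshold means
## and noisy replicates are all called inactive.

#' Classify percent-inhibition assay results
#'
#' @param table Data frame with columns `compound_id`, `target_id`, `mean`
#'   (percent inhibition) and `sd` (standard deviation, percent points,
#'   non-negative).
#' @return Data frame (`assay_calls`) with the input columns plus `call`
#'   (`"active"` or `"inactive"`).
#' @export
classify_assay_results <- function(table) {
  need <- c("compound_id", "target_id", "mean", "sd")
  if (!all(need %in% names(table))) {
    tf_input_error(sprintf("assay table must have columns %s",
                           paste(need, collapse = ", ")))
  }
  if (any(table$sd < 0)) tf_input_error("negative standard deviation in assay table")
  rel_sd <- 100 * table$sd / abs(table$mean)
  active <- table$mean >= 30 & table$mean > 0 & rel_sd <= 20
  out <- data.frame(compound_id = as.character(table$compound_id),
                    target_id = toupper(as.character(table$target_id)),
                    mean_inhibition_pct = as.numeric(table$mean),
                    sd_pct = as.numeric(table$sd),
                    call = ifelse(active, "active", "inactive"),
                    stringsAsFactors = FALSE)
  class(out) <- c("assay_calls", class(out))
  out
}

#' Number of experimentally confirmed targets
#'
#' Counts the distinct targets with at least one active call.
#'
#' @param calls An `assay_calls` data frame from [classify_assay_results()].
#' @return Integer count.
#' @export
confirmed_target_count <- function(calls) {
  length(unique(calls$target_id[calls$call == "active"]))
}
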