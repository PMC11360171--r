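#' Consensus prediction across cell-line models
#'
#' The consensus probability of a chemical is the arithmetic mean of the
#' activity probabilities predicted by the available cell-line models; the
#' consensus call is active when the mean is at least 0.5. With two models a
#' majority vote is ill-defined, so the mean-probability rule governs
#' throughout. The consensus always lies between the per-cell-line
#' probabilities and is symmetric in cell-line order.
#'
#' @param probabilities named list of per-cell-line probability vectors, each
#'   named by chemical id (or aligned by position). At least one cell line is
#'   required; every chemical must be present in all supplied vectors.
#' @param threshold decision threshold (default 0.5; ties are active).
#' @return data.frame: `chemical_id`, one `p_<cell line>` column per model,
#'   `p_consensus`, `call`.
#' @examples
#' consensus_probability(list(MCF7 = c(a = 0.6), A549 = c(a = 0.8)))
#' @export
consensus_probability <- function(probabilities, threshold = 0.5) {
  if (!length(probabilities))
    stop("at least one cell-line probability vector is required",
         call. = FALSE)
  mat <- do.call(cbind, lapply(probabilities, as.numeric))
  if (any(!is.finite(mat)) || min(mat) < 0 || max(mat) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  ids <- names(probabilities[[1]])
  for (p in probabilities[-1])
    if (!identical(names(p), ids))
      stop("cell-line probability vectors must cover the same chemicals",
           call. = FALSE)
  if (is.null(ids)) ids <- sprintf("chem%d", seq_len(nrow(mat)))
  p_cons <- rowMeans(mat)
  out <- data.frame(chemical_id = ids)
  for (cl in names(probabilities))
    out[[paste0("p_", tolower(cl))]] <- as.numeric(probabilities[[cl]])
  out$p_consensus <- p_cons
  out$call <- ifelse(p_cons >= threshold, "active", "inactive")
  out
}

#' Evaluate a consensus prediction on the shared validation set
#'
#' @param predictions data.frame from [consensus_probability()].
#' @param labels binary labels aligned with `predictions$chemical_id` (or a
#'   vector named by chemical id).
#' @return A [metric_set()] computed at threshold 0.5, with AUC from the
#'   consensus probabilities.
#' @export
evaluate_consensus <- function(predictions, labels) {
  if (!is.null(names(labels)))
    labels <- labels[predictions$chemical_id]
  if (anyNA(labels) || length(labels) != nrow(predictions))
    stop("a label is required for every consensus chemical", call. = FALSE)
  p <- predictions$p_consensus
  metric_set(confusion(p, labels), p, labels)
}
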