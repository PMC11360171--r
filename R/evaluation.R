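#' Confusion matrix from predicted probabilities
#'
#' A chemical is called active when its predicted probability is at least
#' `threshold` (ties go to active).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param labels binary labels (1/"active" = active).
#' @param threshold decision threshold, default 0.5.
#' @return A `confusion_matrix` list with integer counts `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(probabilities, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  p <- as.numeric(probabilities)
  if (length(p) != length(y))
    stop("probabilities and labels differ in length", call. = FALSE)
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  pred <- as.integer(p >= threshold)
  structure(list(tp = sum(pred == 1L & y == 1L),
                 tn = sum(pred == 0L & y == 0L),
                 fp = sum(pred == 1L & y == 0L),
                 fn = sum(pred == 0L & y == 1L)),
            class = "confusion_matrix")
}

#' Reconstruct a confusion matrix from class counts and printed SE/SP
#'
#' Given the number of active and inactive chemicals in an evaluation set and
#' a reported sensitivity and specificity (typically rounded to three
#' decimals), recovers the integer counts by rounding `se * n_active` and
#' `sp * n_inactive` to the nearest integer. Reported balanced accuracy and
#' MCC values can then be recomputed exactly from the counts.
#'
#' @param n_active,n_inactive class counts of the evaluation set.
#' @param se,sp reported sensitivity and specificity.
#' @return A `confusion_matrix`.
#' @examples
#' reconstruct_confusion(100, 191, se = 0.570, sp = 0.880)
#' @export
reconstruct_confusion <- function(n_active, n_inactive, se, sp) {
  tp <- round(se * n_active)
  tn <- round(sp * n_inactive)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(n_inactive - tn),
                 fn = as.integer(n_active - tp)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d | TN=%d FP=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Computes sensitivity `SE = TP / (TP + FN)`, specificity
#' `SP = TN / (TN + FP)`, balanced accuracy `BA = (SE + SP) / 2`, the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' and, when probabilities are supplied, the ROC AUC. SE/SP are `NA`
#' (undefined, not 0) when their class is absent; MCC is 0 by convention when
#' any denominator factor vanishes.
#'
#' @param cm a `confusion_matrix`.
#' @param probabilities,labels optional, to compute AUC via [roc_auc()].
#' @return A `metric_set` list: `se`, `sp`, `ba`, `mcc`, `auc`.
#' @examples
#' metric_set(reconstruct_confusion(100, 191, 0.570, 0.880))
#' @export
metric_set <- function(cm, probabilities = NULL, labels = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  se <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  sp <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  ba <- (se + sp) / 2
  denom <- prod(sqrt(c(cm$tp + cm$fp, cm$tp + cm$fn,
                       cm$tn + cm$fp, cm$tn + cm$fn)))
  mcc <- if (denom == 0) 0 else
    (cm$tp * cm$tn - cm$fp * cm$fn) / denom
  auc <- if (!is.null(probabilities)) roc_auc(probabilities, labels)
         else NA_real_
  structure(list(se = se, sp = sp, ba = ba, mcc = mcc, auc = auc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> SE=%.3f SP=%.3f BA=%.3f MCC=%.3f AUC=%s\n",
              x$se, x$sp, x$ba, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney rank statistic, which equals the
#' trapezoidal area under the ROC curve and handles tied scores by midranks.
#'
#' @param probabilities numeric scores (higher = more active).
#' @param labels binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as_binary_labels(labels)
  p <- as.numeric(probabilities)
  if (length(p) != length(y))
    stop("probabilities and labels differ in length", call. = FALSE)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(p)  # midranks for ties
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Aggregate metric sets across cross-validation folds
#'
#' @param metric_sets list of `metric_set` objects (e.g. one per outer fold).
#' @return data.frame with one row per metric (`se`, `sp`, `ba`, `mcc`,
#'   `auc`): arithmetic `mean` and sample `sd` (0 for a single fold),
#'   computed over folds where the metric is defined.
#' @export
aggregate_cv <- function(metric_sets) {
  stopifnot(length(metric_sets) >= 1L)
  metrics <- c("se", "sp", "ba", "mcc", "auc")
  vals <- sapply(metrics, function(m)
    vapply(metric_sets, function(s) s[[m]], numeric(1)))
  vals <- matrix(vals, nrow = length(metric_sets),
                 dimnames = list(NULL, metrics))
  data.frame(
    metric = metrics,
    mean = apply(vals, 2L, mean, na.rm = TRUE),
    sd = apply(vals, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else sd(v)
    }),
    row.names = NULL)
}
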