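#' Cosine similarity between two expression profiles
#'
#' `dot(u, v) / (|u| |v|)`, in \[-1, 1\]. Signed z-score profiles can be
#' anti-correlated, so negative similarities are possible and are kept as-is.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("profiles differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("zero-norm profile has no direction", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# Row-normalize to unit norm; cosine similarity matrix = tcrossprod.
unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-norm profile has no direction", call. = FALSE)
  X / nrm
}

#' Mean similarity to the k most similar training chemicals
#'
#' For each query profile, the mean cosine similarity of its `k` most similar
#' training profiles. When `exclude_self = TRUE` a query identical to a
#' training profile row (matched by row name) does not count itself among its
#' neighbours — used when the queries are the training chemicals themselves.
#'
#' @param query numeric matrix of query profiles (rows), or a single profile
#'   vector.
#' @param training numeric matrix of training profiles with at least `k`
#'   rows.
#' @param k number of neighbours (default 3).
#' @param exclude_self drop the training row with the same name as the query
#'   row.
#' @return numeric vector of mean top-k similarities, one per query row.
#' @export
mean_topk_similarity <- function(query, training, k = 3L, exclude_self = FALSE) {
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  training <- as.matrix(training)
  need <- k + as.integer(exclude_self)
  if (nrow(training) < need)
    stop("training set smaller than k", call. = FALSE)
  S <- tcrossprod(unit_rows(as.matrix(query)), unit_rows(training))
  vapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    if (exclude_self && !is.null(rownames(query)) &&
        !is.null(rownames(training))) {
      drop <- which(rownames(training) == rownames(query)[i])
      if (length(drop)) s <- s[-drop[1]]
    }
    mean(sort(s, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
}

#' Applicability-domain threshold from the training set
#'
#' Each training chemical's mean cosine similarity to its `k` nearest
#' training neighbours (itself excluded) is computed; with `<y>` their mean
#' and `sigma` their standard deviation, the domain threshold is
#' `Dc = <y> - Z * sigma`. `Z` (default 0.5) trades coverage against
#' reliability. Because similarity (not distance) is thresholded, `<y>` is
#' adjusted downward: queries *more* similar than `Dc` are in-domain.
#'
#' @param training numeric matrix of training profiles (rownames = chemical
#'   ids); at least `k + 1` rows.
#' @param Z significance multiplier (default 0.5).
#' @param k neighbours (default 3).
#' @return list: `Dc`, `y_mean`, `y_sd`, `k`, `Z`.
#' @examples
#' # <y> = 0.6, sigma = 0.2, Z = 0.5  =>  Dc = 0.5
#' @export
domain_threshold <- function(training, Z = 0.5, k = 3L) {
  training <- as.matrix(training)
  if (nrow(training) < k + 1L)
    stop("need at least k + 1 training chemicals", call. = FALSE)
  if (is.null(rownames(training)))
    rownames(training) <- sprintf("t%d", seq_len(nrow(training)))
  y <- mean_topk_similarity(training, training, k = k, exclude_self = TRUE)
  y_sd <- sd(y)
  if (y_sd == 0)
    warning("degenerate training set: all self-similarities equal; Dc = <y>")
  list(Dc = mean(y) - Z * y_sd, y_mean = mean(y), y_sd = y_sd,
       k = as.integer(k), Z = Z)
}

#' Assess validation chemicals against the applicability domain
#'
#' @param query matrix of query profiles (rownames = chemical ids).
#' @param training matrix of training profiles.
#' @param Z,k as in [domain_threshold()].
#' @return data.frame: `chemical_id`, `mean_top3_cosine`, `Dc`, `in_domain`
#'   (similarity >= Dc).
#' @export
assess_domain <- function(query, training, Z = 0.5, k = 3L) {
  thr <- domain_threshold(training, Z = Z, k = k)
  query <- as.matrix(query)
  sim <- mean_topk_similarity(query, training, k = k)
  ids <- rownames(query)
  if (is.null(ids)) ids <- sprintf("q%d", seq_len(nrow(query)))
  data.frame(chemical_id = ids, mean_top3_cosine = sim, Dc = thr$Dc,
             in_domain = sim >= thr$Dc)
}

#' Performance/coverage trade-off across similarity thresholds
#'
#' At each threshold, chemicals whose mean top-k similarity is at least the
#' threshold are retained; balanced accuracy is recomputed on the retained
#' chemicals and coverage is the retained fraction. Metrics are `NA`
#' (undefined) when a retained class is empty. Coverage is non-increasing in
#' the threshold.
#'
#' @param similarities per-chemical mean top-k similarity to the training
#'   set.
#' @param probabilities predicted activity probabilities, aligned.
#' @param labels binary labels, aligned.
#' @param thresholds similarity thresholds (default `seq(0, 1, by = 0.05)`).
#' @return data.frame: `threshold`, `balanced_accuracy`, `coverage`,
#'   `n_retained`.
#' @export
coverage_curve <- function(similarities, probabilities, labels,
                           thresholds = seq(0, 1, by = 0.05)) {
  y <- as_binary_labels(labels)
  stopifnot(length(similarities) == length(y),
            length(probabilities) == length(y))
  rows <- lapply(thresholds, function(t) {
    keep <- similarities >= t
    ba <- if (any(keep)) {
      ms <- metric_set(confusion(probabilities[keep], y[keep]))
      ms$ba
    } else NA_real_
    data.frame(threshold = t, balanced_accuracy = ba,
               coverage = mean(keep), n_retained = sum(keep))
  })
  do.call(rbind, rows)
}
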