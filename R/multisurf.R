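#' MultiSURF relief-based feature weighting
#'
#' MultiSURF scores each feature by contrasting its values between
#' neighbouring instances of equal and different class. For every target
#' instance the distance threshold is the mean of its pairwise distances to
#' all other instances, and a dead-band of half the standard deviation of
#' those distances excludes ambiguous neighbours: instance `j` is a *near*
#' neighbour of `i` when `d_ij < T_i - D_i`. Near neighbours of the same
#' class (hits) decrease a feature's weight by its normalized value
#' difference; near neighbours of a different class (misses) increase it,
#' weighted by the class priors. Informative features accumulate positive
#' weight, label-independent features drift to zero or below.
#'
#' @name multisurf
NULL

# Range-normalize columns; zero-range (constant) columns are mapped to 0 so
# they contribute neither distance nor weight.
range_normalize <- function(X) {
  rng <- apply(X, 2L, function(col) diff(range(col)))
  mins <- apply(X, 2L, min)
  Xn <- sweep(X, 2L, mins, "-")
  nz <- rng > 0
  Xn[, nz] <- sweep(Xn[, nz, drop = FALSE], 2L, rng[nz], "/")
  Xn[, !nz] <- 0
  Xn
}

#' Pairwise Manhattan distances on range-normalized features
#'
#' @param X numeric matrix, instances in rows; all values finite.
#' @return symmetric distance matrix with zero diagonal. Distances are sums
#'   over features of `|x_if - x_jf| / range_f` (constant features
#'   contribute 0).
#' @rdname multisurf
#' @export
pairwise_distances <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 1L)
    stop("need at least 2 instances and 1 feature", call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite feature values", call. = FALSE)
  as.matrix(stats::dist(range_normalize(X), method = "manhattan"))
}

#' Near-neighbour sets under the mean-distance threshold with dead band
#'
#' @param distances distance matrix from [pairwise_distances()].
#' @param target integer index of the target instance; if `NULL`, near sets
#'   are returned for every instance.
#' @return integer vector of near-neighbour indices for `target`, or a list
#'   of such vectors for all instances.
#' @rdname multisurf
#' @export
neighbor_sets <- function(distances, target = NULL) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3L)
    stop("need at least 3 instances to define neighbourhoods", call. = FALSE)
  one <- function(i) {
    d <- D[i, -i]
    thr <- mean(d) - sd(d) / 2
    unname(which(D[i, ] < thr & seq_len(n) != i))
  }
  if (!is.null(target)) one(target) else lapply(seq_len(n), one)
}

#' Compute MultiSURF feature weights
#'
#' @param X numeric feature matrix (instances x features); column names are
#'   used as feature ids.
#' @param y binary label vector (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @return A `feature_weights` object: named numeric `weights` (one per
#'   feature, averaged over instances and neighbour counts),
#'   `n_instances_used`, `distance_metric`.
#' @rdname multisurf
#' @export
multisurf_weights <- function(X, y) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(y) != nrow(X))
    stop("one label per instance is required", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  n <- nrow(X)
  D <- pairwise_distances(X)
  near <- neighbor_sets(D)
  Xn <- range_normalize(X)
  prior <- table(factor(y, levels = c(0, 1))) / n
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    nb <- near[[i]]
    if (!length(nb)) next
    diffs <- abs(Xn[nb, , drop = FALSE] -
                   matrix(Xn[i, ], length(nb), ncol(Xn), byrow = TRUE))
    hits <- y[nb] == y[i]
    if (any(hits))
      W <- W - colMeans(diffs[hits, , drop = FALSE])
    if (any(!hits)) {
      other <- as.character(1 - y[i])
      coef <- prior[[other]] / (1 - prior[[as.character(y[i])]])
      W <- W + coef * colMeans(diffs[!hits, , drop = FALSE])
    }
  }
  structure(list(weights = setNames(W / n, colnames(X)),
                 n_instances_used = n,
                 distance_metric = "manhattan/range-normalized"),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> %d features, %d instances, %s distance; %d selected (> 0)\n",
              length(x$weights), x$n_instances_used, x$distance_metric,
              sum(x$weights > 0)))
  invisible(x)
}

#' Retain features with strictly positive weight
#'
#' @param weights a `feature_weights` object (or named numeric vector).
#' @return character vector of feature ids with weight > 0, in decreasing
#'   weight order (ties keep catalog order).
#' @rdname multisurf
#' @export
select_features <- function(weights) {
  w <- if (inherits(weights, "feature_weights")) weights$weights else weights
  w <- w[w > 0]
  names(w)[order(-w)]  # order() is stable: ties keep catalog order
}

#' Write feature weights as TSV (`gene_id`, `weight`, `selected`)
#'
#' @param weights a `feature_weights` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_weights <- function(weights, path) {
  w <- weights$weights
  data.table::fwrite(
    data.frame(gene_id = names(w), weight = unname(w),
               selected = as.integer(w > 0)),
    path, sep = "\t")
  invisible(path)
}

# Coerce labels to 0/1 integers.
as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) {
    if (!all(y %in% c("active", "inactive")))
      stop("character labels must be 'active'/'inactive'", call. = FALSE)
    y <- as.integer(y == "active")
  }
  if (!all(y %in% c(0, 1)))
    stop("labels must be binary", call. = FALSE)
  as.integer(y)
}
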