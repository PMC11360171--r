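# Independent reference implementations and small fixture builders.

# Literal double-loop MultiSURF reference: scalar loops over instances and
# features, raw-value diffs divided by the feature range. Deliberately naive
# and separate from the vectorized package implementation.
multisurf_reference <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) max(col) - min(col))
  dff <- function(f, i, j) if (rng[f] == 0) 0 else abs(X[i, f] - X[j, f]) / rng[f]
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (f in 1:p) s <- s + dff(f, i, j)
    d[i, j] <- s
  }
  priors <- c(mean(y == 0), mean(y == 1))
  W <- numeric(p)
  for (i in 1:n) {
    di <- d[i, -i]
    thr <- mean(di) - sd(di) / 2
    nb <- setdiff(which(d[i, ] < thr), i)
    if (!length(nb)) next
    hits <- nb[y[nb] == y[i]]
    miss <- nb[y[nb] != y[i]]
    coef <- priors[(1 - y[i]) + 1] / (1 - priors[y[i] + 1])
    for (f in 1:p) {
      h <- if (length(hits)) mean(vapply(hits, function(j) dff(f, i, j), 0)) else 0
      m <- if (length(miss)) mean(vapply(miss, function(j) dff(f, i, j), 0)) else 0
      W[f] <- W[f] + coef * m - h
    }
  }
  W / n
}

# Exhaustive near-neighbour reference for one target.
near_reference <- function(D, i) {
  di <- D[i, -i]
  thr <- mean(di) - sd(di) / 2
  setdiff(which(D[i, ] < thr), i)
}

# A small labelled feature matrix with `n_signal` planted features shifted in
# the positive class.
planted_matrix <- function(n, p, n_signal, shift, prev = 0.4, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, prev)
    if (sum(y) < 2) y[1:2] <- 1L
    if (sum(1 - y) < 2) y[(n - 1):n] <- 0L
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%03d", 1:p)))
    if (n_signal > 0) X[y == 1, 1:n_signal] <- X[y == 1, 1:n_signal] + shift
    list(X = X, y = y, signal = colnames(X)[seq_len(n_signal)])
  })
}

# A deduplicated two-cell-line cohort with resolved labels and a shared
# validation split, ready for modelling.
assembled_cohort <- function(n = 120, p = 40, n_informative = 6, shift = 2.5,
                             n_validation = 30, seed = 7, ...) {
  cfg <- synth_config(n_chemicals = n, n_landmark = p,
                      n_informative = n_informative, effect_shift = shift,
                      seed = seed, ...)
  co <- generate_cohort(cfg)
  act <- resolve_activity_conflicts(co$activity)
  sigs <- lapply(co$signatures, dedupe_profiles_by_tas)
  split <- make_split(sigs, act, n_validation, seed = seed + 1)
  list(datasets = lapply(sigs, assemble_dataset, activity = act,
                         split = split),
       truth = co$truth, split = split, activity = act, signatures = sigs)
}

published_metrics <- function() {
  read.delim(system.file("extdata", "published_validation_metrics.tsv",
                         package = "qgexar"))
}
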