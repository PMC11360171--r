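#' Declare a classifier for the model zoo
#'
#' A `model_spec` names an algorithm family, a hyperparameter grid to search,
#' and whether class weighting balances the fit. Shipped families:
#' `gradient_boosting` (xgboost), `random_forest` (ranger), `svm_sgd`
#' (linear-kernel SVM), `logistic_elasticnet` (glmnet) and `dense_nn`
#' (single-hidden-layer perceptron). `external` plugs in any classifier via
#' user-supplied `fit(x, y, params, weights)` and `predict_prob(model, x)`
#' functions, the extension point for AutoML-style candidates.
#'
#' @param algorithm one of `"gradient_boosting"`, `"random_forest"`,
#'   `"svm_sgd"`, `"logistic_elasticnet"`, `"dense_nn"`, `"external"`.
#' @param grid named list of candidate hyperparameter values; crossed with
#'   `expand.grid`. `NULL` uses a small default grid.
#' @param balanced apply inverse-class-frequency weights (default `TRUE`).
#' @param label display label; defaults to the algorithm name.
#' @param fit,predict_prob backend functions, required when
#'   `algorithm = "external"`.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm, grid = NULL, balanced = TRUE,
                       label = algorithm, fit = NULL, predict_prob = NULL) {
  known <- c("gradient_boosting", "random_forest", "svm_sgd",
             "logistic_elasticnet", "dense_nn", "external")
  if (!algorithm %in% known)
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  if (algorithm == "external" && (is.null(fit) || is.null(predict_prob)))
    stop("external models need fit and predict_prob functions", call. = FALSE)
  structure(list(algorithm = algorithm, grid = grid, balanced = balanced,
                 label = label, fit = fit, predict_prob = predict_prob),
            class = "model_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    gradient_boosting = list(nrounds = c(50L, 150L), max_depth = c(2L, 4L),
                             eta = 0.1),
    random_forest = list(num_trees = 300L, min_node_size = c(1L, 5L)),
    svm_sgd = list(cost = c(0.1, 1)),
    logistic_elasticnet = list(alpha = c(0.25, 0.75),
                               lambda = c(0.01, 0.1)),
    dense_nn = list(size = c(4L, 8L), decay = 0.1),
    external = list(default = TRUE))
}

#' The default class-weighted model zoo
#'
#' One `model_spec` per shipped family, in the tie-breaking order used by
#' [select_best_model()].
#'
#' @return named list of [model_spec()] objects.
#' @export
default_model_zoo <- function() {
  algos <- c("gradient_boosting", "random_forest", "svm_sgd",
             "logistic_elasticnet", "dense_nn")
  setNames(lapply(algos, model_spec), algos)
}

# Inverse-class-frequency weights on the fit partition: w_c = n / (2 n_c).
balanced_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * tab)
  as.numeric(w[as.character(y)])
}

# Deterministic per-stage seed derived from a run seed and a stage label.
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Stratified k-fold assignment; every fold holds both classes.
make_folds <- function(y, k, seed) {
  y <- as_binary_labels(y)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (min(table(factor(y, levels = c(0, 1)))) < k)
    stop("stratification error: fewer than k = ", k,
         " instances in a class", call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit one backend at one grid point; returns an object predict_model() accepts.
fit_model <- function(spec, params, x, y, seed) {
  w <- if (spec$balanced) balanced_weights(y) else rep(1, length(y))
  x <- as.matrix(x)
  set.seed(seed)
  model <- switch(spec$algorithm,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = params$max_depth,
                      eta = params$eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    random_forest = {
      tab <- table(factor(y, levels = c(0, 1)))
      cw <- if (spec$balanced) as.numeric(length(y) / (2 * tab)) else c(1, 1)
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = params$num_trees,
                     min.node.size = params$min_node_size,
                     class.weights = cw, seed = seed, num.threads = 1)
    },
    svm_sgd = {
      cw <- if (spec$balanced) {
        tab <- table(factor(y, levels = c(0, 1)))
        setNames(as.numeric(length(y) / (2 * tab)), c("0", "1"))
      } else NULL
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = params$cost, class.weights = cw, probability = TRUE)
    },
    logistic_elasticnet = {
      xg <- pad_single_column(x)
      fit <- glmnet::glmnet(xg, y, family = "binomial", alpha = params$alpha,
                            lambda = params$lambda, weights = w)
      list(fit = fit, lambda = params$lambda, padded = ncol(xg) != ncol(x))
    },
    dense_nn = nnet::nnet(x, y, weights = w, size = params$size,
                          decay = params$decay, maxit = 200, entropy = TRUE,
                          trace = FALSE, MaxNWts = 50000),
    external = spec$fit(x, y, params, w))
  structure(list(backend = model, spec = spec, params = params,
                 features = colnames(x)),
            class = "qgexar_model")
}

# glmnet needs >= 2 columns; pad a zero column when one feature survives
# selection (its coefficient is irrelevant to predictions).
pad_single_column <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `.pad` = 0)
}

# Predicted probability of the active class.
predict_model <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  spec <- model$spec
  p <- switch(spec$algorithm,
    gradient_boosting =
      predict(model$backend, xgboost::xgb.DMatrix(x, nthread = 1)),
    random_forest = predict(model$backend, data = x,
                            num.threads = 1)$predictions[, "1"],
    svm_sgd = {
      pr <- predict(model$backend, x, probability = TRUE)
      probs <- attr(pr, "probabilities")
      if (!is.null(probs) && "1" %in% colnames(probs)) probs[, "1"]
      else stats::plogis(attr(predict(model$backend, x,
                                      decision.values = TRUE),
                              "decision.values")[, 1])
    },
    logistic_elasticnet = {
      xg <- if (model$backend$padded) pad_single_column(x) else x
      as.numeric(predict(model$backend$fit, xg, s = model$backend$lambda,
                         type = "response"))
    },
    dense_nn = as.numeric(predict(model$backend, x)),
    external = spec$predict_prob(model$backend, x))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Inner grid search by 5-fold cross-validated balanced accuracy
#'
#' Evaluates every grid point of a model spec by stratified k-fold
#' cross-validation on the training fold and returns the point with the
#' highest mean balanced accuracy; ties are broken by grid order.
#'
#' @param x,y training-fold features and binary labels (both classes
#'   required).
#' @param spec a [model_spec()].
#' @param k inner folds (default 5).
#' @param seed integer seed.
#' @return list: `params` (best grid point as a one-row list), `mean_ba`,
#'   `grid_ba` (mean BA per grid point, in grid order).
#' @export
inner_grid_search <- function(x, y, spec, k = 5L, seed = 1L) {
  y <- as_binary_labels(y)
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1L)
    return(list(params = as.list(grid[1L, , drop = FALSE]), mean_ba = NA_real_,
                grid_ba = NA_real_))
  folds <- make_folds(y, k, stage_seed(seed, "inner_folds"))
  grid_ba <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    bas <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_model(spec, params, x[tr, , drop = FALSE], y[tr],
                     stage_seed(seed, paste0("inner_fit", g, "_", f)))
      p <- predict_model(m, x[!tr, , drop = FALSE])
      metric_set(confusion(p, y[!tr]))$ba
    }, numeric(1))
    mean(bas)
  }, numeric(1))
  best <- which.max(grid_ba)  # first maximum: grid-order tie rule
  list(params = as.list(grid[best, , drop = FALSE]), mean_ba = grid_ba[best],
       grid_ba = grid_ba)
}

#' Outer repeated cross-validation of one model spec
#'
#' The protocol's model-assessment loop: `repeats` repetitions of stratified
#' k-fold cross-validation. Within each outer fold, feature selection (when a
#' selector is given) and the inner grid search run on the fold's training
#' part only, so no held-out information leaks into selection or tuning; the
#' held-out part is scored with sensitivity, specificity, balanced accuracy,
#' MCC and AUC. At the protocol scale (10 repeats of 5 folds) the report
#' holds 50 fold entries.
#'
#' @param x,y assembled training features and binary labels.
#' @param spec a [model_spec()].
#' @param repeats,k outer repetitions and folds (protocol scale: 10 and 5).
#' @param feature_selector `NULL`, or a `function(x, y)` returning the
#'   feature ids to keep (e.g. [multisurf_selector()]); an empty selection
#'   falls back to all features.
#' @param inner_k inner grid-search folds.
#' @param seed integer seed; the full report is reproducible from it.
#' @return A `cv_report`: `label`, `spec`, `folds` (data.frame with one row
#'   per repeat x fold: metrics, chosen hyperparameters, n selected
#'   features), `aggregate` (mean/SD per metric via [aggregate_cv()]).
#' @export
outer_repeated_cv <- function(x, y, spec, repeats = 10L, k = 5L,
                              feature_selector = NULL, inner_k = 5L,
                              seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  rows <- list()
  sets <- list()
  for (r in seq_len(repeats)) {
    folds <- make_folds(y, k, stage_seed(seed, paste0("outer", r)))
    for (f in seq_len(k)) {
      tr <- folds != f
      xt <- x[tr, , drop = FALSE]
      keep <- colnames(x)
      if (!is.null(feature_selector)) {
        sel <- feature_selector(xt, y[tr])
        if (length(sel)) keep <- sel
      }
      search <- inner_grid_search(xt[, keep, drop = FALSE], y[tr], spec,
                                  k = inner_k,
                                  seed = stage_seed(seed, paste0("in", r, f)))
      m <- fit_model(spec, search$params, xt[, keep, drop = FALSE], y[tr],
                     stage_seed(seed, paste0("fit", r, "_", f)))
      p <- predict_model(m, x[!tr, , drop = FALSE])
      ms <- metric_set(confusion(p, y[!tr]), p, y[!tr])
      sets <- c(sets, list(ms))
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, se = ms$se, sp = ms$sp, ba = ms$ba, mcc = ms$mcc,
        auc = ms$auc, n_features = length(keep),
        params = paste(names(search$params), unlist(search$params),
                       sep = "=", collapse = ";"))
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(label = spec$label, spec = spec, folds = folds_df,
                 aggregate = aggregate_cv(sets)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  agg <- x$aggregate
  cat(sprintf("<cv_report> %s: %d folds; BA = %.3f +/- %.3f\n",
              x$label, nrow(x$folds), agg$mean[agg$metric == "ba"],
              agg$sd[agg$metric == "ba"]))
  invisible(x)
}

# Mean outer-CV balanced accuracy of a report.
cv_mean_ba <- function(report) {
  agg <- report$aggregate
  agg$mean[agg$metric == "ba"]
}

#' Select the best model by mean cross-validated balanced accuracy
#'
#' @param reports list of `cv_report` objects (one per candidate algorithm).
#' @return the winning report's [model_spec()], with attributes
#'   `mean_ba` and `label`; ties go to the earlier report.
#' @export
select_best_model <- function(reports) {
  stopifnot(length(reports) >= 1L)
  bas <- vapply(reports, cv_mean_ba, numeric(1))
  best <- which.max(bas)
  spec <- reports[[best]]$spec
  attr(spec, "mean_ba") <- bas[best]
  spec
}

#' Fit the selected model on the full training set and predict validation
#' chemicals
#'
#' Feature selection and the hyperparameter grid search are re-run on the
#' complete training set (never on validation data), the model is fit with
#' class weights, and the unseen validation chemicals are scored.
#'
#' @param x_train,y_train full training set.
#' @param spec winning [model_spec()].
#' @param x_valid validation features (same gene columns as training).
#' @param feature_selector optional selector, as in [outer_repeated_cv()].
#' @param inner_k inner grid-search folds.
#' @param seed integer seed.
#' @return list: `probabilities` (named by validation rownames when present),
#'   `model`, `selected_features`, `params`.
#' @export
fit_final_and_predict <- function(x_train, y_train, spec, x_valid,
                                  feature_selector = NULL, inner_k = 5L,
                                  seed = 1L) {
  x_train <- as.matrix(x_train)
  y_train <- as_binary_labels(y_train)
  if (is.null(colnames(x_train)))
    colnames(x_train) <- sprintf("f%03d", seq_len(ncol(x_train)))
  x_valid <- as.matrix(x_valid)
  if (nrow(x_valid) > 0 && !all(colnames(x_train) %in% colnames(x_valid)))
    stop("schema error: validation genes do not cover the training genes",
         call. = FALSE)
  keep <- colnames(x_train)
  if (!is.null(feature_selector)) {
    sel <- feature_selector(x_train, y_train)
    if (length(sel)) keep <- sel
  }
  search <- inner_grid_search(x_train[, keep, drop = FALSE], y_train, spec,
                              k = inner_k, seed = stage_seed(seed, "final_in"))
  model <- fit_model(spec, search$params, x_train[, keep, drop = FALSE],
                     y_train, stage_seed(seed, "final_fit"))
  p <- if (nrow(x_valid) == 0) numeric() else
    setNames(predict_model(model, x_valid), rownames(x_valid))
  list(probabilities = p, model = model, selected_features = keep,
       params = search$params)
}

#' A MultiSURF feature selector for cross-validation loops
#'
#' Returns a `function(x, y)` applying [multisurf_weights()] and
#' [select_features()] to the fold's training part, for use as the
#' `feature_selector` argument of [outer_repeated_cv()] and
#' [fit_final_and_predict()].
#'
#' @return a selector function.
#' @export
multisurf_selector <- function() {
  function(x, y) select_features(multisurf_weights(x, y))
}
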