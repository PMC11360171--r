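test_that("stratified folds keep both classes and reject impossible k", {
  y <- c(rep(0, 20), rep(1, 8))
  folds <- qgexar:::make_folds(y, 4, seed = 1)
  for (f in 1:4) expect_setequal(unique(y[folds == f]), c(0, 1))
  expect_error(qgexar:::make_folds(y, 10, seed = 1), "stratification error")
})

test_that("inner grid search prefers working settings and honours tie order", {
  fx <- planted_matrix(60, 8, n_signal = 3, shift = 3, seed = 2)
  # a one-point grid is returned without search
  one <- inner_grid_search(fx$X, fx$y,
                           model_spec("logistic_elasticnet",
                                      grid = list(alpha = 0.5, lambda = 0.05)))
  expect_equal(one$params$lambda, 0.05)
  # a degenerate penalty (intercept-only model) loses to a working one on
  # separable data
  spec <- model_spec("logistic_elasticnet",
                     grid = list(alpha = 0.5, lambda = c(1e3, 0.05)))
  best <- inner_grid_search(fx$X, fx$y, spec, k = 3, seed = 4)
  expect_equal(best$params$lambda, 0.05)
  expect_gt(best$mean_ba, 0.8)
  # duplicated grid points: the first in declared order wins
  dup <- model_spec("logistic_elasticnet",
                    grid = list(alpha = c(0.5, 0.5), lambda = 0.05))
  tie <- inner_grid_search(fx$X, fx$y, dup, k = 3, seed = 4)
  expect_equal(unname(unlist(tie$params)), c(0.5, 0.05))
  expect_equal(tie$grid_ba[1], tie$grid_ba[2])
})

test_that("outer repeated CV separates a strong planted signal", {
  fx <- planted_matrix(120, 15, n_signal = 4, shift = 3, seed = 6)
  rep1 <- outer_repeated_cv(fx$X, fx$y,
                            model_spec("logistic_elasticnet",
                                       grid = list(alpha = 0.5, lambda = 0.05)),
                            repeats = 1, k = 3, seed = 9)
  expect_gt(qgexar:::cv_mean_ba(rep1), 0.95)
  expect_equal(nrow(rep1$folds), 3)
})

test_that("outer CV is deterministic under a fixed seed", {
  fx <- planted_matrix(40, 6, n_signal = 2, shift = 2, seed = 3)
  spec <- model_spec("random_forest",
                     grid = list(num_trees = 50L, min_node_size = 1L))
  r1 <- outer_repeated_cv(fx$X, fx$y, spec, repeats = 1, k = 2, seed = 5)
  r2 <- outer_repeated_cv(fx$X, fx$y, spec, repeats = 1, k = 2, seed = 5)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$aggregate, r2$aggregate)
})

test_that("label-shuffled data yields chance-level balanced accuracy", {
  fx <- planted_matrix(100, 10, n_signal = 3, shift = 2, seed = 12)
  ys <- withr::with_seed(99, sample(fx$y))
  rep0 <- outer_repeated_cv(fx$X, ys,
                            model_spec("logistic_elasticnet",
                                       grid = list(alpha = 0.5, lambda = 0.05)),
                            repeats = 2, k = 5, seed = 7)
  expect_lt(abs(qgexar:::cv_mean_ba(rep0) - 0.5), 0.08)
})

test_that("model selection maximises mean BA with declared-order ties", {
  mk <- function(label, ba) {
    spec <- model_spec("logistic_elasticnet", label = label)
    structure(list(label = label, spec = spec,
                   folds = data.frame(),
                   aggregate = data.frame(metric = "ba", mean = ba, sd = 0)),
              class = "cv_report")
  }
  expect_equal(select_best_model(list(mk("a", 0.62)))$label, "a")
  expect_equal(select_best_model(list(mk("a", 0.62), mk("b", 0.67)))$label, "b")
  expect_equal(select_best_model(list(mk("a", 0.65), mk("b", 0.65)))$label, "a")
})

test_that("a linear planted boundary favours the elastic-net model over a majority baseline", {
  fx <- planted_matrix(120, 10, n_signal = 4, shift = 2, seed = 21)
  majority <- model_spec(
    "external", label = "majority", grid = list(dummy = 1),
    fit = function(x, y, params, w) mean(y),
    predict_prob = function(m, x) rep(ifelse(m >= 0.5, 1, 0), nrow(x)))
  reports <- list(
    outer_repeated_cv(fx$X, fx$y, majority, repeats = 1, k = 3, seed = 2),
    outer_repeated_cv(fx$X, fx$y,
                      model_spec("logistic_elasticnet",
                                 grid = list(alpha = 0.5, lambda = 0.05)),
                      repeats = 1, k = 3, seed = 2))
  expect_equal(select_best_model(reports)$label, "logistic_elasticnet")
})

test_that("final fit predicts unseen chemicals without touching validation data", {
  fx <- planted_matrix(80, 10, n_signal = 3, shift = 3, seed = 14)
  x_valid <- fx$X[1:5, , drop = FALSE]  # includes training actives
  rownames(x_valid) <- paste0("v", 1:5)
  spec <- model_spec("logistic_elasticnet",
                     grid = list(alpha = 0.5, lambda = 0.05))
  out <- fit_final_and_predict(fx$X, fx$y, spec, x_valid,
                               feature_selector = multisurf_selector(),
                               seed = 3)
  expect_true(all(out$probabilities >= 0 & out$probabilities <= 1))
  # a validation chemical identical to a training active scores > 0.5
  act <- which(fx$y == 1)[1]
  x_act <- fx$X[act, , drop = FALSE]
  out2 <- fit_final_and_predict(fx$X, fx$y, spec, x_act, seed = 3)
  expect_gt(out2$probabilities[1], 0.5)
  # empty validation set: empty output
  out3 <- fit_final_and_predict(fx$X, fx$y, spec,
                                fx$X[0, , drop = FALSE], seed = 3)
  expect_length(out3$probabilities, 0)
  # training artifacts are identical whatever validation set is scored:
  # selection and tuning never see validation data
  alt_valid <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, colnames(fx$X)))
  out4 <- fit_final_and_predict(fx$X, fx$y, spec, alt_valid,
                                feature_selector = multisurf_selector(),
                                seed = 3)
  expect_identical(out$selected_features, out4$selected_features)
  expect_identical(out$params, out4$params)
  expect_identical(out$model$backend$fit$beta, out4$model$backend$fit$beta)
  # validation features must cover the training genes
  expect_error(
    fit_final_and_predict(fx$X, fx$y, spec, matrix(0, 2, 2), seed = 3),
    "schema error")
})

test_that("every shipped backend returns probabilities on both classes", {
  fx <- planted_matrix(60, 8, n_signal = 2, shift = 2.5, seed = 33)
  xv <- fx$X[1:10, , drop = FALSE]
  for (algo in names(default_model_zoo())) {
    grid <- lapply(qgexar:::default_grid(algo), function(v) v[1])
    out <- fit_final_and_predict(fx$X, fx$y, model_spec(algo, grid = grid),
                                 xv, seed = 4)
    expect_length(out$probabilities, 10)
    expect_true(all(out$probabilities >= 0 & out$probabilities <= 1),
                info = algo)
  }
})
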