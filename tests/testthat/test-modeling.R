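test_that("fold construction yields the 298/37/37 stratified design", {
  set.seed(8)
  y <- runif(372)
  folds <- make_folds(y, n_bins = 10, seed = 4)
  for (f in folds$folds) {
    expect_length(f$train, 298)
    expect_length(f$dev, 37)
    expect_length(f$test, 37)
    expect_length(intersect(f$test, f$dev), 0)
    expect_length(intersect(f$test, f$train), 0)
  }
  tests <- unlist(lapply(folds$folds, `[[`, "test"))
  expect_equal(length(tests), length(unique(tests)))
  expect_equal(length(tests), 370)
  # the two leftover users sit in every training set
  for (f in folds$folds) expect_true(all(folds$leftover %in% f$train))
  # stratification: every bin spans the target's range
  bin_means <- vapply(folds$bins, function(b) mean(y[b]), numeric(1))
  expect_true(all(abs(bin_means - mean(y)) < 0.05))
  expect_error(make_folds(runif(15), 10), "at least")
})

test_that("RFE keeps planted informative features and honors edge cases", {
  set.seed(3)
  n <- 150
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- 2 * x[, "f7"] + rnorm(n, 0, 0.5)
  tr <- 1:100; dev <- 101:150
  spec <- model_spec("linear")
  sel <- run_rfe(spec, x[tr, ], y[tr], x[dev, ], y[dev])
  expect_true("f7" %in% sel)
  # dev MAE of the selection never exceeds the full-feature dev MAE
  fit_full <- fit_swb_model(spec, x[tr, ], y[tr])
  mae_full <- mean(abs(predict_swb_model(fit_full, x[dev, ]) - y[dev]))
  fit_sel <- fit_swb_model(spec, x[tr, sel, drop = FALSE], y[tr])
  mae_sel <- mean(abs(predict_swb_model(fit_sel, x[dev, sel, drop = FALSE]) -
                        y[dev]))
  expect_lte(mae_sel, mae_full + 1e-12)
  # single feature: returned unconditionally
  expect_equal(run_rfe(spec, x[tr, 1, drop = FALSE], y[tr],
                       x[dev, 1, drop = FALSE], y[dev]), "f1")
  # all-constant features: one arbitrary feature with a warning
  flat <- matrix(1, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(sel0 <- run_rfe(spec, flat[tr, ], y[tr], flat[dev, ],
                                 y[dev]), "constant")
  expect_length(sel0, 1)
})

test_that("regression recovers noiseless linear structure exactly", {
  set.seed(9)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * x[, "a"] - 1
  folds <- make_folds(y, 10, seed = 2)
  cv <- cv_regression(x, y, specs = list(linear = model_spec("linear")),
                      folds = folds, seed = 1)
  expect_lt(cv$models$linear$aggregate[["mae"]], 1e-8)
  expect_gt(cv$models$linear$aggregate[["pearson_r"]], 0.999)
  expect_equal(cv$best, "linear")
  expect_error(cv_regression(cbind(x, bad = NA), y, folds = folds),
               "non-finite")
})

test_that("a constant target collapses model and baseline error to zero", {
  n <- 40
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0.5, n)
  folds <- make_folds(y, 10, seed = 1)
  cv <- cv_regression(x, y, specs = list(linear = model_spec("linear")),
                      folds = folds, seed = 1)
  expect_equal(cv$models$linear$aggregate[["mae"]], 0)
  expect_equal(cv$baselines$mean_baseline[["mae"]], 0)
})

test_that("aggregates are the arithmetic mean of stored fold metrics", {
  set.seed(4)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + rnorm(n, 0, 0.3)
  cv <- cv_regression(x, y, specs = list(lasso = model_spec(
    "lasso", params = list(lambda = 0.01))),
    folds = make_folds(y, 10, seed = 3), seed = 2)
  m <- cv$models$lasso
  stored <- do.call(rbind, lapply(m$folds, `[[`, "metrics"))
  expect_equal(unname(m$aggregate["mae"]), mean(stored[, "mae"]))
  expect_equal(unname(m$aggregate["pearson_r"]), mean(stored[, "pearson_r"]))
  expect_true(all(stored[, "r2"] <= 1))
  expect_true(all(abs(stored[, "pearson_r"]) <= 1))
})

test_that("classification separates planted classes and reports rates", {
  set.seed(6)
  n <- 90
  score <- runif(n)
  x <- cbind(sig = score + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  labels <- assign_class(score, cutoff_set("binary", 0.7))
  folds <- make_folds(score, 10, seed = 5)
  cv <- cv_classification(x, labels,
                          specs = list(logistic = model_spec("logistic")),
                          folds = folds, seed = 1)
  expect_gt(cv$models$logistic$aggregate[["f1_macro"]], 0.95)
  # low is the majority class, so the baseline predicts low everywhere:
  # TPR(low) = FPR(low) = 1
  expect_equal(cv$baselines$majority_baseline[["tpr_low"]], 1)
  expect_equal(cv$baselines$majority_baseline[["fpr_low"]], 1)
})

test_that("classification metrics equal hand-computed confusion values", {
  truth <- factor(c("low", "low", "high", "high"),
                  levels = c("low", "high"))
  pred <- factor(c("low", "high", "high", "high"),
                 levels = c("low", "high"))
  m <- swbtrace:::classification_metrics(truth, pred)
  # low: tp=1 fn=1 fp=0 -> precision 1, recall .5, f1 2/3
  # high: tp=2 fn=0 fp=1 -> precision 2/3, recall 1, f1 0.8
  expect_equal(m[["f1_low"]], 2 / 3)
  expect_equal(m[["f1_high"]], 0.8)
  expect_equal(m[["f1_macro"]], (2 / 3 + 0.8) / 2)
  expect_equal(m[["f1_weighted"]], 0.5 * 2 / 3 + 0.5 * 0.8)
  expect_equal(m[["tpr_low"]], 0.5)
  expect_equal(m[["fpr_low"]], 0)
})

test_that("baseline errors follow their defining formulas", {
  # mean baseline on its own training sample: mean absolute deviation
  y <- c(1, 2, 3, 6)
  expect_equal(mean(abs(y - mean(y))), 1.5)
  m <- swbtrace:::regression_metrics(y, rep(mean(y), 4))
  expect_equal(m[["mae"]], 1.5)
  # skewed toy target: median baseline MAE = 0.25 on that sample
  y2 <- c(0, 0, 0, 1)
  m2 <- swbtrace:::regression_metrics(y2, rep(median(y2), 4))
  expect_equal(m2[["mae"]], 0.25)
})

test_that("stable features require selection in at least half the folds", {
  fake <- list(folds = lapply(1:10, function(i) {
    feats <- if (i <= 5) c("keep", "sometimes") else "keep"
    list(fold = i, features = feats,
         importance = setNames(c(1, 0.5)[seq_along(feats)], feats))
  }))
  rep5 <- stable_features(fake, min_folds = 5)
  expect_true("keep" %in% rep5$feature)
  expect_true("sometimes" %in% rep5$feature)
  expect_equal(rep5$n_selected[rep5$feature == "keep"], 10L)
  # a feature selected in only 4 folds is excluded
  fake4 <- list(folds = lapply(1:10, function(i) {
    feats <- if (i <= 4) c("keep", "rare") else "keep"
    list(fold = i, features = feats,
         importance = setNames(rep(1, length(feats)), feats))
  }))
  expect_false("rare" %in% stable_features(fake4, 5)$feature)
  # importances average only over the folds where the feature was chosen
  expect_equal(rep5$mean_importance[rep5$feature == "sometimes"], 0.5)
  # no feature reaching the floor: an empty but valid report
  none <- list(folds = lapply(1:10, function(i)
    list(fold = i, features = paste0("f", i),
         importance = setNames(1, paste0("f", i)))))
  expect_equal(nrow(stable_features(none, 5)), 0)
})

test_that("a tampered fold triggers the leakage assertion", {
  y <- runif(40)
  folds <- make_folds(y, 10, seed = 1)
  folds$folds[[1]]$train[1] <- folds$folds[[1]]$test[1]
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(cv_regression(x, y, specs = list(linear = model_spec("linear")),
                             folds = folds, seed = 1))
})

test_that("the feature registry reproduces the published family totals", {
  reg <- feature_registry()
  sizes <- setNames(reg$families$size, reg$families$family)
  expect_equal(sizes[["behavior"]], 40L)
  expect_equal(sizes[["appcats"]], 225L)
  expect_equal(sizes[["sentiment"]], 6L)
  expect_equal(sizes[["liwc"]], 8L)
  expect_equal(unname(reg$totals["swls"]), 660)
  expect_equal(unname(reg$totals["who5"]), 651)
})

test_that("every advertised model family fits, predicts and ranks features", {
  set.seed(10)
  n <- 70
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.3)
  labels <- factor(ifelse(y > median(y), "high", "low"),
                   levels = c("low", "high"))
  reg_specs <- default_model_specs("regression", rf_ntree = 50,
                                   ada_rounds = 10)
  expect_length(reg_specs, 7)
  for (spec in reg_specs) {
    fit <- fit_swb_model(spec, x, y, "regression", seed = 1)
    pred <- predict_swb_model(fit, x)
    expect_length(pred, n)
    imp <- importance_swb_model(fit)
    expect_length(imp, 5)
    expect_true(all(imp >= 0))
  }
  cls_specs <- default_model_specs("classification", rf_ntree = 50,
                                   ada_rounds = 10)
  expect_length(cls_specs, 3)
  for (spec in cls_specs) {
    fit <- fit_swb_model(spec, x, labels, "classification", seed = 1)
    pred <- predict_swb_model(fit, x)
    expect_s3_class(pred, "factor")
    expect_true(all(importance_swb_model(fit) >= 0))
  }
  expect_error(fit_swb_model(model_spec("logistic"), x, y, "regression"))
  expect_error(fit_swb_model(model_spec("linear"), x, labels,
                             "classification"))
})
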