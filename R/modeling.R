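#' Value-stratified 10-fold train/dev/test splits
#'
#' The sample is shuffled (seeded), sorted by the target, and sorted
#' positions are dealt to the bins in round-robin order until each bin
#' holds floor(n / n_bins) users, so every bin spans the target's range.
#' Leftover users always stay in the training set. Fold i uses bin i as the
#' test set and bin i+1 (with wraparound) as the dev set.
#'
#' @param y Target values (length n >= 2 * n_bins).
#' @param n_bins Number of bins / folds (default 10).
#' @param seed Shuffle seed.
#' @return Object of class `swb_folds`: list with `bins`, `leftover` and
#'   `folds` (each fold a list of `train`, `dev`, `test` index vectors).
#' @export
make_folds <- function(y, n_bins = 10, seed = 1) {
  n <- length(y)
  if (n < 2 * n_bins) {
    stop("need at least ", 2 * n_bins, " observations for ", n_bins,
         " bins", call. = FALSE)
  }
  m <- n %/% n_bins
  ord <- with_seed(seed, {
    perm <- sample.int(n)
    perm[order(y[perm])] # stable sort: ties stay shuffled
  })
  binned <- ord[seq_len(n_bins * m)]
  leftover <- if (n_bins * m < n) ord[(n_bins * m + 1):n] else integer(0)
  bins <- split(binned, rep_len(seq_len(n_bins), length(binned)))
  folds <- lapply(seq_len(n_bins), function(i) {
    test <- bins[[i]]
    dev <- bins[[if (i == n_bins) 1L else i + 1L]]
    train <- c(setdiff(binned, c(test, dev)), leftover)
    stopifnot(length(intersect(test, dev)) == 0,
              length(intersect(test, train)) == 0,
              length(intersect(dev, train)) == 0)
    list(train = train, dev = dev, test = test)
  })
  structure(list(bins = bins, leftover = leftover, folds = folds,
                 n_bins = n_bins, n = n, seed = seed),
            class = "swb_folds")
}

#' @export
print.swb_folds <- function(x, ...) {
  sizes <- lengths(x$folds[[1]])
  cat(sprintf("%d folds over %d users (train/dev/test = %d/%d/%d)\n",
              x$n_bins, x$n, sizes["train"], sizes["dev"], sizes["test"]))
  invisible(x)
}

#' Recursive feature elimination guided by a development set
#'
#' Starting from all features, the lowest-importance 10% (at least one) are
#' dropped each round; the model is refit and the dev error tracked. The
#' subset with the best dev error is returned.
#'
#' @param spec A [model_spec()].
#' @param x_train,y_train Training data.
#' @param x_dev,y_dev Development data scored with `metric`.
#' @param task `"regression"` or `"classification"`.
#' @param metric `"mae"` (regression default) or `"f1"` (1 - macro F1,
#'   classification default).
#' @param seed Seed for stochastic learners.
#' @param params Hyperparameters for every refit.
#' @return Character vector of selected feature names.
#' @export
run_rfe <- function(spec, x_train, y_train, x_dev, y_dev,
                    task = "regression",
                    metric = if (task == "regression") "mae" else "f1",
                    seed = 1, params = NULL) {
  x_train <- as.matrix(x_train); x_dev <- as.matrix(x_dev)
  feats <- colnames(x_train)
  stopifnot(!is.null(feats))
  if (all(apply(x_train, 2, stats::sd) == 0)) {
    warning("all features constant; returning a single arbitrary feature")
    return(feats[1])
  }
  dev_score <- function(model) {
    pred <- predict_swb_model(model, x_dev)
    if (metric == "mae") mean(abs(pred - y_dev))
    else 1 - f1_scores(y_dev, pred)$macro
  }
  history <- list()
  current <- feats
  repeat {
    model <- fit_swb_model(spec, x_train[, current, drop = FALSE], y_train,
                           task = task, seed = seed, params = params)
    history[[length(history) + 1]] <- list(features = current,
                                           score = dev_score(model))
    if (length(current) == 1) break
    imp <- importance_swb_model(model)
    drop_n <- max(1L, floor(0.1 * length(current)))
    current <- current[order(imp, decreasing = TRUE)]
    current <- current[seq_len(length(current) - drop_n)]
  }
  scores <- vapply(history, `[[`, numeric(1), "score")
  history[[which.min(scores)]]$features
}

# Per-class F1 plus macro / weighted aggregates; empty denominators give 0.
f1_scores <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  per_class <- vapply(levels(truth), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  weights <- as.vector(table(truth)) / length(truth)
  list(per_class = per_class, macro = mean(per_class),
       weighted = sum(per_class * weights))
}

regression_metrics <- function(truth, pred) {
  mae <- mean(abs(pred - truth))
  r <- if (stats::sd(pred) > 0 && stats::sd(truth) > 0) {
    stats::cor(pred, truth)
  } else 0
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot > 0) 1 - sum((pred - truth)^2) / ss_tot else NA_real_
  c(mae = mae, pearson_r = r, r2 = r2)
}

classification_metrics <- function(truth, pred, low_class = "low") {
  f1 <- f1_scores(truth, pred)
  tp_low <- sum(pred == low_class & truth == low_class)
  n_low <- sum(truth == low_class)
  n_not_low <- sum(truth != low_class)
  fp_low <- sum(pred == low_class & truth != low_class)
  c(f1_macro = f1$macro, f1_weighted = f1$weighted,
    f1_low = f1$per_class[[low_class]],
    f1_high = f1$per_class[["high"]],
    tpr_low = if (n_low > 0) tp_low / n_low else 0,
    fpr_low = if (n_not_low > 0) fp_low / n_not_low else 0)
}

assert_no_leakage <- function(fold) {
  stopifnot(length(intersect(fold$test, fold$train)) == 0,
            length(intersect(fold$test, fold$dev)) == 0)
}

# Shared CV loop over folds and model specs.
cv_loop <- function(x, y, specs, folds, task, seed, rfe = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  stopifnot(nrow(x) == length(y), inherits(folds, "swb_folds"))
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "family")
  }
  metric_fun <- if (task == "regression") {
    function(tr, pr) regression_metrics(tr, pr)
  } else {
    function(tr, pr) classification_metrics(tr, pr)
  }
  results <- lapply(names(specs), function(sn) {
    spec <- specs[[sn]]
    fold_rows <- list()
    for (fi in seq_along(folds$folds)) {
      fold <- folds$folds[[fi]]
      assert_no_leakage(fold)
      if (task == "classification" &&
          nlevels(droplevels(factor(y[fold$train]))) < 2) {
        warning("fold ", fi, " skipped: training set is single-class")
        next
      }
      fseed <- derive_seed(seed, fi)
      dev_of <- function(params) {
        m <- fit_swb_model(spec, x[fold$train, , drop = FALSE],
                           y[fold$train], task, seed = fseed,
                           params = params)
        pred <- predict_swb_model(m, x[fold$dev, , drop = FALSE])
        if (task == "regression") mean(abs(pred - y[fold$dev]))
        else 1 - f1_scores(y[fold$dev], pred)$macro
      }
      dev_scores <- vapply(spec$grid, dev_of, numeric(1))
      params <- spec$grid[[which.min(dev_scores)]]
      sel <- if (rfe) {
        run_rfe(spec, x[fold$train, , drop = FALSE], y[fold$train],
                x[fold$dev, , drop = FALSE], y[fold$dev], task = task,
                seed = fseed, params = params)
      } else colnames(x)
      model <- fit_swb_model(spec, x[fold$train, sel, drop = FALSE],
                             y[fold$train], task, seed = fseed,
                             params = params)
      pred <- predict_swb_model(model, x[fold$test, sel, drop = FALSE])
      fold_rows[[length(fold_rows) + 1]] <- list(
        fold = fi, features = sel, params = params,
        importance = importance_swb_model(model),
        metrics = metric_fun(y[fold$test], pred))
    }
    metrics <- do.call(rbind, lapply(fold_rows, `[[`, "metrics"))
    list(family = sn, folds = fold_rows,
         aggregate = colMeans(metrics, na.rm = TRUE))
  })
  names(results) <- names(specs)
  results
}

#' Cross-validated regression over the fold design
#'
#' Per fold and model family: hyperparameters chosen by dev MAE, features
#' by RFE on the dev set, metrics (MAE, Pearson r, R2) on the test set;
#' aggregates are arithmetic means over folds. Mean and median baselines
#' are always included.
#'
#' @param x Feature matrix (users x features).
#' @param y Numeric target, row-aligned with `x`.
#' @param specs List of [model_spec()]s
#'   (default [default_model_specs()]).
#' @param folds A [make_folds()] design.
#' @param seed Seed for stochastic learners.
#' @param rfe Run recursive feature elimination (default TRUE).
#' @return Object of class `swb_cv`: per-model fold results and
#'   aggregates, `baselines`, and `best` (family with lowest mean MAE).
#' @export
cv_regression <- function(x, y, specs = default_model_specs("regression"),
                          folds, seed = 1, rfe = TRUE) {
  models <- cv_loop(x, y, specs, folds, "regression", seed, rfe)
  base <- baselines(y, folds, task = "regression")
  agg_mae <- vapply(models, function(m) m$aggregate[["mae"]], numeric(1))
  structure(list(task = "regression", models = models, baselines = base,
                 best = names(models)[which.min(agg_mae)]),
            class = "swb_cv")
}

#' Cross-validated classification over the fold design
#'
#' Reports macro and weighted F1, per-class F1 for the low and high
#' classes, and the true/false positive rates of the low class, averaged
#' over folds; a train-majority baseline is included.
#'
#' @param x Feature matrix.
#' @param labels Factor labels from [assign_class()], row-aligned.
#' @param specs List of classification [model_spec()]s.
#' @param folds A [make_folds()] design (built on the underlying scores).
#' @param seed Seed for stochastic learners.
#' @param rfe Run recursive feature elimination (default TRUE).
#' @return Object of class `swb_cv`.
#' @export
cv_classification <- function(x, labels,
                              specs = default_model_specs("classification"),
                              folds, seed = 1, rfe = TRUE) {
  labels <- as.factor(labels)
  models <- cv_loop(x, labels, specs, folds, "classification", seed, rfe)
  base <- baselines(labels, folds, task = "classification")
  agg_f1 <- vapply(models, function(m) m$aggregate[["f1_macro"]], numeric(1))
  structure(list(task = "classification", models = models, baselines = base,
                 best = names(models)[which.max(agg_f1)]),
            class = "swb_cv")
}

#' @export
print.swb_cv <- function(x, ...) {
  cat("Cross-validated", x$task, "report\n")
  for (m in x$models) {
    cat(sprintf("  %-11s %s\n", m$family,
                paste(sprintf("%s=%.4f", names(m$aggregate), m$aggregate),
                      collapse = " ")))
  }
  for (b in names(x$baselines)) {
    cat(sprintf("  %-11s %s\n", b,
                paste(sprintf("%s=%.4f", names(x$baselines[[b]]),
                              x$baselines[[b]]), collapse = " ")))
  }
  cat("  best:", x$best, "\n")
  invisible(x)
}

#' Fold-averaged baselines
#'
#' Regression: predict the training mean or median, score test MAE.
#' Classification: predict the training majority class, score the full
#' classification metric set (so the majority-low baseline shows
#' TPR(low) = FPR(low) = 1).
#'
#' @param y Target vector or factor labels.
#' @param folds A [make_folds()] design.
#' @param task `"regression"` or `"classification"`.
#' @return Named list of baseline metric vectors.
#' @export
baselines <- function(y, folds, task = "regression") {
  stopifnot(inherits(folds, "swb_folds"))
  if (task == "regression") {
    list(
      mean_baseline = {
        v <- vapply(folds$folds, function(f)
          regression_metrics(y[f$test],
                             rep(mean(y[f$train]), length(f$test))),
          numeric(3))
        rowMeans(v, na.rm = TRUE)
      },
      median_baseline = {
        v <- vapply(folds$folds, function(f)
          regression_metrics(y[f$test],
                             rep(stats::median(y[f$train]), length(f$test))),
          numeric(3))
        rowMeans(v, na.rm = TRUE)
      })
  } else {
    y <- as.factor(y)
    v <- vapply(folds$folds, function(f) {
      maj <- names(which.max(table(y[f$train])))
      classification_metrics(y[f$test],
                             factor(rep(maj, length(f$test)),
                                    levels = levels(y)))
    }, numeric(6))
    list(majority_baseline = rowMeans(v, na.rm = TRUE))
  }
}

#' Features stably selected across cross-validation folds
#'
#' @param model_result One entry of a `swb_cv` object's `models` list.
#' @param min_folds Minimum folds a feature must be RFE-selected in
#'   (default 5 of 10).
#' @param families Optional named vector mapping feature to feature family
#'   for grouped reporting.
#' @return Data frame with columns `feature`, `n_selected`,
#'   `mean_importance` (mean over the folds where selected) and optionally
#'   `family`, sorted by selection count.
#' @export
stable_features <- function(model_result, min_folds = 5, families = NULL) {
  sel <- unlist(lapply(model_result$folds, `[[`, "features"))
  counts <- table(sel)
  keep <- names(counts)[counts >= min_folds]
  rows <- lapply(keep, function(f) {
    imps <- vapply(model_result$folds, function(fr) {
      if (f %in% fr$features) fr$importance[[f]] else NA_real_
    }, numeric(1))
    data.frame(feature = f, n_selected = as.integer(counts[[f]]),
               mean_importance = mean(imps, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), n_selected = integer(),
               mean_importance = numeric(), stringsAsFactors = FALSE)
  if (!is.null(families) && nrow(out)) {
    out$family <- unname(families[out$feature])
  }
  out[order(-out$n_selected, out$feature), , drop = FALSE]
}

#' Feature-family registry and totals
#'
#' Accounts for the pipeline's feature families: 40 activity features, 225
#' app-category features, 6 sentiment proportions, 8 lexicon categories,
#' the heldout-selected word features, and the target-specific cluster
#' features. The defaults are the study configuration's counts (353 words;
#' 28 SWLS / 19 WHO-5 clusters), under which the totals are 660 features
#' for SWLS and 651 for WHO-5.
#'
#' @param n_words Number of selected word features.
#' @param n_clusters_swls,n_clusters_who5 Cluster features per target.
#' @return List with `families` (data frame of family sizes) and `totals`
#'   (named vector, one total per target).
#' @export
feature_registry <- function(n_words = 353, n_clusters_swls = 28,
                             n_clusters_who5 = 19) {
  families <- data.frame(
    family = c("behavior", "appcats", "sentiment", "liwc", "words",
               "clusters_swls", "clusters_who5"),
    size = c(40L, 225L, 6L, 8L, as.integer(n_words),
             as.integer(n_clusters_swls), as.integer(n_clusters_who5)),
    stringsAsFactors = FALSE
  )
  shared <- sum(families$size[families$family %in%
                                c("behavior", "appcats", "sentiment",
                                  "liwc", "words")])
  list(families = families,
       totals = c(swls = shared + n_clusters_swls,
                  who5 = shared + n_clusters_who5))
}
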