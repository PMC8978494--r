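#' Specification of a model family with hyperparameters
#'
#' Regression families: `linear`, `ridge`, `lasso`, `elasticnet`, `tree`,
#' `rf`, `adaboost`. Classification families: `logistic`, `rf`, `adaboost`.
#'
#' @param family Family name.
#' @param params Named list of hyperparameter values for one fit.
#' @param grid Optional list of `params` lists searched on the dev set; when
#'   NULL, `params` is the single grid point.
#' @return An object of class `swb_model_spec`.
#' @export
model_spec <- function(family, params = list(), grid = NULL) {
  known <- c("linear", "ridge", "lasso", "elasticnet", "tree", "rf",
             "adaboost", "logistic")
  if (!family %in% known) {
    stop("unknown model family: ", family, call. = FALSE)
  }
  structure(list(family = family, params = params,
                 grid = grid %||% list(params)),
            class = "swb_model_spec")
}

#' Default model specifications with small documented hyperparameter grids
#'
#' @param task `"regression"` or `"classification"`.
#' @param rf_ntree,ada_rounds Ensemble sizes (lowered in small studies).
#' @return Named list of [model_spec()]s: the seven regression families or
#'   the three classification families.
#' @export
default_model_specs <- function(task = c("regression", "classification"),
                                rf_ntree = 200, ada_rounds = 50) {
  task <- match.arg(task)
  lam <- list(list(lambda = 0.001), list(lambda = 0.01), list(lambda = 0.1))
  if (task == "regression") {
    list(
      linear = model_spec("linear"),
      ridge = model_spec("ridge", grid = list(list(lambda = 0.01),
                                              list(lambda = 0.1),
                                              list(lambda = 1))),
      lasso = model_spec("lasso", grid = lam),
      elasticnet = model_spec("elasticnet", grid = lam),
      tree = model_spec("tree", grid = list(list(maxdepth = 3),
                                            list(maxdepth = 5))),
      rf = model_spec("rf", params = list(ntree = rf_ntree)),
      adaboost = model_spec("adaboost",
                            params = list(n_rounds = ada_rounds, maxdepth = 3))
    )
  } else {
    list(
      logistic = model_spec("logistic"),
      rf = model_spec("rf", params = list(ntree = rf_ntree)),
      adaboost = model_spec("adaboost",
                            params = list(n_rounds = ada_rounds, maxdepth = 3))
    )
  }
}

#' Fit one model-family instance
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix.
#' @param y Numeric target (regression) or factor labels (classification).
#' @param task `"regression"` or `"classification"`.
#' @param seed Seed for stochastic learners.
#' @param params Hyperparameters overriding `spec$params`.
#' @return An object of class `swb_model`.
#' @export
fit_swb_model <- function(spec, x, y, task = "regression", seed = 1,
                          params = NULL) {
  stopifnot(inherits(spec, "swb_model_spec"))
  if (any(!is.finite(as.matrix(x)))) {
    stop("non-finite feature values", call. = FALSE)
  }
  p <- utils::modifyList(spec$params, params %||% list())
  x <- as.matrix(x)
  fam <- spec$family
  if (task == "classification" && !fam %in% c("logistic", "rf", "adaboost")) {
    stop(fam, " is not a classification family", call. = FALSE)
  }
  if (task == "regression" && fam == "logistic") {
    stop("logistic is not a regression family", call. = FALSE)
  }
  fit <- with_seed(seed, switch(fam,
    linear = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      stats::lm(.y ~ ., data = df)
    },
    ridge = ,
    lasso = ,
    elasticnet = {
      alpha <- switch(fam, ridge = 0, lasso = 1, elasticnet = 0.5)
      xg <- if (ncol(x) < 2) cbind(x, `..pad..` = 0) else x
      glmnet::glmnet(xg, y, alpha = alpha,
                     lambda = p$lambda %||% 0.01)
    },
    tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df,
                   method = if (task == "regression") "anova" else "class",
                   control = rpart::rpart.control(
                     maxdepth = p$maxdepth %||% 5, cp = p$cp %||% 0.001,
                     minsplit = p$minsplit %||% 10, xval = 0))
    },
    rf = randomForest::randomForest(
      x = x, y = y, ntree = p$ntree %||% 200),
    adaboost = if (task == "regression") {
      adaboost_r2(x, y, n_rounds = p$n_rounds %||% 50,
                  maxdepth = p$maxdepth %||% 3)
    } else {
      adaboost_samme(x, y, n_rounds = p$n_rounds %||% 50,
                     maxdepth = p$maxdepth %||% 3)
    },
    logistic = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200)
    }
  ))
  structure(list(family = fam, task = task, fit = fit,
                 features = colnames(x),
                 levels = if (is.factor(y)) levels(y) else NULL),
            class = "swb_model")
}

#' Predict from a fitted model
#'
#' @param model A [fit_swb_model()] result.
#' @param x Feature matrix with the training columns.
#' @return Numeric predictions (regression) or a factor (classification).
#' @export
predict_swb_model <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  fam <- model$family
  out <- switch(fam,
    linear = ,
    logistic = {
      df <- data.frame(x, check.names = FALSE)
      if (fam == "linear") {
        suppressWarnings(unname(stats::predict(model$fit, newdata = df)))
      } else {
        as.character(stats::predict(model$fit, newdata = df))
      }
    },
    ridge = ,
    lasso = ,
    elasticnet = {
      xg <- if (ncol(x) < 2) cbind(x, `..pad..` = 0) else x
      as.vector(stats::predict(model$fit, newx = xg))
    },
    tree = {
      df <- data.frame(x, check.names = FALSE)
      if (model$task == "regression") {
        unname(stats::predict(model$fit, newdata = df))
      } else {
        as.character(stats::predict(model$fit, newdata = df, type = "class"))
      }
    },
    rf = {
      pr <- stats::predict(model$fit, newdata = x)
      if (model$task == "regression") unname(pr) else as.character(pr)
    },
    adaboost = predict_adaboost(model$fit, x)
  )
  if (model$task == "classification") factor(out, levels = model$levels)
  else out
}

#' Feature importances of a fitted model
#'
#' Coefficient magnitudes for linear families, split-based importances for
#' trees and ensembles; always non-negative and named for every training
#' feature (absent features get 0).
#'
#' @param model A [fit_swb_model()] result.
#' @return Named non-negative numeric vector.
#' @export
importance_swb_model <- function(model) {
  feats <- model$features
  raw <- switch(model$family,
    linear = {
      cf <- stats::coef(model$fit)[-1]
      names(cf) <- feats
      abs(ifelse(is.na(cf), 0, cf))
    },
    ridge = ,
    lasso = ,
    elasticnet = {
      cf <- as.matrix(stats::coef(model$fit))
      abs(cf[-1, 1])
    },
    tree = model$fit$variable.importance,
    rf = {
      im <- randomForest::importance(model$fit)
      stats::setNames(im[, 1], rownames(im))
    },
    adaboost = adaboost_importance(model$fit),
    logistic = {
      cf <- stats::coef(model$fit)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                         dimnames = list(NULL, names(cf)))
      cols <- setdiff(colnames(cf), "(Intercept)")
      stats::setNames(apply(abs(cf[, cols, drop = FALSE]), 2, max),
                      make.names(feats))
    }
  )
  # rpart/multinom mangle names through formulas; map back positionally
  out <- stats::setNames(rep(0, length(feats)), feats)
  mangled <- make.names(feats)
  for (nm in names(raw)) {
    hit <- which(feats == nm | mangled == nm)
    if (length(hit)) out[hit[1]] <- out[hit[1]] + raw[[nm]]
  }
  pmax(out, 0)
}

# --- AdaBoost (hand-rolled: regression AdaBoost.R2, classification SAMME,
# --- rpart base learners with case weights) -------------------------------

adaboost_r2 <- function(x, y, n_rounds = 50, maxdepth = 3) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list(); betas <- numeric(0)
  df <- data.frame(.y = y, x, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.001, minsplit = 10,
                          xval = 0))
    pred <- stats::predict(fit, newdata = df)
    err <- abs(pred - y)
    d <- max(err)
    if (d == 0) { learners[[m]] <- fit; betas[m] <- 1e-10; break }
    loss <- err / d
    ebar <- sum(w * loss)
    if (ebar >= 0.5) { if (m == 1) { learners[[m]] <- fit; betas[m] <- 0.5 }
      break }
    beta <- max(ebar / (1 - ebar), 1e-10)
    learners[[m]] <- fit; betas[m] <- beta
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  structure(list(kind = "r2", learners = learners,
                 alpha = log(1 / betas), features = colnames(x)),
            class = "swb_adaboost")
}

adaboost_samme <- function(x, y, n_rounds = 50, maxdepth = 3) {
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  df <- data.frame(.y = y, x, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.001, minsplit = 10,
                          xval = 0))
    pred <- stats::predict(fit, newdata = df, type = "class")
    miss <- pred != y
    err <- sum(w * miss)
    if (err <= 0) { learners[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 1 - 1 / k) break
    alpha <- log((1 - err) / err) + log(k - 1)
    learners[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(learners) == 0) { # degenerate: fall back to one stump
    learners <- list(rpart::rpart(.y ~ ., data = df, method = "class",
                                  control = rpart::rpart.control(
                                    maxdepth = 1, xval = 0)))
    alphas <- 1
  }
  structure(list(kind = "samme", learners = learners, alpha = alphas,
                 classes = levels(y), features = colnames(x)),
            class = "swb_adaboost")
}

predict_adaboost <- function(obj, x) {
  df <- data.frame(as.matrix(x), check.names = FALSE)
  if (obj$kind == "r2") {
    preds <- vapply(obj$learners, function(f)
      stats::predict(f, newdata = df), numeric(nrow(df)))
    preds <- matrix(preds, nrow = nrow(df))
    apply(preds, 1, weighted_median, w = obj$alpha)
  } else {
    votes <- matrix(0, nrow(df), length(obj$classes),
                    dimnames = list(NULL, obj$classes))
    for (m in seq_along(obj$learners)) {
      pred <- as.character(stats::predict(obj$learners[[m]], newdata = df,
                                          type = "class"))
      votes[cbind(seq_len(nrow(df)), match(pred, obj$classes))] <-
        votes[cbind(seq_len(nrow(df)), match(pred, obj$classes))] +
        obj$alpha[m]
    }
    obj$classes[max.col(votes, ties.method = "first")]
  }
}

weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  v[o][which(cw >= 0.5)[1]]
}

adaboost_importance <- function(obj) {
  agg <- list()
  for (m in seq_along(obj$learners)) {
    vi <- obj$learners[[m]]$variable.importance
    if (is.null(vi)) next
    for (nm in names(vi)) {
      agg[[nm]] <- (agg[[nm]] %||% 0) + obj$alpha[m] * vi[[nm]]
    }
  }
  if (length(agg) == 0) return(stats::setNames(numeric(0), character(0)))
  unlist(agg)
}
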