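#' Supervision penalty of a cluster solution
#'
#' Each cluster's feature is the per-user sum of its member lemmas' TfIDF
#' scores; the penalty is the sum over clusters of the two-sided p-value of
#' the Pearson correlation between the cluster feature and the target.
#' Zero-variance cluster features contribute p = 1.
#'
#' @param partition Named integer vector mapping lemma to cluster id.
#' @param tfidf Users x lemmas TfIDF matrix covering the partition lemmas.
#' @param target Numeric target vector (one value per user).
#' @return Penalty value in \[0, number of clusters\].
#' @export
supervision_penalty <- function(partition, tfidf, target) {
  feats <- cluster_feature_matrix(partition, tfidf)
  p <- pearson_pvalues(feats, target)
  p[is.na(p)] <- 1
  sum(p)
}

# Users x clusters matrix of member-TfIDF sums.
cluster_feature_matrix <- function(partition, tfidf) {
  lemmas <- intersect(names(partition), colnames(tfidf))
  ids <- sort(unique(partition))
  m <- vapply(ids, function(cl) {
    mem <- lemmas[partition[lemmas] == cl]
    if (length(mem) == 0) return(rep(0, nrow(tfidf)))
    rowSums(tfidf[, mem, drop = FALSE])
  }, numeric(nrow(tfidf)))
  m <- matrix(m, nrow = nrow(tfidf))
  colnames(m) <- paste0("cluster", ids)
  m
}

new_cluster_solution <- function(partition, k, weight = 0, threshold = NA,
                                 augmented = FALSE, objective = NA_real_,
                                 inertia = NA_real_) {
  structure(list(partition = partition, k = k,
                 n_clusters = length(unique(partition)), weight = weight,
                 threshold = threshold, augmented = augmented,
                 objective = objective, inertia = inertia),
            class = "swb_clusters")
}

#' @export
print.swb_clusters <- function(x, ...) {
  cat(sprintf(
    "Cluster solution: %d lemmas in %d clusters (weight %s, threshold %s%s)\n",
    length(x$partition), x$n_clusters, format(x$weight),
    ifelse(is.na(x$threshold), "-", format(x$threshold)),
    if (x$augmented) ", augmented" else ""))
  invisible(x)
}

#' Supervision-regularized spherical KMeans over word embeddings
#'
#' Lloyd iterations with cosine distance on unit-normalized vectors. After
#' every iteration the objective J = cosine inertia + weight x supervision
#' penalty is evaluated, and the iterate minimizing J is returned: the
#' penalty steers the choice among iterates rather than the assignment
#' rule. With weight 0 this is plain spherical KMeans.
#'
#' @param embeddings Lemma-named embedding matrix covering the vocabulary.
#' @param k Target number of clusters (default 300). If k >= the
#'   vocabulary size, every lemma becomes its own cluster.
#' @param weight Regularization weight (study grid: 0, 50, 100, 500).
#' @param tfidf,target Heldout TfIDF matrix and target for the penalty
#'   (may be NULL when weight = 0).
#' @param seed Integer seed (initial centroids are sampled rows).
#' @param max_iter Maximum Lloyd iterations.
#' @return A cluster solution (class `swb_clusters`).
#' @export
regularized_kmeans <- function(embeddings, k = 300, weight = 0,
                               tfidf = NULL, target = NULL, seed = 1,
                               max_iter = 25) {
  x <- normalize_rows(embeddings)
  n <- nrow(x)
  if (weight > 0 && (is.null(tfidf) || is.null(target))) {
    stop("weight > 0 needs tfidf and target", call. = FALSE)
  }
  if (k >= n) {
    part <- stats::setNames(seq_len(n), rownames(x))
    pen <- if (weight > 0) supervision_penalty(part, tfidf, target) else 0
    return(new_cluster_solution(part, k, weight, objective = weight * pen,
                                inertia = 0))
  }
  obj_of <- function(assign, inertia) {
    if (weight == 0) return(inertia)
    part <- stats::setNames(assign, rownames(x))
    inertia + weight * supervision_penalty(part, tfidf, target)
  }
  with_seed(seed, {
    centroids <- x[sample.int(n, k), , drop = FALSE]
    best <- NULL
    assign <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      sim <- x %*% t(centroids)
      new_assign <- max.col(sim, ties.method = "first")
      # re-seed empty clusters with the worst-fit points
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty)) {
        worst <- order(sim[cbind(seq_len(n), new_assign)])[seq_along(empty)]
        new_assign[worst] <- empty
        centroids[empty, ] <- x[worst, , drop = FALSE]
        sim <- x %*% t(centroids)
      }
      inertia <- sum(1 - sim[cbind(seq_len(n), new_assign)])
      J <- obj_of(new_assign, inertia)
      if (is.null(best) || J < best$objective) {
        best <- list(assign = new_assign, objective = J, inertia = inertia)
      }
      converged <- all(new_assign == assign)
      assign <- new_assign
      if (converged) break
      for (cl in unique(assign)) {
        ctr <- colMeans(x[assign == cl, , drop = FALSE])
        nrm <- sqrt(sum(ctr^2))
        if (nrm > 0) centroids[cl, ] <- ctr / nrm
      }
    }
    ids <- match(best$assign, sort(unique(best$assign)))
    new_cluster_solution(stats::setNames(ids, rownames(x)), k, weight,
                         objective = best$objective, inertia = best$inertia)
  })
}

#' Consensus of several cluster solutions
#'
#' Builds the co-association fraction for every lemma pair (the share of
#' runs assigning both to one cluster), links pairs reaching `threshold`,
#' and takes connected components of the link graph as consensus clusters.
#' Singleton components are allowed.
#'
#' @param runs List of cluster solutions over the same vocabulary.
#' @param threshold Co-association threshold (study grid: 0.25, 0.45,
#'   0.65, 0.75, 0.85). Values above 1 yield all singletons.
#' @return A consensus cluster solution.
#' @export
consensus_solution <- function(runs, threshold) {
  stopifnot(length(runs) >= 1)
  vocab <- sort(names(runs[[1]]$partition))
  for (r in runs) {
    if (!identical(sort(names(r$partition)), vocab)) {
      stop("runs must partition the same vocabulary", call. = FALSE)
    }
  }
  co <- matrix(0, length(vocab), length(vocab),
               dimnames = list(vocab, vocab))
  for (r in runs) {
    a <- r$partition[vocab]
    co <- co + outer(a, a, "==")
  }
  co <- co / length(runs)
  adj <- (co >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  weight <- runs[[1]]$weight
  new_cluster_solution(stats::setNames(as.integer(comp), vocab),
                       k = runs[[1]]$k, weight = weight,
                       threshold = threshold)
}

#' Ascribe infrequent words to their closest consensus cluster
#'
#' Each infrequent lemma with embedding coverage joins the cluster whose
#' centroid (mean member vector) has maximal cosine similarity; original
#' memberships are unchanged. Lemmas without coverage are skipped with a
#' message.
#'
#' @param solution A cluster solution.
#' @param infrequent Lemmas to ascribe (below the vocabulary min count).
#' @param embeddings Embedding matrix covering members and (ideally) the
#'   infrequent lemmas.
#' @return The augmented twin solution (`augmented = TRUE`).
#' @export
augment_infrequent <- function(solution, infrequent, embeddings) {
  out <- solution
  out$augmented <- TRUE
  infrequent <- setdiff(infrequent, names(solution$partition))
  if (length(infrequent) == 0) return(out)
  cover <- embedding_coverage(embeddings, infrequent)
  if (length(cover$missing)) {
    message("skipping ", length(cover$missing),
            " infrequent lemma(s) without embeddings")
  }
  if (length(cover$covered) == 0) return(out)
  x <- normalize_rows(embeddings)
  ids <- sort(unique(solution$partition))
  centroids <- t(vapply(ids, function(cl) {
    mem <- names(solution$partition)[solution$partition == cl]
    ctr <- colMeans(x[mem, , drop = FALSE])
    ctr / sqrt(sum(ctr^2))
  }, numeric(ncol(x))))
  sim <- x[cover$covered, , drop = FALSE] %*% t(centroids)
  extra <- ids[max.col(sim, ties.method = "first")]
  out$partition <- c(solution$partition,
                     stats::setNames(extra, cover$covered))
  out$n_clusters <- length(unique(out$partition))
  out
}

#' Sweep regularization weights and consensus thresholds
#'
#' For every weight, `n_runs` random clusterings are computed and combined
#' at every threshold, giving |weights| x |thresholds| consensus solutions
#' (20 at the study defaults); when `infrequent` lemmas are supplied, each
#' solution gains an augmented twin (40 candidates).
#'
#' @param embeddings Embedding matrix over the frequent vocabulary.
#' @param tfidf,target Heldout TfIDF matrix and target for the penalty.
#' @param weights Regularization weights (default 0, 50, 100, 500).
#' @param thresholds Consensus thresholds (default 0.25, 0.45, 0.65,
#'   0.75, 0.85).
#' @param seed Integer seed.
#' @param n_runs Random restarts per weight (default 10).
#' @param k Cluster count per run (default 300).
#' @param infrequent Optional infrequent lemmas for augmented twins.
#' @param max_iter Lloyd iteration cap per run.
#' @return List of cluster solutions.
#' @export
sweep_solutions <- function(embeddings, tfidf, target,
                            weights = c(0, 50, 100, 500),
                            thresholds = c(0.25, 0.45, 0.65, 0.75, 0.85),
                            seed = 1, n_runs = 10, k = 300,
                            infrequent = NULL, max_iter = 25) {
  out <- list()
  for (wi in seq_along(weights)) {
    runs <- lapply(seq_len(n_runs), function(r) {
      regularized_kmeans(embeddings, k = k, weight = weights[wi],
                         tfidf = tfidf, target = target,
                         seed = derive_seed(seed, wi * 1000L + r),
                         max_iter = max_iter)
    })
    for (th in thresholds) {
      out[[length(out) + 1]] <- consensus_solution(runs, th)
    }
  }
  if (!is.null(infrequent)) {
    out <- c(out, lapply(out, augment_infrequent, infrequent = infrequent,
                         embeddings = embeddings))
  }
  out
}

#' Select the best cluster solution on a heldout cohort
#'
#' For each candidate: clusters whose feature correlates with the target at
#' p < 0.05 are kept; the surviving features enter a 10-fold RandomForest
#' regression with recursive feature elimination on the heldout cohort; the
#' candidate with the lowest fold-averaged test MAE wins. Candidates with
#' no surviving cluster get infinite MAE.
#'
#' @param candidates List of cluster solutions (e.g. [sweep_solutions()]).
#' @param tfidf Heldout users x lemmas TfIDF matrix.
#' @param target Heldout target values.
#' @param seed Integer seed for fold construction and forests.
#' @param n_folds Cross-validation folds (default 10).
#' @param ntree RandomForest size (default 100).
#' @param p_filter Correlation p-value filter (default 0.05).
#' @return List with `best` (the winning solution), `metadata` (one row per
#'   candidate: regularization weight, consensus threshold, infrequent-word
#'   flag, number of clusters after filtering, MAE) and `best_row`.
#' @export
select_best_solution <- function(candidates, tfidf, target, seed = 1,
                                 n_folds = 10, ntree = 100,
                                 p_filter = 0.05) {
  stopifnot(length(candidates) >= 1)
  rows <- vector("list", length(candidates))
  maes <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    feats <- cluster_feature_matrix(cand$partition, tfidf)
    p <- pearson_pvalues(feats, target)
    keep <- !is.na(p) & p < p_filter
    n_kept <- sum(keep)
    if (n_kept == 0) {
      message("candidate ", ci, ": no cluster passes the p < ", p_filter,
              " filter; assigned worst MAE")
      maes[ci] <- Inf
    } else {
      maes[ci] <- heldout_rf_mae(feats[, keep, drop = FALSE], target,
                                 seed = derive_seed(seed, ci),
                                 n_folds = n_folds, ntree = ntree)
    }
    rows[[ci]] <- data.frame(
      weight = cand$weight, threshold = cand$threshold,
      infrequent = ifelse(cand$augmented, "+", "-"),
      n_clusters = n_kept, mae = maes[ci], stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, rows)
  best_i <- which.min(maes)
  list(best = candidates[[best_i]], metadata = metadata,
       best_row = metadata[best_i, ])
}

# Fold-averaged test MAE of an RFE-assisted RandomForest regression,
# carving a dev fifth out of each training fold to guide the elimination.
heldout_rf_mae <- function(x, y, seed, n_folds = 10, ntree = 100) {
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  spec <- model_spec("rf", params = list(ntree = ntree))
  mae <- vapply(seq_len(n_folds), function(f) {
    test <- which(folds == f)
    tr <- setdiff(seq_len(n), test)
    dev <- tr[seq_len(max(1, floor(length(tr) / 5)))]
    fit_idx <- setdiff(tr, dev)
    sel <- run_rfe(spec, x[fit_idx, , drop = FALSE], y[fit_idx],
                   x[dev, , drop = FALSE], y[dev], task = "regression",
                   seed = derive_seed(seed, f))
    fit <- fit_swb_model(spec, x[tr, sel, drop = FALSE], y[tr],
                         task = "regression", seed = derive_seed(seed, f))
    mean(abs(predict_swb_model(fit, x[test, sel, drop = FALSE]) - y[test]))
  }, numeric(1))
  mean(mae)
}
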