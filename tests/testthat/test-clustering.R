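make_tfidf_fixture <- function(n_users, vocab, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_users * length(vocab)), n_users, length(vocab))
  colnames(m) <- vocab
  m
}

test_that("the supervision penalty tracks cluster-target correlation", {
  set.seed(3)
  n <- 80
  vocab <- c("s1", "s2", paste0("n", 1:10))
  target <- rnorm(n)
  tfidf <- make_tfidf_fixture(n, vocab, 4)
  tfidf[, "s1"] <- target + rnorm(n, 0, 0.01)
  tfidf[, "s2"] <- target + rnorm(n, 0, 0.01)
  part <- setNames(c(1, 1, rep(2:6, each = 2)), vocab)
  pen <- supervision_penalty(part, tfidf, target)
  n_clusters <- length(unique(part))
  expect_lt(pen, n_clusters) # bounded above by one per cluster
  # the correlated cluster contributes essentially nothing
  pen_noise <- supervision_penalty(part[-(1:2)], tfidf[, -(1:2)], target)
  expect_lt(pen - pen_noise, 0.01)
  # a zero-variance cluster feature counts as p = 1
  flat <- matrix(1, n, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(supervision_penalty(setNames(c(1, 1), c("f1", "f2")),
                                   flat, target), 1)
})

test_that("null cluster features give a near-uniform penalty", {
  set.seed(11)
  n_clusters <- 60
  n <- 100
  pens <- replicate(5, {
    vocab <- paste0("w", seq_len(n_clusters))
    tfidf <- make_tfidf_fixture(n, vocab, sample.int(1e6, 1))
    part <- setNames(seq_len(n_clusters), vocab)
    supervision_penalty(part, tfidf, rnorm(n))
  })
  expect_lt(abs(mean(pens) / n_clusters - 0.5), 0.1)
})

test_that("unregularized spherical kmeans recovers planted blobs", {
  vocab <- sprintf("w%03d", 1:40)
  blobs <- list(vocab[1:20], vocab[21:40])
  truth <- rep(1:2, each = 20)
  hits <- vapply(1:100, function(s) {
    emb <- random_embeddings(vocab, dim = 8, seed = s, blobs = blobs,
                             blob_sd = 0.15)
    sol <- regularized_kmeans(emb, k = 2, seed = s)
    mclust::adjustedRandIndex(sol$partition[vocab], truth) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("weight zero reduces the objective to cosine inertia", {
  vocab <- sprintf("w%03d", 1:30)
  emb <- random_embeddings(vocab, dim = 6, seed = 2)
  sol <- regularized_kmeans(emb, k = 4, seed = 9)
  expect_equal(sol$objective, sol$inertia)
  expect_setequal(names(sol$partition), vocab)
  # k at or above the vocabulary size: singletons with zero inertia
  single <- regularized_kmeans(emb, k = 50, seed = 1)
  expect_equal(single$n_clusters, 30)
  expect_equal(single$inertia, 0)
})

test_that("the penalty steers selection among candidate partitions", {
  set.seed(21)
  vocab <- sprintf("w%03d", 1:24)
  emb <- random_embeddings(vocab, dim = 6, seed = 7,
                           blobs = list(vocab[1:12], vocab[13:24]),
                           blob_sd = 0.2)
  n <- 60
  target <- rnorm(n)
  tfidf <- make_tfidf_fixture(n, vocab, 8)
  # cluster 1's summed tfidf correlates strongly with the target
  for (w in vocab[1:12]) tfidf[, w] <- target / 12 + rnorm(n, 0, 0.05)
  sol <- regularized_kmeans(emb, k = 2, weight = 100, tfidf = tfidf,
                            target = target, seed = 3)
  expect_true(is.finite(sol$objective))
  expect_gte(sol$objective, sol$inertia)
})

test_that("consensus of identical runs returns that partition", {
  vocab <- letters[1:8]
  part <- setNames(c(1, 1, 2, 2, 2, 3, 3, 3), vocab)
  runs <- replicate(10, new_sol <- structure(
    list(partition = part, k = 3, weight = 0, threshold = NA,
         augmented = FALSE), class = "swb_clusters"), simplify = FALSE)
  cons <- consensus_solution(runs, 0.45)
  expect_true(same_partition(cons$partition, part))
  # threshold above 1 severs every link
  singles <- consensus_solution(runs, 1.5)
  expect_equal(singles$n_clusters, 8)
})

test_that("consensus components match the brute-force graph oracle", {
  set.seed(6)
  vocab <- letters[1:5]
  for (rep in 1:10) {
    runs <- lapply(1:4, function(i) {
      structure(list(partition = setNames(sample(1:3, 5, TRUE), vocab),
                     k = 3, weight = 0, threshold = NA, augmented = FALSE),
                class = "swb_clusters")
    })
    for (th in c(0.25, 0.45, 0.75)) {
      cons <- consensus_solution(runs, th)
      oracle <- components_oracle(runs, th)
      expect_true(same_partition(cons$partition, oracle))
    }
  }
})

test_that("higher thresholds only break links, never merge clusters", {
  set.seed(9)
  vocab <- sprintf("w%02d", 1:12)
  runs <- lapply(1:6, function(i) {
    structure(list(partition = setNames(sample(1:4, 12, TRUE), vocab),
                   k = 4, weight = 0, threshold = NA, augmented = FALSE),
              class = "swb_clusters")
  })
  lo <- consensus_solution(runs, 0.25)
  hi <- consensus_solution(runs, 0.75)
  expect_gte(hi$n_clusters, lo$n_clusters)
  # refinement: every high-threshold cluster sits inside one low cluster
  for (cl in unique(hi$partition)) {
    mem <- names(hi$partition)[hi$partition == cl]
    expect_equal(length(unique(lo$partition[mem])), 1)
  }
})

test_that("infrequent words join their nearest cluster by cosine", {
  vocab <- c("a1", "a2", "b1", "b2")
  emb <- rbind(
    a1 = c(1, 0, 0), a2 = c(0.9, 0.1, 0),
    b1 = c(0, 1, 0), b2 = c(0, 0.9, 0.1),
    x_near_a = c(1, 0, 0), x_near_b = c(0.05, 1, 0)
  )
  sol <- structure(list(partition = setNames(c(1, 1, 2, 2), vocab),
                        k = 2, n_clusters = 2, weight = 0, threshold = NA,
                        augmented = FALSE), class = "swb_clusters")
  aug <- suppressMessages(
    augment_infrequent(sol, c("x_near_a", "x_near_b", "x_missing"), emb))
  expect_true(aug$augmented)
  expect_equal(unname(aug$partition[["x_near_a"]]), 1)
  expect_equal(unname(aug$partition[["x_near_b"]]), 2)
  expect_false("x_missing" %in% names(aug$partition))
  expect_equal(aug$partition[vocab], sol$partition)
  # brute-force check of every assignment against all centroids
  xn <- emb / sqrt(rowSums(emb^2))
  for (w in c("x_near_a", "x_near_b")) {
    sims <- vapply(1:2, function(cl) {
      mem <- vocab[sol$partition == cl]
      ctr <- colMeans(xn[mem, , drop = FALSE])
      sum(xn[w, ] * ctr / sqrt(sum(ctr^2)))
    }, numeric(1))
    expect_equal(unname(aug$partition[[w]]), which.max(sims))
  }
  # no infrequent lemmas: unchanged but flagged
  noop <- augment_infrequent(sol, character(0), emb)
  expect_true(noop$augmented)
  expect_equal(noop$partition, sol$partition)
})

test_that("the weight-by-threshold sweep emits consensus solutions and twins", {
  vocab <- sprintf("w%03d", 1:30)
  emb <- random_embeddings(vocab, dim = 6, seed = 5)
  tfidf <- make_tfidf_fixture(40, vocab, 2)
  target <- rnorm(40)
  one <- sweep_solutions(emb, tfidf, target, weights = 0, thresholds = 0.45,
                         seed = 3, n_runs = 3, k = 4, max_iter = 5)
  expect_length(one, 1)
  paired <- sweep_solutions(emb, tfidf, target, weights = 0,
                            thresholds = 0.45, seed = 3, n_runs = 3, k = 4,
                            infrequent = "w031", max_iter = 5)
  expect_length(paired, 2)
  expect_false(paired[[1]]$augmented)
  expect_true(paired[[2]]$augmented)
  for (sol in paired) {
    expect_true(all(vocab %in% names(sol$partition)))
  }
})

test_that("solution selection prefers candidates carrying planted signal", {
  set.seed(31)
  vocab <- sprintf("w%03d", 1:12)
  wins <- 0
  n_sims <- 50
  for (sim in 1:n_sims) {
    n <- 80
    target <- rnorm(n)
    tfidf <- make_tfidf_fixture(n, vocab, 1000 + sim)
    # candidate A groups the signal words together; B scatters them
    for (w in vocab[1:4]) tfidf[, w] <- target / 4 + rnorm(n, 0, 0.35)
    cand_signal <- structure(
      list(partition = setNames(c(rep(1, 4), rep(2:5, each = 2)), vocab),
           k = 5, weight = 0, threshold = 0.45, augmented = FALSE),
      class = "swb_clusters")
    cand_noise <- structure(
      list(partition = setNames(rep(1:4, times = 3), vocab),
           k = 4, weight = 50, threshold = 0.45, augmented = FALSE),
      class = "swb_clusters")
    res <- suppressMessages(select_best_solution(
      list(signal = cand_signal, noise = cand_noise), tfidf, target,
      seed = sim, n_folds = 5, ntree = 25))
    if (res$best_row$weight == 0) wins <- wins + 1
  }
  expect_gte(wins / n_sims, 0.9)
})

test_that("selection metadata mirrors the reporting fields", {
  set.seed(12)
  vocab <- sprintf("w%03d", 1:8)
  tfidf <- make_tfidf_fixture(50, vocab, 3)
  target <- rowSums(tfidf[, 1:2]) + rnorm(50, 0, 0.2)
  cand <- structure(
    list(partition = setNames(rep(1:4, each = 2), vocab),
         k = 4, weight = 100, threshold = 0.65, augmented = TRUE),
    class = "swb_clusters")
  res <- select_best_solution(list(cand), tfidf, target, seed = 2,
                              n_folds = 4, ntree = 25)
  expect_identical(names(res$metadata),
                   c("weight", "threshold", "infrequent", "n_clusters",
                     "mae"))
  expect_identical(res$metadata$infrequent, "+")
  expect_identical(res$best, cand)
})

test_that("the word2vec text reader round-trips an embedding file", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 4",
               "alpha 1 0 0 0",
               "beta 0 2 0 0",
               "gamma 0 0 1 1"), path)
  emb <- read_word2vec(path)
  expect_equal(rownames(emb), c("alpha", "beta", "gamma"))
  expect_equal(unname(rowSums(emb^2)), rep(1, 3))
  expect_equal(unname(emb["beta", ]), c(0, 1, 0, 0))
  cov <- embedding_coverage(emb, c("alpha", "delta"))
  expect_equal(cov$covered, "alpha")
  expect_equal(cov$missing, "delta")
  bad <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("1 2", "zero 0 0"), bad)
  expect_error(read_word2vec(bad), "zero embedding")
})
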