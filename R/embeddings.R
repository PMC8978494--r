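#' Deterministic random embeddings, optionally with planted blobs
#'
#' A stand-in embedding provider for synthetic cohorts: each lemma gets a
#' reproducible random vector (seeded from the lemma string itself, so the
#' lookup does not depend on the vocabulary it is requested with). Planted
#' blob structure places each group of lemmas around a common random center
#' at a given dispersion, giving clusterable geometry on demand.
#'
#' @param vocab Character vector of lemmas.
#' @param dim Embedding dimensionality (default 300).
#' @param seed Integer seed.
#' @param blobs Optional list of character vectors; each element's lemmas
#'   are placed around one shared center.
#' @param blob_sd Within-blob dispersion relative to unit centers.
#' @return Numeric matrix, one row per lemma, rows unit-normalized.
#' @export
random_embeddings <- function(vocab, dim = 300, seed = 1, blobs = NULL,
                              blob_sd = 0.1) {
  lemma_vec <- function(lemma, center = NULL, sd = 1) {
    h <- sum(utf8ToInt(lemma) * seq_along(utf8ToInt(lemma)))
    with_seed(derive_seed(seed, h %% 1000000L), {
      v <- stats::rnorm(dim, 0, sd)
      if (!is.null(center)) v <- center + v
      v
    })
  }
  centers <- list()
  if (!is.null(blobs)) {
    for (b in seq_along(blobs)) {
      centers[[b]] <- with_seed(derive_seed(seed, 2000000L + b),
                                stats::rnorm(dim))
      centers[[b]] <- centers[[b]] / sqrt(sum(centers[[b]]^2))
    }
  }
  m <- matrix(0, length(vocab), dim, dimnames = list(vocab, NULL))
  for (w in vocab) {
    ctr <- NULL; sd <- 1
    if (!is.null(blobs)) {
      hit <- which(vapply(blobs, function(b) w %in% b, logical(1)))
      if (length(hit)) { ctr <- centers[[hit[1]]]; sd <- blob_sd }
    }
    m[w, ] <- lemma_vec(w, ctr, sd)
  }
  normalize_rows(m)
}

#' Read word embeddings in word2vec text format
#'
#' The format: a header line `n dim`, then one line per lemma with `dim`
#' whitespace-separated values.
#'
#' @param path Path to the text-format embedding file.
#' @return Numeric matrix with lemma rownames, rows unit-normalized.
#' @export
read_word2vec <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  header <- scan(con, what = integer(), n = 2, quiet = TRUE)
  n <- header[1]; d <- header[2]
  m <- matrix(NA_real_, n, d)
  lemmas <- character(n)
  for (i in seq_len(n)) {
    parts <- scan(con, what = character(), n = d + 1, quiet = TRUE)
    lemmas[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  rownames(m) <- lemmas
  normalize_rows(m)
}

# Unit-normalize rows; zero vectors are rejected at load.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("zero embedding vector for: ",
         paste(utils::head(rownames(m)[nrm == 0]), collapse = ", "),
         call. = FALSE)
  }
  m / nrm
}

#' Embedding coverage report
#'
#' @param embeddings Embedding matrix with lemma rownames.
#' @param vocab Lemmas to look up.
#' @return List with `covered` and `missing` lemma vectors.
#' @export
embedding_coverage <- function(embeddings, vocab) {
  list(covered = intersect(vocab, rownames(embeddings)),
       missing = setdiff(vocab, rownames(embeddings)))
}
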