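#' Read a two-column lexicon (lemma, tag) from TSV
#'
#' @param path Path to a tab-separated file with columns `lemma` and `tag`.
#' @return Data frame with unique lemmas.
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("lemma", "tag") %in% names(lex))) {
    stop("lexicon needs columns 'lemma' and 'tag'", call. = FALSE)
  }
  if (anyDuplicated(lex$lemma)) {
    stop("duplicate lemmas in lexicon", call. = FALSE)
  }
  lex
}

#' Concatenate message streams into per-user token documents
#'
#' @param messages Message data frame (`user_id`, `timestamp`, list column
#'   `tokens`) as produced by [generate_cohort()].
#' @param user_ids Users to materialize (defaults to those present); users
#'   without messages get empty documents.
#' @return Named list of data frames, one per user, with columns `token`
#'   and `timestamp`.
#' @export
user_documents <- function(messages, user_ids = NULL) {
  if (is.null(user_ids)) user_ids <- unique(messages$user_id)
  lens <- lengths(messages$tokens)
  long <- data.frame(
    user_id = rep(messages$user_id, lens),
    token = unlist(messages$tokens, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long$timestamp <- rep(messages$timestamp, lens)
  out <- split(long[c("token", "timestamp")], factor(long$user_id, user_ids))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Sentiment proportions over three backward time windows
#'
#' For each of the windows (30 days, 365 days, entire history) measured
#' backward from `reference_time` and each polarity, the proportion of
#' window tokens carrying that polarity; 0 when the window holds no tokens.
#'
#' @param document One [user_documents()] entry (`token`, `timestamp`).
#' @param lexicon Sentiment lexicon with tags `positive` and `negative`.
#' @param reference_time The user's reference timestamp.
#' @return Named numeric vector of 6 features
#'   (`Positive_month`, `Negative_month`, ..., `Negative_all`).
#' @export
sentiment_proportions <- function(document, lexicon, reference_time) {
  stopifnot(all(c("positive", "negative") %in% lexicon$tag))
  pos <- lexicon$lemma[lexicon$tag == "positive"]
  neg <- lexicon$lemma[lexicon$tag == "negative"]
  windows <- list(month = 30 * 86400, year = 365 * 86400, all = Inf)
  out <- numeric(0)
  for (w in names(windows)) {
    age <- as.numeric(reference_time) - as.numeric(document$timestamp)
    tok <- document$token[age <= windows[[w]] & age >= 0]
    total <- length(tok)
    out[paste0("Positive_", w)] <- if (total) sum(tok %in% pos) / total else 0
    out[paste0("Negative_", w)] <- if (total) sum(tok %in% neg) / total else 0
  }
  out
}

#' Fit a TfIDF model over per-user documents
#'
#' The vocabulary keeps lemmas whose total corpus frequency is at least
#' `min_count`; the score of word w in document d is
#' `count(w, d) * ln(N / df(w))` with N the number of fitting documents
#' and df the document frequency (no length normalization).
#'
#' @param documents List of [user_documents()] entries, or a list of
#'   character token vectors.
#' @param min_count Minimum corpus frequency for vocabulary inclusion
#'   (default 200; use 1 for an unrestricted vocabulary).
#' @return An object of class `swb_tfidf` with `vocabulary`, `df` and
#'   `n_documents`.
#' @export
fit_tfidf <- function(documents, min_count = 200) {
  toks <- lapply(documents, function(d) if (is.data.frame(d)) d$token else d)
  if (length(toks) < 2) stop("need at least 2 documents", call. = FALSE)
  freq <- table(unlist(toks, use.names = FALSE))
  vocab <- sort(names(freq)[freq >= min_count])
  if (length(vocab) == 0) {
    stop("min_count = ", min_count, " leaves an empty vocabulary",
         call. = FALSE)
  }
  df <- vapply(vocab, function(w)
    sum(vapply(toks, function(tk) w %in% tk, logical(1))), numeric(1))
  structure(list(vocabulary = vocab, df = df, n_documents = length(toks)),
            class = "swb_tfidf")
}

#' Score documents under a fitted TfIDF model
#'
#' @param model A [fit_tfidf()] model.
#' @param documents List of documents (as in [fit_tfidf()]); a single
#'   character vector is treated as one document.
#' @return Numeric matrix, documents in rows, vocabulary lemmas in columns.
#' @export
tfidf_matrix <- function(model, documents) {
  stopifnot(inherits(model, "swb_tfidf"))
  if (is.character(documents)) documents <- list(documents)
  if (is.data.frame(documents)) documents <- list(documents)
  toks <- lapply(documents, function(d) if (is.data.frame(d)) d$token else d)
  idf <- log(model$n_documents / model$df)
  m <- t(vapply(toks, function(tk) {
    counts <- table(factor(tk, levels = model$vocabulary))
    as.numeric(counts) * idf
  }, numeric(length(model$vocabulary))))
  colnames(m) <- model$vocabulary
  rownames(m) <- names(documents)
  m
}

#' Select target-associated words on a heldout cohort
#'
#' For every vocabulary word and every target, the word's TfIDF column is
#' tested against the target with the F-test of the univariate linear
#' regression (equivalent to the two-sided Pearson-correlation test); words
#' with p <= `alpha` are kept. Zero-variance columns are excluded with a
#' note. The union of the per-target lists is the modeling feature set.
#'
#' @param tfidf Heldout TfIDF matrix (users x words).
#' @param targets Named list of normalized target vectors (e.g.
#'   `list(swls = ..., who5 = ...)`).
#' @param alpha Significance level (default 0.01).
#' @return List with `per_target` (named list of selected lemma vectors),
#'   `union`, and `excluded` (zero-variance lemmas).
#' @export
anova_select_words <- function(tfidf, targets, alpha = 0.01) {
  if (!is.list(targets)) targets <- list(target = targets)
  if (ncol(tfidf) == 0) {
    return(list(per_target = lapply(targets, function(...) character(0)),
                union = character(0), excluded = character(0)))
  }
  sds <- apply(tfidf, 2, stats::sd)
  excluded <- colnames(tfidf)[sds == 0]
  if (length(excluded)) {
    message("excluding ", length(excluded), " zero-variance word column(s)")
  }
  keep <- tfidf[, sds > 0, drop = FALSE]
  per_target <- lapply(targets, function(y) {
    p <- pearson_pvalues(keep, y)
    colnames(keep)[!is.na(p) & p <= alpha]
  })
  list(per_target = per_target,
       union = sort(unique(unlist(per_target, use.names = FALSE))),
       excluded = excluded)
}

#' Lexicon-category features as TfIDF sums
#'
#' For each of the eight lexicon categories, the sum of the user's TfIDF
#' scores over the category's lemmas. The TfIDF model must cover the full
#' vocabulary (fit with `min_count = 1`): category sums deliberately count
#' all words regardless of frequency.
#'
#' @param document One [user_documents()] entry or token vector.
#' @param category_lexicon Lexicon with tags in the eight categories.
#' @param tfidf_model A full-vocabulary [fit_tfidf()] model.
#' @return Named numeric vector, one feature per category.
#' @export
lexicon_category_features <- function(document, category_lexicon,
                                      tfidf_model) {
  cats <- swb_lexicon_categories()
  extra <- setdiff(unique(category_lexicon$tag), cats)
  if (length(extra)) {
    stop("unknown lexicon categories: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  scores <- tfidf_matrix(tfidf_model, list(document))[1, ]
  vapply(cats, function(cl) {
    lem <- intersect(category_lexicon$lemma[category_lexicon$tag == cl],
                     names(scores))
    sum(scores[lem])
  }, numeric(1))
}

#' The eight lexicon category labels
#' @return Character vector of category labels.
#' @export
swb_lexicon_categories <- function() {
  c("Bio", "Cognitive", "Social", "Time", "Percept", "Feel", "Hear", "See")
}

#' Category lexicon matching the synthetic vocabulary
#'
#' Deterministically assigns a slice of the neutral synthetic vocabulary to
#' each of the eight categories.
#'
#' @param config A [cohort_config()].
#' @param words_per_category Lemmas per category.
#' @return Data frame with columns `lemma` and `tag`.
#' @export
default_category_lexicon <- function(config, words_per_category = 12) {
  v <- config_vocab(config)$neutral
  cats <- swb_lexicon_categories()
  need <- length(cats) * words_per_category
  if (need > length(v)) stop("vocabulary too small for the category lexicon",
                             call. = FALSE)
  data.frame(lemma = v[seq_len(need)],
             tag = rep(cats, each = words_per_category),
             stringsAsFactors = FALSE)
}
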