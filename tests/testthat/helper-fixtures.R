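# Small cohorts and toy streams shared across tests; everything is built in
# code at run time.

small_cohort <- function(n = 30, seed = 7, message_rate = 50,
                         usage_rate = 30, ...) {
  generate_cohort(cohort_config(n, seed = seed, message_rate = message_rate,
                                usage_rate = usage_rate, ...))
}

# A users-only cohort (no trace streams) for score-level work.
score_cohort <- function(n, seed, ...) {
  generate_cohort(cohort_config(n, seed = seed, message_rate = 0,
                                usage_rate = 0, ...))
}

# One usage event at a given local clock time on an arbitrary day.
usage_event <- function(hhmm, duration_s, package = "app.game.1",
                        day = "2021-06-02") {
  data.frame(
    user_id = "u1", package = package,
    start = as.POSIXct(paste(day, hhmm), tz = "UTC"),
    duration_ms = as.integer(duration_s * 1000),
    stringsAsFactors = FALSE
  )
}

# Messages at fixed ages (in days) before a reference time.
message_stream <- function(ages_days, alters, tokens, reference_time) {
  out <- data.frame(
    user_id = rep("u1", length(ages_days)),
    alter_id = alters,
    timestamp = reference_time - ages_days * 86400,
    stringsAsFactors = FALSE
  )
  out$tokens <- tokens
  out
}

ref_time <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")

# Exhaustive-counting oracle for screening confusion rates.
confusion_oracle <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    screen <- scores[i] < cutoff
    if (screen && labels[i]) tp <- tp + 1
    if (screen && !labels[i]) fp <- fp + 1
    if (!screen && !labels[i]) tn <- tn + 1
    if (!screen && labels[i]) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Brute-force connected components of the >= threshold co-association graph.
components_oracle <- function(runs, threshold) {
  vocab <- sort(names(runs[[1]]$partition))
  n <- length(vocab)
  co <- matrix(0, n, n)
  for (r in runs) {
    a <- r$partition[vocab]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (a[i] == a[j]) co[i, j] <- co[i, j] + 1
    }
  }
  co <- co / length(runs)
  linked <- co >= threshold
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(linked[v, ] & comp == 0 & seq_len(n) != v))
    }
  }
  stats::setNames(comp, vocab)
}

# TRUE when two partitions induce the same grouping (up to label renaming).
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  identical(as.integer(match(a, unique(a))),
            as.integer(match(b, unique(b))))
}
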