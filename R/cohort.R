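#' Configuration of a synthetic digital-trace cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study conditions the pipeline is designed for: well-being scores
#' skewed low with an inter-scale Pearson correlation near 0.568, private
#' message streams carrying planted word and negative-sentiment associations
#' with well-being, one week of app-usage sessions whose night-time share
#' shifts with WHO-5, and depression/anxiety/stress questionnaire scores
#' noisily and monotonically decreasing in WHO-5.
#'
#' @param n_users Number of users (>= 0).
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @param scale_corr Target Pearson correlation between the normalized SWLS
#'   and WHO-5 scores (default 0.568).
#' @param swb_location,swb_spread Mean and standard deviation of the latent
#'   Beta-distributed well-being score on the normalized (0, 1) scale.
#' @param vocab_size Number of neutral vocabulary lemmas.
#' @param n_sentiment_words Total sentiment lemmas (split evenly between
#'   positive and negative polarity).
#' @param planted_word_effects Named numeric vector mapping lemma to a signed
#'   effect size: positive effects make the lemma more frequent for happier
#'   users, negative effects for unhappier users.
#' @param sentiment_effect Strength of the latent well-being modulation of
#'   sentiment-word rates (0 disables it).
#' @param message_rate Mean messages per user per year.
#' @param n_alters_mean Mean number of distinct correspondents per user.
#' @param app_categories Exactly nine app-category labels.
#' @param usage_rate Mean app sessions per user over the 7-day window.
#' @param circadian_effect Signed effect of (standardized) WHO-5 on the
#'   night-time (0-6 h) share of app usage; positive values concentrate
#'   night usage among low-WHO-5 users.
#' @param mh_noise Noise multiplier of the questionnaire-score link to WHO-5
#'   (1 = calibrated default; 0 = deterministic link).
#' @param observation_days Length of the app-usage observation window.
#' @return An object of class `swb_config`.
#' @export
cohort_config <- function(n_users,
                          seed = 1L,
                          scale_corr = 0.568,
                          swb_location = 0.46,
                          swb_spread = 0.19,
                          vocab_size = 500L,
                          n_sentiment_words = 60L,
                          planted_word_effects = c(plant_neg = -1, plant_pos = 1),
                          sentiment_effect = 0.5,
                          message_rate = 2000,
                          n_alters_mean = 15,
                          app_categories = swb_app_categories(),
                          usage_rate = 100,
                          circadian_effect = 0.8,
                          mh_noise = 1,
                          observation_days = 7) {
  fail <- function(field, why) {
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  }
  if (length(n_users) != 1 || is.na(n_users) || n_users < 0 ||
      n_users != floor(n_users)) fail("n_users", "must be a non-negative integer")
  if (length(seed) != 1 || is.na(seed)) fail("seed", "must be an integer")
  if (abs(scale_corr) >= 1) fail("scale_corr", "must lie in (-1, 1)")
  if (swb_location <= 0 || swb_location >= 1)
    fail("swb_location", "must lie in (0, 1)")
  if (swb_spread <= 0) fail("swb_spread", "must be positive")
  if (length(app_categories) != 9 || anyDuplicated(app_categories))
    fail("app_categories", "exactly 9 distinct labels required")
  for (f in c("message_rate", "n_alters_mean", "usage_rate", "mh_noise",
              "observation_days")) {
    v <- get(f)
    if (length(v) != 1 || is.na(v) || v < 0) fail(f, "must be >= 0")
  }
  if (vocab_size < 1) fail("vocab_size", "must be >= 1")
  if (n_sentiment_words < 2 || n_sentiment_words %% 2 != 0)
    fail("n_sentiment_words", "must be an even count >= 2")
  if (length(planted_word_effects) &&
      is.null(names(planted_word_effects)))
    fail("planted_word_effects", "must be a named numeric vector")
  # fails early if the Beta family cannot realize the location/spread pair
  beta_shapes(swb_location, swb_spread)
  structure(list(
    n_users = as.integer(n_users), seed = as.integer(seed),
    scale_corr = scale_corr, swb_location = swb_location,
    swb_spread = swb_spread, vocab_size = as.integer(vocab_size),
    n_sentiment_words = as.integer(n_sentiment_words),
    planted_word_effects = planted_word_effects,
    sentiment_effect = sentiment_effect,
    message_rate = message_rate, n_alters_mean = n_alters_mean,
    app_categories = app_categories, usage_rate = usage_rate,
    circadian_effect = circadian_effect, mh_noise = mh_noise,
    observation_days = observation_days
  ), class = "swb_config")
}

#' The nine app-category labels
#' @return Character vector of the nine category labels.
#' @export
swb_app_categories <- function() {
  c("Game", "Education+Productivity", "Tools", "Entertainment",
    "Personalization", "Health+Medical", "Social+Communication+Dating",
    "Photography", "Other")
}

# Sentiment and planted lemma inventories implied by a config.
config_vocab <- function(config) {
  half <- config$n_sentiment_words %/% 2L
  list(
    neutral = sprintf("w%04d", seq_len(config$vocab_size)),
    positive = sprintf("pos%03d", seq_len(half)),
    negative = sprintf("neg%03d", seq_len(half)),
    planted = names(config$planted_word_effects)
  )
}

#' Sentiment lexicon matching the synthetic vocabulary
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `lemma` and `tag` (polarity).
#' @export
default_sentiment_lexicon <- function(config) {
  v <- config_vocab(config)
  data.frame(
    lemma = c(v$positive, v$negative),
    tag = rep(c("positive", "negative"), c(length(v$positive),
                                           length(v$negative))),
    stringsAsFactors = FALSE
  )
}

# Questionnaire links: score = intercept + slope * (0.51 - who5_norm) + noise,
# rounded and clipped to the instrument range. Slopes and base noise were
# fixed by forward calibration so that the binary screening regime at the
# 0.51 cutoff (high sensitivity, moderate specificity) is realized.
mh_link_params <- function() {
  list(
    phq = list(intercept = 9.5, slope = 17.5, sd = 3.5, range = c(0, 27)),
    gad = list(intercept = 9.5, slope = 15.0, sd = 3.0, range = c(0, 21)),
    pss = list(intercept = 20.5, slope = 18.0, sd = 3.0, range = c(0, 40))
  )
}

# Completion probabilities of the three questionnaires (mirroring the
# differing per-condition sample sizes of a partially-completed battery).
mh_completion <- c(phq = 0.825, gad = 0.741, pss = 0.775)

#' Generate noisy mental-health questionnaire scores from normalized WHO-5
#'
#' Each score is a monotonically decreasing linear function of the
#' normalized WHO-5 value plus Gaussian noise, rounded and clipped to the
#' instrument range (PHQ-9 0-27, GAD 0-21, PSS 0-40).
#'
#' @param who5_norm Normalized WHO-5 values in \[0, 1\].
#' @param config A [cohort_config()]; only `mh_noise` is used.
#' @param seed Integer seed.
#' @param missing If `TRUE`, each questionnaire is missing at random at the
#'   per-instrument completion rates.
#' @return Data frame with columns `phq`, `gad`, `pss`.
#' @export
generate_mh_scores <- function(who5_norm, config, seed, missing = FALSE) {
  stopifnot(all(who5_norm >= 0 & who5_norm <= 1))
  n <- length(who5_norm)
  with_seed(seed, {
    out <- lapply(mh_link_params(), function(p) {
      x <- p$intercept + p$slope * (0.51 - who5_norm) +
        stats::rnorm(n, 0, config$mh_noise * p$sd)
      pmin(pmax(round(x), p$range[1]), p$range[2])
    })
    out <- as.data.frame(out)
    if (missing) {
      for (s in names(out)) {
        out[[s]][stats::runif(n) >= mh_completion[[s]]] <- NA
      }
    }
    out
  })
}

#' Generate a message stream for one user
#'
#' Message counts follow a Poisson law at `message_rate` per year with a
#' mild seasonal intensity; timestamps fall in the 365 days preceding the
#' user's reference time. Alters are drawn from a Dirichlet-multinomial so
#' correspondent counts vary. Tokens mix a Zipf-weighted neutral vocabulary,
#' sentiment lemmas whose rates are modulated by latent well-being, and
#' planted-effect lemmas.
#'
#' @param user A single-row user record carrying `user_id`, `reference_time`
#'   and the standardized latent well-being `z_swb`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `user_id`, `alter_id`, `timestamp` and a
#'   list column `tokens`.
#' @export
generate_messages <- function(user, config, seed) {
  stopifnot(!is.null(user$reference_time))
  empty <- data.frame(user_id = character(), alter_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE)
  empty$tokens <- list()
  if (config$message_rate <= 0) return(empty)
  v <- config_vocab(config)
  z <- user$z_swb
  with_seed(seed, {
    n_msg <- stats::rpois(1, config$message_rate)
    if (n_msg == 0) return(empty)
    # seasonal arrival density 1 + 0.3 sin(2 pi u) over the year, by rejection
    ages <- numeric(0)
    while (length(ages) < n_msg) {
      u <- stats::runif(2 * n_msg)
      keep <- stats::runif(length(u)) < (1 + 0.3 * sin(2 * pi * u)) / 1.3
      ages <- c(ages, u[keep])
    }
    ages <- ages[seq_len(n_msg)]
    ts <- user$reference_time - ages * 365 * 86400
    n_alt <- 1 + stats::rpois(1, max(config$n_alters_mean - 1, 0))
    alt_w <- stats::rgamma(n_alt, 1)
    alters <- sprintf("%s_a%03d", user$user_id,
                      sample.int(n_alt, n_msg, replace = TRUE,
                                 prob = alt_w / sum(alt_w)))
    lemmas <- c(v$neutral, v$positive, v$negative, v$planted)
    w_neutral <- (1 / seq_along(v$neutral))
    w_neutral <- w_neutral / sum(w_neutral)
    base_sent <- 0.05
    w_pos <- rep(base_sent * exp(config$sentiment_effect * z) /
                   length(v$positive), length(v$positive))
    w_neg <- rep(base_sent * exp(-config$sentiment_effect * z) /
                   length(v$negative), length(v$negative))
    w_plant <- 0.01 * exp(config$planted_word_effects * z)
    probs <- c(w_neutral, w_pos, w_neg, w_plant)
    lens <- 1 + stats::rpois(n_msg, 6)
    all_tokens <- sample(lemmas, sum(lens), replace = TRUE, prob = probs)
    tok <- split(all_tokens, rep(seq_len(n_msg), lens))
    out <- data.frame(user_id = rep(user$user_id, n_msg),
                      alter_id = alters, timestamp = ts,
                      stringsAsFactors = FALSE)
    out$tokens <- unname(tok)
    out
  })
}

#' Generate a 7-day app-usage log for one user
#'
#' Session start hours are drawn from a circadian mixture: a day component
#' peaked in the late afternoon and a night component uniform over 0-6 h
#' whose mass shifts with the user's standardized WHO-5 by
#' `circadian_effect` (low WHO-5 means more night usage at the default
#' positive effect).
#'
#' @param user Single-row user record with `user_id`, `reference_time` and
#'   the standardized WHO-5 latent `z_who5`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `user_id`, `package`, `start`
#'   (POSIXct) and `duration_ms` (integer milliseconds > 0).
#' @export
generate_usage <- function(user, config, seed) {
  empty <- data.frame(user_id = character(), package = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      duration_ms = integer(), stringsAsFactors = FALSE)
  if (config$usage_rate <= 0 || config$observation_days <= 0) return(empty)
  with_seed(seed, {
    n <- stats::rpois(1, config$usage_rate)
    if (n == 0) return(empty)
    p_night <- stats::plogis(stats::qlogis(0.12) -
                               config$circadian_effect * user$z_who5)
    night <- stats::runif(n) < p_night
    hour <- numeric(n)
    hour[night] <- stats::runif(sum(night), 0, 6)
    n_day <- sum(!night)
    if (n_day > 0) {
      h <- stats::rnorm(2 * n_day + 20, 17, 4)
      h <- h[h >= 6 & h < 24]
      while (length(h) < n_day) {
        extra <- stats::rnorm(2 * n_day + 20, 17, 4)
        h <- c(h, extra[extra >= 6 & extra < 24])
      }
      hour[!night] <- h[seq_len(n_day)]
    }
    day <- sample.int(ceiling(config$observation_days), n, replace = TRUE) - 1
    window_start <- user$reference_time - config$observation_days * 86400
    # anchor to the drawn clock hour: offset to its next occurrence after
    # the window start, then one of the window's days
    sod <- as.numeric(window_start) %% 86400
    offset <- (hour * 3600 - sod) %% 86400
    start <- window_start + offset + day * 86400
    start <- pmin(start, user$reference_time)
    prefs <- stats::rgamma(9, 0.5)
    cat_idx <- sample.int(9, n, replace = TRUE, prob = prefs / sum(prefs))
    slug <- category_slug(config$app_categories[cat_idx])
    pkg <- sprintf("app.%s.%d", slug, sample.int(5, n, replace = TRUE))
    unknown <- stats::runif(n) < 0.02
    pkg[unknown] <- sprintf("app.unknown.%d", sample.int(20, sum(unknown),
                                                         replace = TRUE))
    dur <- pmax(1L, as.integer(round(stats::rlnorm(n, log(40000), 1))))
    data.frame(user_id = rep(user$user_id, n), package = pkg, start = start,
               duration_ms = dur, stringsAsFactors = FALSE)
  })
}

category_slug <- function(labels) tolower(gsub("[^A-Za-z]", "", labels))

#' Default package-to-category map covering the synthetic app inventory
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `package` and `category`.
#' @export
default_app_map <- function(config) {
  cats <- config$app_categories
  data.frame(
    package = sprintf("app.%s.%d", rep(category_slug(cats), each = 5), 1:5),
    category = rep(cats, each = 5),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort of users with message and usage streams
#'
#' Latent well-being is a low-skewed Beta variable; the two scales are
#' correlated Gaussian-copula transforms of a shared factor hitting the
#' configured inter-scale correlation, then discretized onto their raw
#' ranges (SWLS 5-35, WHO-5 5-30). Questionnaire scores, messages and app
#' usage are generated per user from seeds derived from `config$seed`, so a
#' fixed seed gives a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @return An object of class `swb_cohort`: a list with `users` (data
#'   frame), `messages`, `usage`, `items` (per-scale item-score matrices for
#'   internal-consistency analyses) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "swb_config"))
  n <- config$n_users
  sh <- beta_shapes(config$swb_location, config$swb_spread)
  users <- with_seed(config$seed, {
    rho <- abs(config$scale_corr)
    sgn <- sign(config$scale_corr + (config$scale_corr == 0))
    L <- stats::rnorm(n)
    x1 <- sqrt(rho) * L + sqrt(1 - rho) * stats::rnorm(n)
    x2 <- sgn * sqrt(rho) * L + sqrt(1 - rho) * stats::rnorm(n)
    swls_lat <- stats::qbeta(stats::pnorm(x1), sh[1], sh[2])
    who5_lat <- stats::qbeta(stats::pnorm(x2), sh[1], sh[2])
    swb_lat <- stats::qbeta(stats::pnorm(L), sh[1], sh[2])
    ref <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC") +
      round(stats::runif(n, 0, 60 * 86400))
    data.frame(
      user_id = sprintf("u%05d", seq_len(n)),
      age = pmin(pmax(round(stats::rnorm(n, 23, 5)), 18), 53),
      gender = ifelse(stats::runif(n) < 0.8, "female", "male"),
      n_vk_friends = stats::rnbinom(n, mu = 200, size = 2),
      n_subscriptions = stats::rnbinom(n, mu = 80, size = 1.5),
      swls_raw = as.integer(round(swls_lat * 30) + 5),
      who5_raw = as.integer(round(who5_lat * 25) + 5),
      reference_time = ref,
      swls_latent = swls_lat, who5_latent = who5_lat,
      z_swb = (swb_lat - config$swb_location) / config$swb_spread,
      z_who5 = (who5_lat - config$swb_location) / config$swb_spread,
      stringsAsFactors = FALSE
    )
  })
  mh <- generate_mh_scores((users$who5_raw - 5) / 25, config,
                           derive_seed(config$seed, 1L), missing = TRUE)
  users$phq <- if (n) mh$phq else integer()
  users$gad <- if (n) mh$gad else integer()
  users$pss <- if (n) mh$pss else integer()
  items <- with_seed(derive_seed(config$seed, 2L), {
    dir_split <- function(raw, k = 5, conc = 5) {
      g <- matrix(stats::rgamma(length(raw) * k, conc), ncol = k)
      m <- raw * g / rowSums(g)
      colnames(m) <- sprintf("item%d", seq_len(k))
      m
    }
    list(swls = dir_split(users$swls_raw), who5 = dir_split(users$who5_raw))
  })
  msg_seeds <- vapply(seq_len(n), function(i)
    derive_seed(config$seed, 10L + i), integer(1))
  use_seeds <- vapply(seq_len(n), function(i)
    derive_seed(config$seed, 500000L + i), integer(1))
  messages <- lapply(seq_len(n), function(i)
    generate_messages(users[i, ], config, msg_seeds[i]))
  usage <- lapply(seq_len(n), function(i)
    generate_usage(users[i, ], config, use_seeds[i]))
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  msg_proto <- generate_messages(
    list(user_id = "x", reference_time = Sys.time(), z_swb = 0),
    cohort_config(0, message_rate = 0), 1)
  use_proto <- generate_usage(
    list(user_id = "x", reference_time = Sys.time(), z_who5 = 0),
    cohort_config(0, usage_rate = 0), 1)
  structure(list(users = users,
                 messages = bind(messages, msg_proto),
                 usage = bind(usage, use_proto),
                 items = items, config = config),
            class = "swb_cohort")
}

#' @export
print.swb_cohort <- function(x, ...) {
  cat("Synthetic digital-trace cohort\n")
  cat("  users:    ", nrow(x$users), "\n")
  cat("  messages: ", nrow(x$messages), "\n")
  cat("  sessions: ", nrow(x$usage), "\n")
  invisible(x)
}

#' Write a cohort to disk in the pipeline's exchange formats
#'
#' Writes `users.csv` (fixed header, ISO-8601 reference times),
#' `messages.jsonl` (one JSON object per message) and `usage.csv`
#' (durations in integer milliseconds).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  u <- cohort$users
  users_out <- data.frame(
    user_id = u$user_id, age = u$age, gender = u$gender,
    n_vk_friends = u$n_vk_friends, n_subscriptions = u$n_subscriptions,
    swls_raw = u$swls_raw, who5_raw = u$who5_raw,
    phq = u$phq, gad = u$gad, pss = u$pss,
    reference_time = iso(u$reference_time),
    stringsAsFactors = FALSE
  )
  paths <- file.path(dir, c("users.csv", "messages.jsonl", "usage.csv"))
  utils::write.csv(users_out, paths[1], row.names = FALSE, na = "")
  m <- cohort$messages
  lines <- vapply(seq_len(nrow(m)), function(i) {
    jsonlite::toJSON(list(user = m$user_id[i], alter = m$alter_id[i],
                          timestamp = iso(m$timestamp[i]),
                          tokens = m$tokens[[i]]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, paths[2])
  us <- cohort$usage
  utils::write.csv(
    data.frame(user_id = us$user_id, package = us$package,
               start = iso(us$start), duration_ms = us$duration_ms,
               stringsAsFactors = FALSE),
    paths[3], row.names = FALSE)
  invisible(paths)
}
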