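#' Distinct correspondents per 30-day month before the reference time
#'
#' Month m (m = 1..12) covers the half-open interval
#' (reference_time - 30m days, reference_time - 30(m-1) days].
#'
#' @param messages One user's message data frame (`alter_id`, `timestamp`).
#' @param reference_time The user's reference timestamp.
#' @return Integer vector of 12 distinct-alter counts, months -1 to -12.
#' @export
monthly_alters <- function(messages, reference_time) {
  age_days <- (as.numeric(reference_time) -
                 as.numeric(messages$timestamp)) / 86400
  vapply(1:12, function(m) {
    inwin <- age_days > 30 * (m - 1) & age_days <= 30 * m
    length(unique(messages$alter_id[inwin]))
  }, integer(1))
}

#' Symmetric weighted growth between two non-negative totals
#'
#' `(v1 - v2) / (v1 + v2)`, bounded in \[-1, 1\]; defined as 0 when both
#' totals are 0.
#'
#' @param value_m1,value_m2 Totals of months -1 and -2 (>= 0).
#' @return Signed relative difference.
#' @export
weighted_growth <- function(value_m1, value_m2) {
  stopifnot(value_m1 >= 0, value_m2 >= 0)
  s <- value_m1 + value_m2
  ifelse(s == 0, 0, (value_m1 - value_m2) / s)
}

# Seconds of usage per 3-hour clock slot, sessions split proportionally
# across slot (and day) boundaries. Returns a length-8 vector for slots
# [0,3), [3,6), ..., [21,24).
slot_seconds <- function(start, duration_s) {
  totals <- numeric(8)
  for (i in seq_along(start)) {
    t0 <- as.numeric(start[i]) %% 86400
    left <- duration_s[i]
    while (left > 0) {
      slot <- floor(t0 / 10800)
      boundary <- (slot + 1) * 10800
      chunk <- min(left, boundary - t0)
      totals[slot + 1] <- totals[slot + 1] + chunk
      left <- left - chunk
      t0 <- boundary %% 86400
    }
  }
  totals
}

slot_labels <- function() {
  paste0(seq(0, 21, 3), "-", seq(3, 24, 3))
}

#' Circadian slot usage totals and ratios
#'
#' @param usage One user's app-usage data frame (`start`, `duration_ms`).
#' @return Named vector of 8 per-slot totals in seconds
#'   (`AppUsage0-3`, ...) and 8 ratios normalized by the overall total
#'   (`AppUsage0-3Ratio`, ...); ratios are 0 when there is no usage.
#' @export
slot_usage_features <- function(usage) {
  totals <- slot_seconds(usage$start, usage$duration_ms / 1000)
  overall <- sum(totals)
  ratios <- if (overall > 0) totals / overall else rep(0, 8)
  stats::setNames(c(totals, ratios),
                  c(paste0("AppUsage", slot_labels()),
                    paste0("AppUsage", slot_labels(), "Ratio")))
}

#' The 40 metadata and overall-activity features for one user
#'
#' Demographics and profile counts, trailing-30-day message volume, the
#' weighted month-over-month growth of message volume and alter counts,
#' app-session counts and durations with 3-hour circadian slot totals and
#' ratios, and the 12 monthly distinct-alter counts.
#'
#' @param user Single-row user record (`age`, `gender`, `n_vk_friends`,
#'   `n_subscriptions`).
#' @param messages,usage The user's trace streams.
#' @param reference_time The user's reference timestamp.
#' @param observation_days App-usage observation window length (default 7).
#' @return Named numeric vector of exactly 40 features.
#' @export
activity_features <- function(user, messages, usage, reference_time,
                              observation_days = 7) {
  age_days <- (as.numeric(reference_time) -
                 as.numeric(messages$timestamp)) / 86400
  in_month <- function(m) age_days > 30 * (m - 1) & age_days <= 30 * m
  chars <- function(idx) {
    if (!any(idx)) return(0)
    sum(nchar(unlist(messages$tokens[idx], use.names = FALSE)))
  }
  alters_by_month <- monthly_alters(messages, reference_time)
  all_alters <- length(unique(messages$alter_id[age_days > 0 &
                                                  age_days <= 360]))
  slots <- slot_usage_features(usage)
  all_time <- sum(usage$duration_ms) / 1000
  gender_code <- if (is.na(user$gender)) NA_real_ else
    c(male = 0, female = 1)[[user$gender]]
  out <- c(
    Age = as.numeric(user$age),
    Gender = gender_code,
    NVkFriends = as.numeric(user$n_vk_friends),
    AllAlters = all_alters,
    Subscriptions = as.numeric(user$n_subscriptions),
    Mess_1 = sum(in_month(1)),
    MessChars_1 = chars(in_month(1)),
    `growth-2to-1weighted` = weighted_growth(chars(in_month(1)),
                                             chars(in_month(2))),
    altersdiff = weighted_growth(alters_by_month[1], alters_by_month[2]),
    AppUsage1Week = nrow(usage),
    AllAppTime1Week = all_time,
    RatioAppTime1Week = all_time / (observation_days * 86400),
    slots,
    stats::setNames(as.numeric(alters_by_month), paste0("Alters-", 1:12))
  )
  stopifnot(length(out) == 40)
  out
}

#' Activity feature matrix for a whole cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return Numeric matrix, one row per user, 40 named columns.
#' @export
behavior_features <- function(cohort) {
  u <- cohort$users
  rows <- lapply(seq_len(nrow(u)), function(i) {
    activity_features(
      u[i, ],
      cohort$messages[cohort$messages$user_id == u$user_id[i], ],
      cohort$usage[cohort$usage$user_id == u$user_id[i], ],
      u$reference_time[i],
      observation_days = cohort$config$observation_days)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- u$user_id
  m
}
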