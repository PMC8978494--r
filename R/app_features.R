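#' Load or construct a package-to-category map
#'
#' @param x A data frame with columns `package` and `category`, or a path
#'   to a two-column TSV.
#' @return Validated map data frame; categories must come from the nine
#'   canonical labels.
#' @export
app_category_map <- function(x) {
  map <- if (is.character(x)) {
    utils::read.delim(x, header = TRUE, stringsAsFactors = FALSE)
  } else x
  if (!all(c("package", "category") %in% names(map))) {
    stop("map needs columns 'package' and 'category'", call. = FALSE)
  }
  bad <- setdiff(unique(map$category), swb_app_categories())
  if (length(bad)) {
    stop("unknown app categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$package)) stop("duplicate packages in map",
                                       call. = FALSE)
  map
}

#' Categorize an app package
#'
#' @param package Package identifier(s).
#' @param map An [app_category_map()]; unmapped packages resolve to
#'   `Other`.
#' @return Character vector of categories.
#' @export
categorize_app <- function(package, map) {
  i <- match(package, map$package)
  out <- map$category[i]
  out[is.na(i)] <- "Other"
  out
}

# "Education+Productivity" -> "EDUCATION + PRODUCTIVITY" etc.
category_feature_label <- function(category) {
  toupper(gsub("+", " + ", category, fixed = TRUE))
}

#' The 225 category-by-time-slot app-usage features for one user
#'
#' Nine raw per-category totals (seconds over the whole window), 72
#' per-day-averaged category-by-slot values, and two normalized variants of
#' each: divided by the category's per-day-average total
#' (`CATEGORY_slot/CATEGORY`) and by the slot's per-day-average total over
#' all categories (`CATEGORY_slot/slot`). Sessions are split across slot
#' boundaries proportionally; empty denominators give 0.
#'
#' @param usage One user's app-usage data frame (`package`, `start`,
#'   `duration_ms`).
#' @param map An [app_category_map()].
#' @param window_days Observation-window length in days used as the
#'   per-day averaging denominator (default 7).
#' @return Named numeric vector of exactly 225 features.
#' @export
category_slot_features <- function(usage, map, window_days = 7) {
  cats <- swb_app_categories()
  labels <- category_feature_label(cats)
  slots <- slot_labels()
  by_cat <- matrix(0, length(cats), 8, dimnames = list(cats, slots))
  if (nrow(usage) > 0) {
    ucat <- categorize_app(usage$package, map)
    for (cl in unique(ucat)) {
      sel <- ucat == cl
      by_cat[cl, ] <- slot_seconds(usage$start[sel],
                                   usage$duration_ms[sel] / 1000)
    }
  }
  cat_total <- rowSums(by_cat)
  slot_total <- colSums(by_cat)
  per_day <- by_cat / window_days
  div0 <- function(a, b) ifelse(b > 0, a / b, 0)
  by_cat_norm <- div0(by_cat, matrix(cat_total, length(cats), 8))
  by_slot_norm <- div0(by_cat, matrix(slot_total, length(cats), 8,
                                      byrow = TRUE))
  name_grid <- function(suffix_fun) {
    unlist(lapply(seq_along(cats), function(ci)
      vapply(slots, function(sl) suffix_fun(labels[ci], sl), character(1))))
  }
  out <- c(
    stats::setNames(cat_total, labels),
    stats::setNames(as.vector(t(per_day)),
                    name_grid(function(l, sl) paste0(l, "_", sl))),
    stats::setNames(as.vector(t(by_cat_norm)),
                    name_grid(function(l, sl) paste0(l, "_", sl, "/", l))),
    stats::setNames(as.vector(t(by_slot_norm)),
                    name_grid(function(l, sl) paste0(l, "_", sl, "/", sl)))
  )
  stopifnot(length(out) == 225)
  out
}

#' App-category feature matrix for a whole cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param map An [app_category_map()] (defaults to the synthetic
#'   inventory's map).
#' @return Numeric matrix, one row per user, 225 named columns.
#' @export
app_features <- function(cohort, map = default_app_map(cohort$config)) {
  map <- app_category_map(map)
  u <- cohort$users
  rows <- lapply(seq_len(nrow(u)), function(i) {
    category_slot_features(
      cohort$usage[cohort$usage$user_id == u$user_id[i], ], map,
      window_days = cohort$config$observation_days)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- u$user_id
  m
}
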