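#' Specification of a well-being scale
#'
#' Both scales are mapped onto \[0, 1\] by subtracting 5 and dividing by the
#' scale width: SWLS (raw 5-35) by 30, WHO-5 (raw 5-30) by 25.
#'
#' @param name `"SWLS"` or `"WHO5"`.
#' @return An object of class `swb_scale` with fields `name`, `raw_min`,
#'   `raw_max`, `shift` and `divisor`.
#' @export
scale_spec <- function(name = c("SWLS", "WHO5")) {
  name <- match.arg(name)
  spec <- switch(name,
    SWLS = list(name = "SWLS", raw_min = 5, raw_max = 35, shift = 5,
                divisor = 30),
    WHO5 = list(name = "WHO5", raw_min = 5, raw_max = 30, shift = 5,
                divisor = 25))
  stopifnot((spec$raw_max - spec$shift) / spec$divisor == 1,
            (spec$raw_min - spec$shift) / spec$divisor == 0)
  structure(spec, class = "swb_scale")
}

#' Normalize raw scale scores onto \[0, 1\]
#'
#' @param spec A [scale_spec()].
#' @param raw Numeric raw scores within the scale range.
#' @return `(raw - shift) / divisor`, in \[0, 1\].
#' @export
normalize_score <- function(spec, raw) {
  stopifnot(inherits(spec, "swb_scale"))
  bad <- !is.na(raw) & (raw < spec$raw_min | raw > spec$raw_max)
  if (any(bad)) {
    stop("raw ", spec$name, " score outside [", spec$raw_min, ", ",
         spec$raw_max, "]: ", raw[bad][1], call. = FALSE)
  }
  (raw - spec$shift) / spec$divisor
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total).
#'
#' @param item_scores Numeric matrix or data frame, users in rows, items in
#'   columns (>= 2 of each).
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(item_scores) {
  m <- as.matrix(item_scores)
  if (ncol(m) < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 users", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Cutoffs discretizing a normalized well-being score
#'
#' @param mode `"binary"` (one cutoff, default 0.51) or `"trinary"` (two
#'   ascending cutoffs, default 0.35 and 0.59).
#' @param cutoffs Cutoff value(s) on the normalized scale, in (0, 1).
#' @return An object of class `swb_cutoffs`.
#' @export
cutoff_set <- function(mode = c("binary", "trinary"), cutoffs = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoffs)) {
    cutoffs <- if (mode == "binary") 0.51 else c(0.35, 0.59)
  }
  n_expected <- if (mode == "binary") 1L else 2L
  if (length(cutoffs) != n_expected) {
    stop(mode, " mode needs ", n_expected, " cutoff(s)", call. = FALSE)
  }
  if (any(cutoffs <= 0 | cutoffs >= 1) || is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly ascending values in (0, 1)", call. = FALSE)
  }
  structure(list(mode = mode, cutoffs = cutoffs), class = "swb_cutoffs")
}

#' Assign well-being classes from normalized scores
#'
#' Scores at or above a cutoff fall in the upper class (the boundary
#' convention is fixed here: `score >= cutoff` is the higher class).
#'
#' @param norm_score Normalized scores in \[0, 1\].
#' @param cutoffs A [cutoff_set()].
#' @return Factor with levels `low`/`high` (binary) or
#'   `low`/`medium`/`high` (trinary).
#' @export
assign_class <- function(norm_score, cutoffs) {
  stopifnot(inherits(cutoffs, "swb_cutoffs"),
            all(is.na(norm_score) | (norm_score >= 0 & norm_score <= 1)))
  if (cutoffs$mode == "binary") {
    factor(ifelse(norm_score < cutoffs$cutoffs[1], "low", "high"),
           levels = c("low", "high"))
  } else {
    cls <- ifelse(norm_score < cutoffs$cutoffs[1], "low",
                  ifelse(norm_score >= cutoffs$cutoffs[2], "high", "medium"))
    factor(cls, levels = c("low", "medium", "high"))
  }
}
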