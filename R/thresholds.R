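#' Screen-positive rule for a mental-health condition
#'
#' Depression is PHQ-9 >= 10, anxiety GAD >= 10, stress PSS >= 21.
#'
#' @param name `"depression"`, `"anxiety"` or `"stress"`.
#' @return An object of class `swb_condition` with the source scale, its
#'   range and the positivity threshold.
#' @export
condition_spec <- function(name = c("depression", "anxiety", "stress")) {
  name <- match.arg(name)
  spec <- switch(name,
    depression = list(name = name, scale = "phq", threshold = 10,
                      range = c(0, 27)),
    anxiety = list(name = name, scale = "gad", threshold = 10,
                   range = c(0, 21)),
    stress = list(name = name, scale = "pss", threshold = 21,
                  range = c(0, 40)))
  structure(spec, class = "swb_condition")
}

#' Binarize a questionnaire score into screen-positive / negative
#'
#' @param spec A [condition_spec()].
#' @param score Numeric scores within the instrument range (NA passes
#'   through; exclusion of incomplete records is the caller's job).
#' @return Logical vector: `TRUE` = screen-positive.
#' @export
binarize_condition <- function(spec, score) {
  stopifnot(inherits(spec, "swb_condition"))
  ok <- is.na(score) | (score >= spec$range[1] & score <= spec$range[2])
  if (!all(ok)) {
    stop(spec$scale, " score outside [", spec$range[1], ", ", spec$range[2],
         "]", call. = FALSE)
  }
  score >= spec$threshold
}

#' Confusion counts of a WHO-5 screening cutoff
#'
#' Low WHO-5 is the positive screen: a user screens positive when the
#' normalized score is strictly below the cutoff.
#'
#' @param who5_norm Normalized WHO-5 scores.
#' @param condition_labels Logical condition labels (TRUE = condition
#'   positive), same length.
#' @param cutoff Normalized cutoff value.
#' @param condition Optional condition name carried into the result.
#' @return A one-row data frame of class `swb_cutoff_eval` with the
#'   condition, cutoff, n, confusion counts (TP, FP, TN, FN), sensitivity,
#'   specificity and an `undefined` flag set when a rate has an empty
#'   denominator.
#' @export
cutoff_confusion <- function(who5_norm, condition_labels, cutoff,
                             condition = NA_character_) {
  stopifnot(length(who5_norm) == length(condition_labels))
  keep <- !is.na(who5_norm) & !is.na(condition_labels)
  s <- who5_norm[keep]
  y <- as.logical(condition_labels[keep])
  screen <- s < cutoff
  tp <- sum(screen & y); fn <- sum(!screen & y)
  tn <- sum(!screen & !y); fp <- sum(screen & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(data.frame(
    condition = condition, cutoff = cutoff, n = length(s),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    undefined = is.na(sens) || is.na(spec),
    stringsAsFactors = FALSE
  ), class = c("swb_cutoff_eval", "data.frame"))
}

#' Sweep candidate WHO-5 cutoffs against one or more conditions
#'
#' @param scores Normalized WHO-5 scores.
#' @param labels_by_condition Named list of logical condition-label vectors
#'   (NA labels drop the record for that condition only).
#' @param grid Candidate cutoffs; defaults to the midpoints of the sorted
#'   unique scores.
#' @return Data frame with one `cutoff_confusion()` row per
#'   (condition, cutoff).
#' @export
sweep_cutoffs <- function(scores, labels_by_condition, grid = NULL) {
  if (!is.list(labels_by_condition)) {
    labels_by_condition <- list(condition = labels_by_condition)
  }
  if (is.null(grid)) {
    u <- sort(unique(scores[!is.na(scores)]))
    if (length(u) < 2) stop("need at least 2 distinct scores", call. = FALSE)
    grid <- (u[-1] + u[-length(u)]) / 2
  }
  if (length(grid) == 0) stop("empty cutoff grid", call. = FALSE)
  rows <- lapply(names(labels_by_condition), function(cond) {
    do.call(rbind, lapply(grid, function(cut) {
      cutoff_confusion(scores, labels_by_condition[[cond]], cut, cond)
    }))
  })
  do.call(rbind, rows)
}

#' Select binary and trinary WHO-5 cutoffs from a sweep
#'
#' The binary cutoff maximizes the mean Youden J
#' (sensitivity + specificity - 1) across conditions. The trinary lower
#' cutoff is the largest candidate with mean specificity >= `spec_floor`
#' (so the low class is called with high confidence), the upper cutoff the
#' smallest candidate with mean sensitivity >= `sens_floor`.
#'
#' @param sweep_table A [sweep_cutoffs()] result covering the conditions.
#' @param policy List of policy constants: `spec_floor` (default 0.8) and
#'   `sens_floor` (default 0.9).
#' @return List with `binary` and `trinary` [cutoff_set()]s (the latter
#'   `NULL` on failure), a `report` of per-cutoff mean rates, and a
#'   `failed` character vector naming any unsatisfiable constraint.
#' @export
select_cutoffs <- function(sweep_table,
                           policy = list(spec_floor = 0.8, sens_floor = 0.9)) {
  spec_floor <- policy$spec_floor %||% 0.8
  sens_floor <- policy$sens_floor %||% 0.9
  usable <- !sweep_table$undefined
  failed <- character(0)
  if (!any(usable)) {
    return(list(binary = NULL, trinary = NULL, report = NULL,
                failed = "all conditions single-class"))
  }
  tab <- sweep_table[usable, ]
  agg <- stats::aggregate(tab[c("sensitivity", "specificity")],
                          by = list(cutoff = tab$cutoff), FUN = mean)
  agg <- agg[order(agg$cutoff), ]
  agg$youden <- agg$sensitivity + agg$specificity - 1
  binary_cut <- agg$cutoff[which.max(agg$youden)]
  lower_ok <- agg$cutoff[agg$specificity >= spec_floor]
  upper_ok <- agg$cutoff[agg$sensitivity >= sens_floor]
  lower <- if (length(lower_ok)) max(lower_ok) else NA_real_
  upper <- if (length(upper_ok)) min(upper_ok) else NA_real_
  if (is.na(lower)) failed <- c(failed, "trinary lower: no cutoff reaches the specificity floor")
  if (is.na(upper)) failed <- c(failed, "trinary upper: no cutoff reaches the sensitivity floor")
  trinary <- NULL
  if (!length(failed)) {
    if (lower < upper) {
      trinary <- cutoff_set("trinary", c(lower, upper))
    } else {
      failed <- c(failed, "trinary cutoffs not strictly ascending")
    }
  }
  list(binary = cutoff_set("binary", binary_cut), trinary = trinary,
       report = agg, failed = failed)
}
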