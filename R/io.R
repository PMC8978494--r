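#' Write a feature matrix as CSV with a provenance sidecar
#'
#' The matrix goes to `path` (users in rows, a `user_id` column first) and
#' a JSON sidecar `<path>.provenance.json` names each feature's family.
#'
#' @param features Numeric matrix with user rownames and feature colnames.
#' @param path Output CSV path.
#' @param families Named character vector mapping feature name to family;
#'   unnamed features are recorded as `"unknown"`.
#' @return Invisibly, the two paths written.
#' @export
write_feature_matrix <- function(features, path, families = NULL) {
  stopifnot(!is.null(colnames(features)))
  df <- data.frame(user_id = rownames(features) %||%
                     seq_len(nrow(features)), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- stats::setNames(rep("unknown", ncol(features)),
                          colnames(features))
  if (!is.null(families)) {
    hit <- intersect(names(families), colnames(features))
    prov[hit] <- families[hit]
  }
  sidecar <- paste0(path, ".provenance.json")
  jsonlite::write_json(as.list(prov), sidecar, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}

#' Serialize a cluster solution to JSON
#'
#' @param solution A cluster solution (class `swb_clusters`).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cluster_solution <- function(solution, path) {
  stopifnot(inherits(solution, "swb_clusters"))
  jsonlite::write_json(list(
    partition = as.list(solution$partition),
    metadata = list(k = solution$k, weight = solution$weight,
                    threshold = solution$threshold,
                    augmented = solution$augmented,
                    n_clusters = length(unique(solution$partition)))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized cluster solution
#'
#' @param path JSON path written by [write_cluster_solution()].
#' @return A cluster solution (class `swb_clusters`).
#' @export
read_cluster_solution <- function(path) {
  obj <- jsonlite::fromJSON(path)
  part <- unlist(obj$partition)
  md <- obj$metadata
  structure(list(partition = part, k = md$k,
                 n_clusters = md$n_clusters, weight = md$weight,
                 threshold = md$threshold %||% NA,
                 augmented = isTRUE(md$augmented),
                 objective = NA_real_, inertia = NA_real_),
            class = "swb_clusters")
}
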