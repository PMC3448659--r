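# Progression-marker cluster reports: which (meta)features co-cluster with
# MMSE, NFT count, Braak stage or the JSD progression scores, ranked by
# their Spearman correlation with the marker, and which probes recur across
# the clusters of several markers ("robust markers").

.marker_node <- function(marker_id, feature_ids) {
  cand <- c(paste0("MARKER:", marker_id), marker_id)
  hit <- cand[cand %in% feature_ids]
  if (length(hit) == 0L) stop("marker '", marker_id, "' absent from clustering")
  hit[1L]
}

#' Co-members of each progression marker's cluster
#'
#' @param C An `mstknn_clustering` whose nodes include the marker rows
#'   (named `"MARKER:<id>"`, as produced by [assemble_analysis_matrix()]).
#' @param marker_ids Marker names, e.g. `c("mmse", "nft", "braak",
#'   "jsd_control", "jsd_severe")`.
#' @return Named list: for each marker, the character vector of co-clustered
#'   feature ids (marker nodes themselves excluded).
#' @export
find_marker_clusters <- function(C, marker_ids) {
  assignment <- C$assignment
  nodes <- vapply(marker_ids, .marker_node, character(1L),
                  feature_ids = names(assignment))
  all_marker_nodes <- names(assignment)[startsWith(names(assignment), "MARKER:")]
  out <- lapply(nodes, function(nd) {
    cid <- assignment[[nd]]
    members <- names(assignment)[assignment == cid]
    setdiff(members, c(nd, all_marker_nodes))
  })
  names(out) <- marker_ids
  out
}

#' Rank cluster members by correlation with a marker
#'
#' Members are ordered by Spearman correlation with the marker, most
#' positive first; ties are broken lexicographically by feature id for
#' determinism. Correlations are reported to full precision; report writers
#' print them with 6 decimals.
#'
#' @param members Character vector of feature ids.
#' @param F Feature x sample matrix containing those rows.
#' @param marker Numeric vector over the samples.
#' @param marker_id Optional marker name recorded in the report.
#' @return A `marker_report` data.frame with columns feature_id and spearman.
#' @export
rank_members <- function(members, F, marker, marker_id = NA_character_) {
  miss <- setdiff(members, rownames(F))
  if (length(miss)) stop("member(s) absent from matrix: ", paste(miss, collapse = ", "))
  rho <- vapply(members, function(m) spearman_cor(F[m, ], marker), numeric(1L))
  ord <- order(-rho, members)
  res <- data.frame(feature_id = members[ord], spearman = unname(rho[ord]),
                    stringsAsFactors = FALSE)
  attr(res, "marker_id") <- marker_id
  class(res) <- c("marker_report", class(res))
  res
}

#' Probes that recur in the clusters of several progression markers
#'
#' Decomposes every reported (meta)feature into its constituent probes and
#' keeps the probes whose features appear in the clusters of at least
#' `min_markers` distinct markers.
#'
#' @param reports Named list of `marker_report`s (names are marker ids), or
#'   a named list of member-id character vectors.
#' @param min_markers Minimum number of distinct markers (default 2).
#' @return Named list mapping each robust probe id to the sorted character
#'   vector of marker ids whose clusters contain it.
#' @export
robust_markers <- function(reports, min_markers = 2L) {
  if (length(reports) < 2L) stop("need reports for at least 2 markers")
  if (is.null(names(reports))) stop("reports must be named by marker id")
  probe_map <- list()
  for (mk in names(reports)) {
    r <- reports[[mk]]
    ids <- if (is.data.frame(r)) r$feature_id else r
    probes <- unique(unlist(lapply(ids, constituent_probes)))
    for (pb in probes) probe_map[[pb]] <- union(probe_map[[pb]], mk)
  }
  keep <- vapply(probe_map, function(v) length(v) >= min_markers, logical(1L))
  out <- lapply(probe_map[keep], function(v) sort(v))
  out[order(names(out))]
}

#' Re-run the clustering on a sample subset
#'
#' Stratified re-analysis (for example sex-specific clustering): the full
#' MST-kNN pipeline is re-run on the selected samples only. Compare marker
#' cluster membership with the unstratified run via [find_marker_clusters()].
#'
#' @param X Feature x sample matrix (markers already assembled if desired).
#' @param annotation Annotation data.frame as from [read_annotation()].
#' @param predicate Either a function of the annotation data.frame returning
#'   a logical vector, or a character vector of sample ids.
#' @param min_samples Minimum subset size (default 4).
#' @param ... Passed to [mstknn()].
#' @return An `mstknn_clustering` over the subset, with the selected sample
#'   ids in `$samples`.
#' @export
stratified_recluster <- function(X, annotation, predicate, min_samples = 4L, ...) {
  ids <- if (is.character(predicate)) {
    predicate
  } else {
    annotation$sample_id[predicate(annotation)]
  }
  ids <- intersect(colnames(X), ids)
  if (length(ids) < min_samples) {
    stop("stratified subset has fewer than ", min_samples, " samples")
  }
  res <- mstknn(X[, ids, drop = FALSE], ...)
  res$samples <- ids
  res
}

#' Write one marker report as tab-separated text
#'
#' Correlations are printed with 6 decimal places; bytes are deterministic.
#'
#' @param report A `marker_report`.
#' @param path Output path.
#' @export
write_marker_report <- function(report, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("feature_id\tspearman", con)
  if (nrow(report)) {
    writeLines(paste(report$feature_id, sprintf("%.6f", report$spearman),
                     sep = "\t"), con)
  }
  invisible(path)
}
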