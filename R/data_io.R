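#' Read an expression matrix from tab-separated text
#'
#' The expected layout is a header row of sample identifiers, followed by one
#' row per feature whose first column is the feature identifier. All cells
#' must be numeric; identifiers on both axes must be unique.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (features x samples) with feature ids as rownames
#'   and sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop("empty or malformed expression table: ", path)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty or malformed expression table: ", path)
  }
  feature_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  num
}

#' Write an expression matrix as tab-separated text
#'
#' Values are printed with 17 significant digits so that a read/write round
#' trip reproduces the doubles exactly; output bytes are deterministic for a
#' fixed input.
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Validate an expression matrix
#'
#' @param x Candidate matrix.
#' @param require_positive If TRUE, all values must be strictly positive
#'   (needed for ratio metafeatures and probability profiles). Violations are
#'   reported with feature/sample coordinates.
#' @return The matrix, invisibly.
#' @export
validate_expression <- function(x, require_positive = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (require_positive && any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive value at feature '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read an expression matrix from GEO series-matrix text
#'
#' Strips the metadata lines beginning with "!" that GEO series-matrix files
#' carry around the expression table, then parses the remainder as a
#' tab-separated matrix. Quoted identifiers are unquoted.
#'
#' @param path Path to a series-matrix style text file.
#' @return A numeric matrix as for [read_expression()].
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path)
  keep <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(keep) < 2L) stop("no expression table found in ", path)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(gsub('"', "", keep, fixed = TRUE), tmp)
  read_expression(tmp)
}

.group_levels <- c("control", "incipient", "moderate", "severe")
.sex_levels <- c("male", "female", "unknown")

#' Read a sample annotation table
#'
#' Accepts comma- or tab-separated text with a header. Recognized columns are
#' sample_id, group, sex, mmse, nft and braak; unknown columns are ignored
#' with a warning. A missing sex column yields "unknown" for every sample.
#'
#' @param path Path to the annotation file.
#' @return A data.frame with columns sample_id, group (factor:
#'   control/incipient/moderate/severe), sex (factor: male/female/unknown),
#'   mmse (integer 0-30), nft (non-negative numeric) and braak
#'   (integer 1-6, encoding stages I-VI).
#' @export
read_annotation <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  known <- c("sample_id", "group", "sex", "mmse", "nft", "braak")
  extra <- setdiff(colnames(df), known)
  if (length(extra)) {
    warning("ignoring unknown annotation columns: ", paste(extra, collapse = ", "))
  }
  if (!"sample_id" %in% colnames(df)) stop("annotation lacks a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  if ("group" %in% colnames(df)) {
    bad <- setdiff(unique(tolower(df$group)), .group_levels)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    group <- factor(tolower(df$group), levels = .group_levels)
  } else {
    group <- factor(rep(NA_character_, nrow(df)), levels = .group_levels)
  }
  sex <- if ("sex" %in% colnames(df)) {
    bad <- setdiff(unique(tolower(df$sex)), .sex_levels)
    if (length(bad)) stop("unknown sex label(s): ", paste(bad, collapse = ", "))
    factor(tolower(df$sex), levels = .sex_levels)
  } else {
    factor(rep("unknown", nrow(df)), levels = .sex_levels)
  }
  take_num <- function(col) if (col %in% colnames(df)) as.numeric(df[[col]]) else rep(NA_real_, nrow(df))
  mmse <- take_num("mmse")
  if (any(!is.na(mmse) & (mmse < 0 | mmse > 30))) {
    i <- which(!is.na(mmse) & (mmse < 0 | mmse > 30))[1L]
    stop(sprintf("mmse out of [0, 30] for sample '%s'", df$sample_id[i]))
  }
  braak <- take_num("braak")
  if (any(!is.na(braak) & (braak < 1 | braak > 6))) {
    i <- which(!is.na(braak) & (braak < 1 | braak > 6))[1L]
    stop(sprintf("braak stage out of [1, 6] for sample '%s'", df$sample_id[i]))
  }
  nft <- take_num("nft")
  if (any(!is.na(nft) & nft < 0)) stop("negative nft count")
  data.frame(sample_id = as.character(df$sample_id), group = group, sex = sex,
             mmse = as.integer(mmse), nft = nft, braak = as.integer(braak),
             stringsAsFactors = FALSE)
}

#' Construct a clustering result
#'
#' @param assignment Named integer vector mapping feature ids to cluster ids;
#'   cluster ids are renumbered to be contiguous from 0, ordered by each
#'   cluster's lexicographically smallest member.
#' @param split_log Optional data.frame logging the recursive splits, with
#'   columns component_size, criterion (C1/C2/C3/MINSIZE) and
#'   removed_edge_count.
#' @param q_used Optional integer, the neighbourhood size that produced the
#'   connected graph.
#' @return An object of class `mstknn_clustering`.
#' @export
clustering_result <- function(assignment, split_log = NULL, q_used = NA_integer_) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must be named with unique feature ids")
  }
  clusters <- split(names(assignment), assignment)
  first <- vapply(clusters, function(m) min(m), character(1L))
  ord <- order(first)
  remap <- integer(length(clusters))
  remap[ord] <- seq_along(clusters) - 1L
  new_assign <- remap[match(as.character(assignment), names(clusters))]
  names(new_assign) <- names(assignment)
  if (is.null(split_log)) {
    split_log <- data.frame(component_size = integer(), criterion = character(),
                            removed_edge_count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(assignment = new_assign, split_log = split_log,
                 q_used = as.integer(q_used)),
            class = "mstknn_clustering")
}

#' @export
print.mstknn_clustering <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("MST-kNN clustering: %d features in %d clusters (q = %s)\n",
              length(x$assignment), length(sizes),
              ifelse(is.na(x$q_used), "?", x$q_used)))
  cat(sprintf("cluster sizes: min %d, median %s, max %d\n",
              min(sizes), format(stats::median(sizes)), max(sizes)))
  invisible(x)
}

#' Write a clustering as two-column tab-separated text
#'
#' Features are sorted lexicographically, so output bytes are deterministic
#' for a fixed clustering.
#'
#' @param result An `mstknn_clustering` (or a named integer vector).
#' @param path Output path.
#' @export
write_clusters <- function(result, path) {
  assignment <- if (inherits(result, "mstknn_clustering")) result$assignment else result
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("feature_id\tcluster_id", con)
  if (length(assignment)) {
    ord <- order(names(assignment))
    writeLines(paste(names(assignment)[ord], assignment[ord], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a clustering written by [write_clusters()]
#'
#' @param path Path to a two-column tab-separated table.
#' @return An `mstknn_clustering`.
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  assignment <- as.integer(df$cluster_id)
  names(assignment) <- df$feature_id
  clustering_result(assignment)
}

#' Export an annotated spanning forest as edge-list text
#'
#' One row per edge: node_a, node_b, weight, p. Edges are ordered by
#' (node_a, node_b) with node_a the lexicographically smaller endpoint, and
#' weights printed to 6 decimals, so the bytes are deterministic.
#'
#' @param forest A `spanning_forest` (see [minimum_spanning_tree()]).
#' @param path Output path.
#' @export
write_forest_edges <- function(forest, path) {
  stopifnot(inherits(forest, "spanning_forest"))
  e <- forest$edges
  a <- pmin(e$a, e$b)
  b <- pmax(e$a, e$b)
  ord <- order(a, b)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tweight\tp", con)
  p_col <- if (!is.null(e$p)) e$p[ord] else rep(NA_integer_, nrow(e))
  if (nrow(e)) {
    writeLines(paste(a[ord], b[ord], sprintf("%.6f", e$weight[ord]), p_col,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Export an annotated spanning forest as GraphML
#'
#' @param forest A `spanning_forest`.
#' @param path Output path (GraphML XML).
#' @export
write_forest_graphml <- function(forest, path) {
  stopifnot(inherits(forest, "spanning_forest"))
  e <- forest$edges[order(pmin(forest$edges$a, forest$edges$b),
                          pmax(forest$edges$a, forest$edges$b)),
                    intersect(c("a", "b", "weight", "p"), colnames(forest$edges)),
                    drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = sort(forest$nodes), stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
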