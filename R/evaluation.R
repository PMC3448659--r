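# Cluster quality (homogeneity/separation), permutation FDR, and partition
# agreement scoring.

.cluster_members <- function(C) {
  assignment <- if (inherits(C, "mstknn_clustering")) C$assignment else C
  split(names(assignment), assignment)
}

#' Average cluster homogeneity
#'
#' The mean, over all clustered features, of the Pearson correlation between
#' a feature's expression vector and its cluster centroid (the mean
#' expression vector of the cluster's members). Singleton clusters
#' contribute a similarity of 1 by convention (switchable); members of a
#' cluster whose centroid is constant are excluded with a warning.
#'
#' @param X Feature x sample numeric matrix covering every clustered feature.
#' @param C An `mstknn_clustering` or named assignment vector.
#' @param singletons_as_one Count singleton members as similarity 1 (TRUE,
#'   default) or drop them from the average (FALSE).
#' @return H_avg in `[-1, 1]`.
#' @export
homogeneity <- function(X, C, singletons_as_one = TRUE) {
  members <- .cluster_members(C)
  miss <- setdiff(unlist(members), rownames(X))
  if (length(miss)) stop("clustered feature(s) absent from matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  sims <- numeric(0)
  n_excluded <- 0L
  for (m in members) {
    if (length(m) == 1L) {
      if (singletons_as_one) sims <- c(sims, 1)
      next
    }
    centroid <- colMeans(X[m, , drop = FALSE])
    if (stats::sd(centroid) == 0) {
      n_excluded <- n_excluded + length(m)
      next
    }
    ok <- apply(X[m, , drop = FALSE], 1L, stats::sd) > 0
    n_excluded <- n_excluded + sum(!ok)
    if (any(ok)) {
      sims <- c(sims, as.vector(stats::cor(t(X[m[ok], , drop = FALSE]), centroid)))
    }
  }
  if (n_excluded > 0L) {
    warning(n_excluded, " member(s) excluded (constant feature or centroid)")
  }
  if (length(sims) == 0L) stop("no scorable members")
  mean(sims)
}

#' Size-weighted average cluster separation
#'
#' `S_avg = sum_{i<j} |C_i||C_j| cor(centroid_i, centroid_j) /
#'  sum_{i<j} |C_i||C_j|` over all cluster pairs (Pearson on centroids).
#'
#' @inheritParams homogeneity
#' @return S_avg in `[-1, 1]`; lower means better-separated clusters.
#' @export
separation <- function(X, C) {
  members <- .cluster_members(C)
  if (length(members) < 2L) stop("separation is undefined for a single cluster")
  centroids <- t(vapply(members, function(m) colMeans(X[m, , drop = FALSE]),
                        numeric(ncol(X))))
  sizes <- unname(lengths(members))
  num <- 0
  den <- 0
  for (i in seq_len(nrow(centroids) - 1L)) {
    for (j in (i + 1L):nrow(centroids)) {
      w <- sizes[i] * sizes[j]
      num <- num + w * stats::cor(centroids[i, ], centroids[j, ])
      den <- den + w
    }
  }
  num / den
}

#' Monte-Carlo permutation estimate of the correlation-screen FDR
#'
#' For each threshold, counts the features whose absolute Spearman
#' correlation with the marker reaches the threshold, then repeats the count
#' after randomly permuting the marker across samples. The FDR estimate at a
#' threshold is the mean null count divided by the observed count (capped
#' at 1).
#'
#' @param F Feature x sample numeric matrix.
#' @param marker Numeric vector over the samples (must not be constant).
#' @param thresholds Strictly increasing values in (0, 1].
#' @param n_perm Number of random permutations (the study convention is
#'   1000; smaller values trade precision for speed).
#' @param seed Integer seed controlling the permutations.
#' @return A data.frame with columns threshold, observed_count,
#'   mean_null_count and fdr.
#' @export
permutation_fdr <- function(F, marker, thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must lie in (0, 1]")
  if (length(unique(marker)) < 2L) stop("marker is constant")
  if (ncol(F) != length(marker)) stop("marker length does not match sample count")
  const <- apply(F, 1L, function(r) length(unique(r)) < 2L)
  ranks <- t(apply(F[!const, , drop = FALSE], 1L, rank))
  rs <- ranks - rowMeans(ranks)
  rs <- rs / sqrt(rowSums(rs^2))
  mr <- rank(marker)
  count_at <- function(mrank) {
    z <- mrank - mean(mrank)
    z <- z / sqrt(sum(z^2))
    rho <- abs(as.vector(rs %*% z))
    vapply(thresholds, function(th) sum(rho >= th), numeric(1L))
  }
  observed <- count_at(mr)
  set.seed(seed)
  null_counts <- matrix(0, n_perm, length(thresholds))
  m <- length(marker)
  for (b in seq_len(n_perm)) {
    null_counts[b, ] <- count_at(mr[sample.int(m)])
  }
  mean_null <- colMeans(null_counts)
  data.frame(threshold = thresholds,
             observed_count = as.integer(observed),
             mean_null_count = mean_null,
             fdr = pmin(1, mean_null / pmax(observed, 1)))
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting ARI from the contingency table of the two
#' labelings; 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Named cluster labelings over the same element set (names
#'   matter, label values do not).
#' @return ARI, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b))) {
    stop("partitions must be named over the same element set")
  }
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
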