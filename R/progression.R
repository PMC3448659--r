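# Jensen-Shannon-divergence progression quantifiers and Spearman screening.
#
# Each sample's positive expression vector over the signature's features is
# normalized to a unit-sum probability profile; the divergence of a sample
# from the average profile of the control (or severe) group is a continuous
# disease-progression score. Natural logarithms throughout, so JSD is
# bounded by ln 2.

#' Normalize a positive vector to a probability profile
#'
#' @param x Strictly positive numeric vector (one sample's expression over
#'   the signature features).
#' @return A unit-sum nonnegative vector, names preserved.
#' @export
normalize_profile <- function(x) {
  if (length(x) == 0L) stop("empty profile")
  if (any(!is.finite(x)) || any(x <= 0)) stop("profile entries must be strictly positive")
  x / sum(x)
}

#' Shannon entropy of a probability profile (nats)
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`.
#'
#' @param p Nonnegative vector summing to 1 (tolerance 1e-9).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-9) stop("profile does not sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Jensen-Shannon divergence between two profiles (nats)
#'
#' `H((P+Q)/2) - (H(P) + H(Q))/2`: symmetric, zero iff the profiles are
#' equal, and bounded above by ln 2.
#'
#' @param p,q Probability profiles over the same features in the same order
#'   (checked via names when present).
#' @return Divergence in `[0, ln 2]`.
#' @export
jensen_shannon_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("profile length mismatch")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("profile features do not match")
  }
  h <- shannon_entropy((p + q) / 2) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  min(max(h, 0), log(2))  # clamp rounding noise to the analytic bounds
}

#' Average characteristic profile of a sample group
#'
#' The arithmetic mean of the members' normalized profiles (each member is
#' weighted equally regardless of its overall intensity); the mean of
#' unit-sum vectors is unit-sum.
#'
#' @param X Strictly positive expression matrix.
#' @param member_samples Nonempty character vector of sample ids.
#' @return A probability profile over `rownames(X)`.
#' @export
group_profile <- function(X, member_samples) {
  if (length(member_samples) == 0L) stop("empty member list")
  missing <- setdiff(member_samples, colnames(X))
  if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  profs <- apply(X[, member_samples, drop = FALSE], 2L, normalize_profile)
  rowMeans(profs)
}

#' Per-sample divergence from the control and severe group profiles
#'
#' @param X Strictly positive expression matrix over the signature features.
#' @param control_ids,severe_ids Sample ids of the reference groups.
#' @param sample_ids Samples to score (default: all columns of `X`).
#' @return A data.frame with columns sample_id, jsd_control and jsd_severe.
#' @export
jsd_scores <- function(X, control_ids, severe_ids, sample_ids = colnames(X)) {
  validate_expression(X, require_positive = TRUE)
  missing <- setdiff(sample_ids, colnames(X))
  if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  ctrl <- group_profile(X, control_ids)
  sev <- group_profile(X, severe_ids)
  res <- vapply(sample_ids, function(s) {
    p <- normalize_profile(X[, s])
    c(jensen_shannon_divergence(p, ctrl), jensen_shannon_divergence(p, sev))
  }, numeric(2L))
  data.frame(sample_id = sample_ids,
             jsd_control = res[1L, ], jsd_severe = res[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data; ties receive average ranks.
#' Errors on constant input rather than returning NA, so callers that must
#' tolerate constant features handle it explicitly (see [correlate_all()]).
#'
#' @param x,y Numeric vectors, equal length of at least 3, each with at least
#'   2 distinct values.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation of every feature against a marker vector
#'
#' Constant features yield NA with a warning instead of an error, so a scan
#' over many (meta)features survives degenerate rows.
#'
#' @param F Feature x sample numeric matrix.
#' @param marker Numeric vector, one value per sample.
#' @return Named numeric vector of correlations, NA for flagged features.
#' @export
correlate_all <- function(F, marker) {
  if (ncol(F) != length(marker)) stop("marker length does not match sample count")
  if (length(unique(marker)) < 2L) stop("marker is constant")
  const <- apply(F, 1L, function(r) length(unique(r)) < 2L)
  if (any(const)) {
    warning(sum(const), " constant feature(s) flagged with NA correlation")
  }
  rho <- rep(NA_real_, nrow(F))
  names(rho) <- rownames(F)
  if (any(!const)) {
    ranks <- t(apply(F[!const, , drop = FALSE], 1L, rank))
    rho[!const] <- as.vector(stats::cor(t(ranks), rank(marker)))
  }
  rho
}
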