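# Planted-block synthetic expression data.
#
# Each block shares a latent standard-normal factor over samples; a feature
# in block k is exp(a * z_k + noise), so values are strictly positive with
# an intensity-like log-normal skew, and the log-values of two features in
# the same block have expected Pearson correlation rho_within
# (a = noise_sd * sqrt(rho / (1 - rho)) makes a^2 / (a^2 + noise_sd^2) =
# rho). Marker vectors are blends of a block's latent factor with fresh
# noise, calibrated to a target correlation with the block members.

#' Generate a positive expression matrix with planted correlation blocks
#'
#' @param n_blocks Number of blocks.
#' @param features_per_block Features in each block (recycled to length
#'   `n_blocks`).
#' @param n_samples Number of samples (at least 5).
#' @param rho_within Expected within-block correlation of log-values, in
#'   (0, 1).
#' @param noise_sd Standard deviation of the per-feature log-scale noise.
#' @param seed Integer seed; the dataset is a pure function of the
#'   parameters.
#' @return A `planted_dataset`: `X` (strictly positive matrix, features
#'   `B<k>_F<j>` x samples `S<i>`), `labels` (named block id per feature),
#'   `latents` (block x sample matrix), `params`.
#' @export
planted_expression <- function(n_blocks = 5L, features_per_block = 30L,
                               n_samples = 17L, rho_within = 0.9,
                               noise_sd = 0.3, seed = 1L) {
  if (n_samples < 5L) stop("need at least 5 samples")
  if (n_blocks < 1L || any(features_per_block < 1L)) stop("invalid shape")
  if (rho_within <= 0 || rho_within >= 1) stop("rho_within must be in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  sizes <- rep_len(features_per_block, n_blocks)
  set.seed(seed)
  latents <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples,
                    dimnames = list(paste0("B", seq_len(n_blocks)),
                                    paste0("S", seq_len(n_samples))))
  a <- noise_sd * sqrt(rho_within / (1 - rho_within))
  rows <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    eps <- matrix(stats::rnorm(sizes[k] * n_samples, sd = noise_sd),
                  sizes[k], n_samples)
    logx <- matrix(rep(a * latents[k, ], each = sizes[k]), sizes[k], n_samples) + eps
    rownames(logx) <- sprintf("B%d_F%02d", k, seq_len(sizes[k]))
    rows[[k]] <- exp(logx)
  }
  X <- do.call(rbind, rows)
  colnames(X) <- colnames(latents)
  labels <- rep(seq_len(n_blocks), sizes)
  names(labels) <- rownames(X)
  structure(list(X = X, labels = labels, latents = latents,
                 params = list(n_blocks = n_blocks, sizes = sizes,
                               n_samples = n_samples, rho_within = rho_within,
                               noise_sd = noise_sd, seed = seed)),
            class = "planted_dataset")
}

#' Generate a marker vector correlated with one planted block
#'
#' The marker is `c * z_k + sqrt(1 - c^2) * noise` with the latent and
#' noise standardized, where the blend weight `c` is calibrated so the
#' expected correlation with the block's members is about `rho_target`
#' (members correlate with the latent at `sqrt(rho_within)`, so
#' `c = min(1, rho_target / sqrt(rho_within))`). `rho_target = 0` yields a
#' pure-noise null marker.
#'
#' @param dataset A `planted_dataset`.
#' @param block_id Block to target.
#' @param rho_target Target absolute correlation with block members, in
#'   `[0, 1]`.
#' @param seed Integer seed for the fresh noise.
#' @return Named numeric vector over the dataset's samples.
#' @export
planted_marker <- function(dataset, block_id, rho_target = 0.9, seed = 1L) {
  stopifnot(inherits(dataset, "planted_dataset"))
  if (!block_id %in% seq_len(dataset$params$n_blocks)) {
    stop("unknown block: ", block_id)
  }
  if (rho_target < 0 || rho_target > 1) stop("rho_target must be in [0, 1]")
  z <- dataset$latents[block_id, ]
  z <- (z - mean(z)) / stats::sd(z)
  set.seed(seed)
  eps <- stats::rnorm(length(z))
  eps <- eps - mean(eps)
  # orthogonalize the noise against the latent so the blend weight is exact
  eps <- eps - z * sum(eps * z) / sum(z * z)
  eps <- eps / stats::sd(eps)
  cc <- min(1, rho_target / sqrt(dataset$params$rho_within))
  marker <- cc * z + sqrt(max(0, 1 - cc^2)) * eps
  names(marker) <- colnames(dataset$latents)
  marker
}
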