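# Independent definitional oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# average ranks computed from first principles (no rank())
oracle_avg_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1L))
}

# Spearman = Pearson on average ranks, Pearson written out explicitly
oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

# term-by-term entropy and JSD
oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  oracle_entropy(m) - (oracle_entropy(p) + oracle_entropy(q)) / 2
}

# ARI from raw pair agreement counts (no contingency table)
oracle_ari <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# definitional homogeneity / separation
oracle_homogeneity <- function(X, assignment, singletons_as_one = TRUE) {
  sims <- numeric(0)
  for (cid in unique(assignment)) {
    m <- names(assignment)[assignment == cid]
    if (length(m) == 1L) {
      if (singletons_as_one) sims <- c(sims, 1)
      next
    }
    centroid <- colMeans(X[m, , drop = FALSE])
    for (f in m) sims <- c(sims, oracle_pearson(X[f, ], centroid))
  }
  mean(sims)
}

oracle_separation <- function(X, assignment) {
  cids <- unique(assignment)
  num <- 0; den <- 0
  for (i in seq_len(length(cids) - 1)) {
    for (j in (i + 1):length(cids)) {
      mi <- names(assignment)[assignment == cids[i]]
      mj <- names(assignment)[assignment == cids[j]]
      ci <- colMeans(X[mi, , drop = FALSE])
      cj <- colMeans(X[mj, , drop = FALSE])
      w <- length(mi) * length(mj)
      num <- num + w * oracle_pearson(ci, cj)
      den <- den + w
    }
  }
  num / den
}

# exhaustive minimum spanning weight of a complete graph: enumerate every
# (n-1)-edge subset, keep the acyclic connected ones, minimize total weight
.spanning_subset_cache <- new.env(parent = emptyenv())

oracle_spanning_subsets <- function(n) {
  key <- as.character(n)
  if (!is.null(.spanning_subset_cache[[key]])) return(.spanning_subset_cache[[key]])
  edges <- utils::combn(n, 2L)
  m <- ncol(edges)
  subsets <- utils::combn(m, n - 1L)
  is_tree <- function(cols) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in cols) {
      ra <- find(edges[1L, k]); rb <- find(edges[2L, k])
      if (ra == rb) return(FALSE)
      parent[ra] <- rb
    }
    TRUE
  }
  keep <- apply(subsets, 2L, is_tree)
  ind <- matrix(0, m, sum(keep))
  kept <- subsets[, keep, drop = FALSE]
  for (j in seq_len(ncol(kept))) ind[kept[, j], j] <- 1
  res <- list(edges = edges, indicator = ind)
  .spanning_subset_cache[[key]] <- res
  res
}

oracle_mst_weight <- function(D) {
  n <- nrow(D)
  ss <- oracle_spanning_subsets(n)
  w <- D[t(ss$edges)]
  min(as.vector(w %*% ss$indicator))
}

# random symmetric distance matrix with zero diagonal and named nodes
random_distance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2)
  D <- D + t(D)
  dimnames(D) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  D
}

# strictly positive random expression fixture
random_expression <- function(n_features, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(exp(rnorm(n_features * n_samples)), n_features, n_samples,
              dimnames = list(sprintf("F%02d", seq_len(n_features)),
                              sprintf("S%02d", seq_len(n_samples))))
  X
}

# hand-built annotated spanning forest
make_forest <- function(nodes, a, b, weight, p = NA_integer_) {
  edges <- data.frame(ai = match(a, nodes), bi = match(b, nodes),
                      a = a, b = b, weight = weight,
                      p = rep(as.integer(p), length.out = length(a)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes), class = "spanning_forest")
}
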