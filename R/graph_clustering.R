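# Modified MST-kNN partitioning.
#
# Features become nodes of a q-nearest-neighbour graph under the correlation
# distance d = 1 - |Spearman|. A minimum spanning tree of that graph is
# annotated per edge with p = min(f(a,b), f(b,a)), where f(a,b) is the
# 1-based position of b in a's sorted nearest-neighbour list. Components are
# then split recursively: edges whose p exceeds the component's threshold
# t = floor(ln n_c) are eliminated (an edge with p > k is exactly an edge
# whose endpoints are not within each other's k nearest neighbours), until
# every component is declared a cluster.

#' Correlation distance matrix
#'
#' `d(i, j) = 1 - |Spearman(x_i, x_j)|`, so features that are strongly
#' correlated in either direction are close. Constant features (undefined
#' correlation) are dropped with a warning; their ids are recorded in the
#' `"dropped"` attribute.
#'
#' @param X Feature x sample numeric matrix with at least 3 samples.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal, feature ids as
#'   dimnames.
#' @export
correlation_distance <- function(X) {
  if (ncol(X) < 3L) stop("need at least 3 samples")
  const <- apply(X, 1L, function(r) length(unique(r)) < 2L)
  dropped <- rownames(X)[const]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " constant feature(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
    X <- X[!const, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("fewer than 2 usable features")
  rho <- stats::cor(t(X), method = "spearman")
  D <- 1 - abs(rho)
  D[D < 0] <- 0
  diag(D) <- 0
  attr(D, "dropped") <- dropped
  D
}

#' Global nearest-neighbour ranking
#'
#' For each node `a`, every other node is ranked by distance (ties broken by
#' the smaller node index in the distance matrix's order). The result
#' `f[a, b]` is the 1-based position of `b` in `a`'s sorted neighbour list.
#' Ranks are computed once from the full distance matrix and reused for
#' every component during partitioning.
#'
#' @param D Symmetric distance matrix.
#' @return Integer matrix of ranks with NA diagonal.
#' @export
neighbor_ranking <- function(D) {
  n <- nrow(D)
  f <- matrix(NA_integer_, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], others)]
    f[i, ord] <- seq_len(n - 1L)
  }
  f
}

#' Initial neighbourhood size
#'
#' `q = floor(ln n) + 1`, clamped to `n - 1`: the smallest k above ln(n),
#' the scale at which the k-NN graph is expected to contain the MST.
#'
#' @param n Number of nodes (at least 2).
#' @return A positive integer.
#' @export
initial_q <- function(n) {
  if (n < 2L) stop("need at least 2 nodes")
  min(floor(log(n)) + 1L, n - 1L)
}

#' Build the symmetrized q-nearest-neighbour graph
#'
#' An undirected edge `{a, b}` is present iff `b` is among `a`'s `q` nearest
#' neighbours or vice versa. Connectivity is not guaranteed.
#'
#' @param D Symmetric distance matrix.
#' @param q Neighbourhood size, `1 <= q <= n - 1`.
#' @param ranking Optional precomputed [neighbor_ranking()] of `D`.
#' @return A `qnn_graph`: list with `edges` (data.frame ai, bi, a, b, weight),
#'   `nodes`, `q`.
#' @export
build_qnn_graph <- function(D, q, ranking = neighbor_ranking(D)) {
  n <- nrow(D)
  if (q < 1L || q > n - 1L) stop("q must be in [1, n-1]")
  near <- ranking <= q
  near[is.na(near)] <- FALSE
  keep <- (near | t(near)) & upper.tri(near)
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(ai = idx[, 1L], bi = idx[, 2L],
                      a = rownames(D)[idx[, 1L]], b = rownames(D)[idx[, 2L]],
                      weight = D[idx], stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = rownames(D), q = as.integer(q)),
            class = "qnn_graph")
}

.is_connected <- function(edges, n) {
  if (n <= 1L) return(TRUE)
  comp <- .components(edges$ai, edges$bi, n)
  length(unique(comp)) == 1L
}

# connected component labels via union-find
.components <- function(ai, bi, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ai)) {
    ra <- find(ai[k]); rb <- find(bi[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Smallest connected q-NN graph at or above a starting q
#'
#' Escalates `q` by 1 until the symmetrized q-NN graph is connected
#' (`q = n - 1` always is).
#'
#' @param D Symmetric distance matrix.
#' @param q0 Starting neighbourhood size (default [initial_q()]).
#' @param ranking Optional precomputed ranking.
#' @return List with `graph` (a `qnn_graph`) and `q_used`.
#' @export
ensure_connected <- function(D, q0 = initial_q(nrow(D)), ranking = neighbor_ranking(D)) {
  n <- nrow(D)
  q <- min(max(1L, q0), n - 1L)
  repeat {
    g <- build_qnn_graph(D, q, ranking)
    if (.is_connected(g$edges, n)) return(list(graph = g, q_used = q))
    q <- q + 1L
  }
}

#' Minimum spanning tree with deterministic tie-breaking
#'
#' Kruskal's algorithm over edges sorted by ascending (weight, smaller
#' endpoint index, larger endpoint index), so equal-weight inputs always
#' yield the same tree.
#'
#' @param G A `qnn_graph` (must be connected).
#' @return A `spanning_forest`: list with `edges` (ai, bi, a, b, weight, p)
#'   and `nodes`; `p` is NA until [annotate_edges()].
#' @export
minimum_spanning_tree <- function(G) {
  e <- G$edges
  n <- length(G$nodes)
  if (!.is_connected(e, n)) stop("input graph is disconnected; use ensure_connected()")
  lo <- pmin(e$ai, e$bi); hi <- pmax(e$ai, e$bi)
  ord <- order(e$weight, lo, hi)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- logical(nrow(e))
  n_taken <- 0L
  for (k in ord) {
    ra <- find(e$ai[k]); rb <- find(e$bi[k])
    if (ra != rb) {
      parent[ra] <- rb
      take[k] <- TRUE
      n_taken <- n_taken + 1L
      if (n_taken == n - 1L) break
    }
  }
  edges <- e[take, c("ai", "bi", "a", "b", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  edges$p <- NA_integer_
  structure(list(edges = edges, nodes = G$nodes), class = "spanning_forest")
}

#' Annotate spanning-tree edges with the mutual neighbour rank p
#'
#' `p(a, b) = min(f(a, b), f(b, a))`: an edge has `p > k` exactly when
#' neither endpoint is among the other's k nearest neighbours.
#'
#' @param forest A `spanning_forest`.
#' @param ranking A [neighbor_ranking()] covering every tree node.
#' @return The forest with integer `p` set on every edge.
#' @export
annotate_edges <- function(forest, ranking) {
  stopifnot(inherits(forest, "spanning_forest"))
  miss <- setdiff(forest$nodes, rownames(ranking))
  if (length(miss)) stop("node(s) missing from ranking: ", paste(miss, collapse = ", "))
  e <- forest$edges
  fa <- ranking[cbind(e$a, e$b)]
  fb <- ranking[cbind(e$b, e$a)]
  forest$edges$p <- as.integer(pmin(fa, fb))
  forest
}

#' Edge-elimination threshold for a component
#'
#' `t = floor(ln n_c)`; criterion C1 removes edges with `p > t`.
#'
#' @param n_c Component size (at least 2).
#' @return Nonnegative integer threshold.
#' @examples
#' component_threshold(10) # 2
#' @export
component_threshold <- function(n_c) {
  if (n_c < 2L) stop("component must have at least 2 nodes")
  as.integer(floor(log(n_c)))
}

#' Decide whether and how to split one annotated component
#'
#' With `t = component_threshold(n_c)` and `p_max` the largest edge
#' annotation in the component, the exhaustive and mutually exclusive cases
#' are:
#' \itemize{
#'   \item MINSIZE: `n_c <= min_size` (default 3) — terminal cluster;
#'   \item C1: `p_max > t` — remove every edge with `p > t`;
#'   \item C3: `p_max = 1` or `p_max = t` — terminal cluster;
#'   \item C2: `1 < p_max < t` — remove every edge with `p = p_max`
#'     (policy `"pmax"`), or `p = p_max - 1` (policy `"pmax_minus_1"`,
#'     falling back to `p_max` when no such edge exists so that the recursion
#'     always progresses).
#' }
#'
#' @param component A connected, annotated `spanning_forest`.
#' @param min_size Components at or below this size are terminal.
#' @param c2_policy `"pmax"` (default) or `"pmax_minus_1"`.
#' @return A list: `criterion`, `terminal`, and for splits `removed` (edge
#'   rows) plus `subcomponents` (list of `spanning_forest`s).
#' @export
partition_component <- function(component, min_size = 3L, c2_policy = c("pmax", "pmax_minus_1")) {
  stopifnot(inherits(component, "spanning_forest"))
  c2_policy <- match.arg(c2_policy)
  n_c <- length(component$nodes)
  if (n_c == 0L) stop("empty component")
  e <- component$edges
  if (n_c <= min_size) {
    return(list(criterion = "MINSIZE", terminal = TRUE))
  }
  if (anyNA(e$p)) stop("component edges are not annotated")
  t <- component_threshold(n_c)
  p_max <- max(e$p)
  if (p_max > t) {
    drop <- e$p > t
    criterion <- "C1"
  } else if (p_max == 1L || p_max == t) {
    return(list(criterion = "C3", terminal = TRUE))
  } else {
    target <- if (c2_policy == "pmax_minus_1" && any(e$p == p_max - 1L)) p_max - 1L else p_max
    drop <- e$p == target
    criterion <- "C2"
  }
  kept <- e[!drop, , drop = FALSE]
  ai <- match(kept$a, component$nodes)
  bi <- match(kept$b, component$nodes)
  comp <- .components(ai, bi, n_c)
  subs <- lapply(split(seq_len(n_c), comp), function(members) {
    nodes <- component$nodes[members]
    sub_e <- kept[kept$a %in% nodes & kept$b %in% nodes, , drop = FALSE]
    rownames(sub_e) <- NULL
    structure(list(edges = sub_e, nodes = nodes), class = "spanning_forest")
  })
  names(subs) <- NULL
  list(criterion = criterion, terminal = FALSE,
       removed = e[drop, , drop = FALSE], subcomponents = subs)
}

#' Cluster features with the modified MST-kNN algorithm
#'
#' Orchestrates the full method: correlation distance, smallest connected
#' q-NN graph starting from `q = floor(ln n) + 1`, deterministic MST, edge
#' annotation `p = min(f(a,b), f(b,a))`, then recursive component
#' partitioning (annotations are fixed once; the threshold
#' `t = floor(ln n_c)` is recomputed for every component).
#'
#' @param X Feature x sample numeric matrix (at least 3 samples). Constant
#'   features are dropped with a warning and are absent from the result.
#' @param min_size Terminal component size (default 3).
#' @param q Optional override of the starting neighbourhood size.
#' @param c2_policy Edge-removal policy for criterion C2 (see
#'   [partition_component()]).
#' @return An `mstknn_clustering`: `assignment` (feature id to cluster id,
#'   ids contiguous from 0), `split_log` (one row per component decision),
#'   `q_used`, plus the annotated `forest` used for the partition.
#' @examples
#' sim <- planted_expression(n_blocks = 2, features_per_block = 10,
#'                           n_samples = 12, seed = 1)
#' cl <- mstknn(sim$X)
#' table(cl$assignment, sim$labels)
#' @export
mstknn <- function(X, min_size = 3L, q = NULL, c2_policy = c("pmax", "pmax_minus_1")) {
  c2_policy <- match.arg(c2_policy)
  D <- correlation_distance(X)
  ranking <- neighbor_ranking(D)
  conn <- ensure_connected(D, q %||% initial_q(nrow(D)), ranking)
  forest <- annotate_edges(minimum_spanning_tree(conn$graph), ranking)
  queue <- list(forest)
  clusters <- list()
  log_rows <- list()
  while (length(queue)) {
    comp <- queue[[1L]]
    queue <- queue[-1L]
    if (length(comp$nodes) == 1L) {
      # an isolated node produced by a split is a terminal singleton
      decision <- list(criterion = "MINSIZE", terminal = TRUE)
    } else {
      decision <- partition_component(comp, min_size = min_size, c2_policy = c2_policy)
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      component_size = length(comp$nodes), criterion = decision$criterion,
      removed_edge_count = if (decision$terminal) 0L else nrow(decision$removed),
      stringsAsFactors = FALSE)
    if (decision$terminal) {
      clusters[[length(clusters) + 1L]] <- comp$nodes
    } else {
      queue <- c(queue, decision$subcomponents)
    }
  }
  assignment <- integer(0)
  nm <- character(0)
  for (k in seq_along(clusters)) {
    assignment <- c(assignment, rep(k - 1L, length(clusters[[k]])))
    nm <- c(nm, clusters[[k]])
  }
  names(assignment) <- nm
  res <- clustering_result(assignment, split_log = do.call(rbind, log_rows),
                           q_used = conn$q_used)
  res$forest <- forest
  res
}
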