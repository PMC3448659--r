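test_that("correlation distance is sign-blind and matches the rank oracle", {
  X <- random_expression(4, 5, seed = 31)
  X <- rbind(X, DUP = X[1, ], NEG = max(X[2, ]) + 1 - X[2, ])
  D <- correlation_distance(X)
  expect_equal(D["F01", "DUP"], 0)          # duplicate feature
  expect_equal(D["F02", "NEG"], 0)          # anti-monotone feature
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  for (i in rownames(X)) {
    for (j in rownames(X)) {
      expect_equal(D[i, j], 1 - abs(oracle_spearman(X[i, ], X[j, ])),
                   info = paste(i, j))
    }
  }
  expect_error(correlation_distance(X[, 1:2]), "at least 3 samples")
  expect_warning(correlation_distance(rbind(X, K = rep(1, 5))), "constant")
})

test_that("initial q and the component threshold follow floor(ln n)", {
  expect_equal(initial_q(10), 3)
  expect_equal(initial_q(1372), 8)
  expect_equal(initial_q(3), 2)
  expect_equal(initial_q(2), 1)   # clamped to n - 1
  expect_error(initial_q(1), "at least 2")
  expect_equal(component_threshold(10), 2)
  expect_equal(component_threshold(1372), 7)
  expect_equal(component_threshold(4), 1)
  expect_error(component_threshold(1), "at least 2")
})

test_that("q-NN graph is the symmetrized union of directed neighbour lists", {
  # 3 nodes with d(1,2) < d(1,3) < d(2,3), q = 1:
  # 1 picks 2, 2 picks 1, 3 picks 1 -> edges {1,2} and {1,3}
  D <- matrix(c(0, .1, .2, .1, 0, .9, .2, .9, 0), 3, 3,
              dimnames = list(c("N1", "N2", "N3"), c("N1", "N2", "N3")))
  g <- build_qnn_graph(D, 1)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$a, g$edges$b), c("N1 N2", "N1 N3"))
  # q = n - 1 gives the complete graph
  g3 <- build_qnn_graph(D, 2)
  expect_equal(nrow(g3$edges), 3)
  expect_error(build_qnn_graph(D, 3), "q must be")
  # brute-force enumeration oracle on random instances
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    Dr <- random_distance(n)
    q <- sample(seq_len(n - 1), 1)
    g <- build_qnn_graph(Dr, q)
    got <- sort(paste(g$edges$ai, g$edges$bi))
    want <- character(0)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ord_i <- setdiff(order(Dr[i, ], seq_len(n)), i)
        ord_j <- setdiff(order(Dr[j, ], seq_len(n)), j)
        if (j %in% ord_i[1:q] || i %in% ord_j[1:q]) want <- c(want, paste(i, j))
      }
    }
    expect_identical(got, sort(want))
  }
})

test_that("q escalates until the graph connects", {
  # two tight pairs far apart: disconnected at q = 1, connected at q = 2
  D <- matrix(1, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.05
  D[3, 4] <- D[4, 3] <- 0.06
  D[1, 3] <- D[3, 1] <- 0.90
  D[2, 4] <- D[4, 2] <- 0.95
  dimnames(D) <- list(paste0("N", 1:4), paste0("N", 1:4))
  g1 <- build_qnn_graph(D, 1)
  expect_equal(nrow(g1$edges), 2)  # the two pairs only
  conn <- ensure_connected(D, 1)
  expect_equal(conn$q_used, 2)
  # already connected: q unchanged
  expect_equal(ensure_connected(D, 3)$q_used, 3)
  # n = 2: a single edge at q = 1
  D2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  c2 <- ensure_connected(D2, 1)
  expect_equal(c2$q_used, 1)
  expect_equal(nrow(c2$graph$edges), 1)
})

test_that("MST matches exhaustive search and breaks ties deterministically", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    D <- random_distance(n)
    g <- build_qnn_graph(D, n - 1)  # complete graph
    tree <- minimum_spanning_tree(g)
    expect_equal(nrow(tree$edges), n - 1)
    expect_equal(sum(tree$edges$weight), oracle_mst_weight(D))
  }
  # input already a tree is returned unchanged
  D <- random_distance(5, seed = 4)
  g <- build_qnn_graph(D, 4)
  t1 <- minimum_spanning_tree(g)
  g_tree <- g; g_tree$edges <- t1$edges[, c("ai", "bi", "a", "b", "weight")]
  t2 <- minimum_spanning_tree(g_tree)
  expect_equal(sort(paste(t2$edges$a, t2$edges$b)), sort(paste(t1$edges$a, t1$edges$b)))
  # all weights equal: the lexicographically forced star on node 1
  De <- matrix(1, 4, 4); diag(De) <- 0
  dimnames(De) <- list(paste0("N", 1:4), paste0("N", 1:4))
  te <- minimum_spanning_tree(build_qnn_graph(De, 3))
  expect_identical(paste(te$edges$ai, te$edges$bi), c("1 2", "1 3", "1 4"))
  # disconnected input errors
  gd <- build_qnn_graph(De, 3)
  gd$edges <- gd$edges[1, , drop = FALSE]
  expect_error(minimum_spanning_tree(gd), "disconnected")
})

test_that("MST total weight agrees with igraph on larger random graphs", {
  set.seed(123)
  for (rep in 1:5) {
    D <- random_distance(15)
    g <- build_qnn_graph(D, 14)
    tree <- minimum_spanning_tree(g)
    ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
    ref <- igraph::mst(ig, weights = igraph::E(ig)$weight)
    expect_equal(sum(tree$edges$weight), sum(igraph::E(ref)$weight))
  }
})

test_that("edge annotation p = min of the two neighbour ranks", {
  D <- random_distance(6, seed = 55)
  R <- neighbor_ranking(D)
  # ranking is a permutation of 1..n-1 per node
  for (i in 1:6) expect_setequal(R[i, -i], 1:5)
  conn <- ensure_connected(D, 2)
  tree <- annotate_edges(minimum_spanning_tree(conn$graph), R)
  for (k in seq_len(nrow(tree$edges))) {
    a <- tree$edges$ai[k]; b <- tree$edges$bi[k]
    ord_a <- setdiff(order(D[a, ], seq_len(6)), a)
    ord_b <- setdiff(order(D[b, ], seq_len(6)), b)
    expect_equal(tree$edges$p[k], min(which(ord_a == b), which(ord_b == a)))
  }
  # mutual nearest neighbours get p = 1
  Dm <- matrix(c(0, .1, .8, .1, 0, .7, .8, .7, 0), 3, 3,
               dimnames = list(paste0("N", 1:3), paste0("N", 1:3)))
  Rm <- neighbor_ranking(Dm)
  expect_equal(Rm["N1", "N2"], 1L)
  expect_equal(Rm["N2", "N1"], 1L)
  fm <- make_forest(paste0("N", 1:3), a = c("N1", "N2"), b = c("N2", "N3"),
                    weight = c(.1, .7))
  am <- annotate_edges(fm, Rm)
  expect_equal(am$edges$p[1], 1L)
  expect_error(annotate_edges(make_forest("Z", character(0), character(0),
                                          numeric(0)), Rm), "missing from ranking")
})

test_that("partition criteria C1/C2/C3/MINSIZE fire as specified", {
  # n_c = 3 is terminal regardless of p
  f3 <- make_forest(c("A", "B", "C"), a = c("A", "B"), b = c("B", "C"),
                    weight = c(.1, .2), p = c(9L, 9L))
  expect_identical(partition_component(f3)$criterion, "MINSIZE")
  # n = 10 path with one edge of p = 3, rest p <= 2: t = 2, C1 removes it
  nodes <- paste0("F", 1:10)
  f10 <- make_forest(nodes, a = nodes[1:9], b = nodes[2:10],
                     weight = seq(.1, .9, by = .1),
                     p = c(1L, 2L, 1L, 1L, 3L, 1L, 2L, 1L, 1L))
  d <- partition_component(f10)
  expect_identical(d$criterion, "C1")
  expect_equal(nrow(d$removed), 1)
  expect_identical(c(d$removed$a, d$removed$b), c("F5", "F6"))
  expect_equal(sort(lengths(lapply(d$subcomponents, `[[`, "nodes"))), c(5, 5))
  # all p = 1 is a terminal cluster via C3
  f1 <- make_forest(nodes, a = nodes[1:9], b = nodes[2:10],
                    weight = seq(.1, .9, by = .1), p = rep(1L, 9))
  expect_identical(partition_component(f1)$criterion, "C3")
  # p_max = t is also terminal via C3
  f2 <- make_forest(nodes, a = nodes[1:9], b = nodes[2:10],
                    weight = seq(.1, .9, by = .1),
                    p = c(rep(1L, 8), 2L))
  expect_identical(partition_component(f2)$criterion, "C3")
  # 1 < p_max < t: C2 removes the p_max edges (default policy)
  nodes30 <- sprintf("G%02d", 1:30)   # t = floor(ln 30) = 3
  f30 <- make_forest(nodes30, a = nodes30[1:29], b = nodes30[2:30],
                     weight = rep(.1, 29), p = c(rep(1L, 27), 2L, 2L))
  d30 <- partition_component(f30)
  expect_identical(d30$criterion, "C2")
  expect_equal(nrow(d30$removed), 2)
  expect_equal(length(d30$subcomponents), 3)
  # alternative policy removes p_max - 1 edges instead
  d30b <- partition_component(f30, c2_policy = "pmax_minus_1")
  expect_identical(d30b$criterion, "C2")
  expect_true(all(d30b$removed$p == 1L))
  expect_error(partition_component(structure(list(edges = NULL, nodes = character(0)),
                                             class = "spanning_forest")), "empty")
})

test_that("edge elimination is exactly the mutual k-NN exclusion rule", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    D <- random_distance(n)
    R <- neighbor_ranking(D)
    conn <- ensure_connected(D)
    tree <- annotate_edges(minimum_spanning_tree(conn$graph), R)
    for (k in sample(seq_len(n - 2), 3)) {
      for (e in seq_len(nrow(tree$edges))) {
        a <- tree$edges$ai[e]; b <- tree$edges$bi[e]
        ord_a <- setdiff(order(D[a, ], seq_len(n)), a)
        ord_b <- setdiff(order(D[b, ], seq_len(n)), b)
        neither_knn <- !(b %in% ord_a[1:k]) && !(a %in% ord_b[1:k])
        expect_identical(tree$edges$p[e] > k, neither_knn)
      }
    }
  }
})

test_that("clustering is deterministic, total, and merges duplicate-like features", {
  # four copies of one varying vector form a single cluster
  base <- c(1, 3, 2, 5, 4)
  X <- rbind(A = base, B = base, C = base, D = base)
  colnames(X) <- paste0("S", 1:5)
  cl <- mstknn(X)
  expect_equal(length(unique(cl$assignment)), 1)
  expect_setequal(names(cl$assignment), c("A", "B", "C", "D"))
  # identical input, identical output (run twice)
  X2 <- random_expression(20, 8, seed = 77)
  c1 <- mstknn(X2); c2 <- mstknn(X2)
  expect_identical(c1$assignment, c2$assignment)
  expect_identical(c1$split_log, c2$split_log)
  # the assignment is a partition: every feature exactly once
  expect_setequal(names(c1$assignment), rownames(X2))
  expect_identical(sort(unique(c1$assignment)),
                   seq_len(length(unique(c1$assignment))) - 1L)
})

test_that("clustering is invariant under per-feature monotone transforms", {
  X <- random_expression(18, 9, seed = 101)
  c1 <- mstknn(X)
  Xt <- X
  Xt[seq(1, 17, by = 2), ] <- exp(Xt[seq(1, 17, by = 2), ])   # monotone per feature
  Xt[seq(2, 18, by = 2), ] <- Xt[seq(2, 18, by = 2), ]^3
  c2 <- mstknn(Xt)
  expect_identical(c1$assignment, c2$assignment)
})

test_that("split log records every decision and removals are bounded", {
  X <- random_expression(40, 10, seed = 5)
  cl <- mstknn(X)
  expect_true(all(cl$split_log$criterion %in% c("C1", "C2", "C3", "MINSIZE")))
  expect_lte(sum(cl$split_log$removed_edge_count), 40 - 1)
  terminal <- cl$split_log$removed_edge_count == 0
  expect_equal(sum(terminal), length(unique(cl$assignment)))
  expect_equal(sum(cl$split_log$component_size[terminal]), length(cl$assignment))
})
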