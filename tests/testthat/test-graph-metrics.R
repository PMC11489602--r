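test_that("degree and strength follow the significance mask", {
  empty <- make_network(matrix(0, 4, 4))
  expect_equal(unname(node_degree(empty)), rep(0L, 4))
  expect_equal(unname(node_strength(empty)), rep(0, 4))

  complete <- make_network(graph_complete(4) * 0.1)
  expect_equal(unname(node_degree(complete)), rep(3L, 4))

  star <- make_network(graph_star(5) * 0.2)
  expect_equal(unname(node_degree(star)), c(4L, 1L, 1L, 1L, 1L))

  # single edge of weight 0.23: both endpoints inherit it as strength
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.23
  net <- make_network(W)
  expect_equal(unname(node_strength(net)), c(0.23, 0.23, 0, 0))

  # linearity: doubling weights doubles strengths
  net2 <- make_network(2 * W)
  expect_equal(node_strength(net2), 2 * node_strength(net))

  # handshake identities
  set.seed(5)
  A <- matrix(0, 6, 6)
  A[upper.tri(A)] <- runif(15) * (runif(15) < 0.5)
  A <- A + t(A)
  rnet <- make_network(A)
  n_edges <- sum(rnet$significant[upper.tri(A)])
  expect_equal(sum(node_degree(rnet)), 2 * n_edges)
  expect_equal(sum(node_strength(rnet)), 2 * sum(A[upper.tri(A)]))
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  # canonical cases
  path3 <- make_network(graph_path(3) * 0.1)
  expect_equal(unname(node_betweenness(path3)), c(0, 1, 0))
  expect_equal(unname(node_betweenness(make_network(graph_complete(5) * 0.1))),
               rep(0, 5))

  # sweep of random graphs on <= 7 nodes against the brute-force oracle
  set.seed(23)
  for (i in 1:40) {
    k <- sample(3:7, 1)
    A <- matrix(0, k, k)
    A[upper.tri(A)] <- as.numeric(runif(choose(k, 2)) < 0.45)
    A <- A + t(A)
    net <- make_network(A * 0.1)
    expect_equal(unname(node_betweenness(net)), oracle_betweenness(A),
                 tolerance = 1e-10)
  }
})

test_that("inverse-weight betweenness uses 1/MI path lengths", {
  # a--b--c chain plus a direct weak a--c edge: with inverse-weight
  # lengths the two-hop strong route is shorter, so b lies on the a-c path
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.1
  net <- make_network(W)
  expect_equal(unname(node_betweenness(net, mode = "unweighted")), rep(0, 3))
  expect_equal(unname(node_betweenness(net, mode = "inverse-weight")),
               c(0, 1, 0))
  expect_error(node_betweenness(net, mode = "bogus"))
})

test_that("core-periphery local search attains the exhaustive optimum", {
  # ideal planted core: 5-clique with every periphery node tied to the
  # whole core and no periphery-periphery edges -- the exact pattern the
  # Borgatti-Everett quality idealizes, so recovery must be perfect
  k_core <- 5; k_peri <- 5
  k <- k_core + k_peri
  W <- matrix(0, k, k)
  W[seq_len(k_core), ] <- 0.2
  W[, seq_len(k_core)] <- 0.2
  diag(W) <- 0
  net <- make_network(W)
  res <- core_periphery(net, restarts = 50, seed = 2)
  expect_equal(unname(res$is_core),
               rep(c(TRUE, FALSE), c(k_core, k_peri)))
  expect_equal(res$quality, 1.0, tolerance = 1e-12)

  # pendant wiring (one attachment per periphery node): the optimum under
  # the correlation quality need not be the planted split, but the local
  # search must still find the exhaustive optimum
  Wp <- matrix(0, k, k)
  Wp[seq_len(k_core), seq_len(k_core)] <- 0.2
  for (p in seq_len(k_peri)) {
    Wp[k_core + p, p] <- Wp[p, k_core + p] <- 0.2
  }
  diag(Wp) <- 0
  netp <- make_network(Wp)
  resp <- core_periphery(netp, restarts = 50, seed = 2)
  expect_equal(resp$quality, oracle_core_quality(netp$weights * netp$significant),
               tolerance = 1e-12)

  # random weighted networks on <= 10 nodes
  set.seed(31)
  for (i in 1:8) {
    kk <- sample(4:10, 1)
    A <- matrix(0, kk, kk)
    A[upper.tri(A)] <- runif(choose(kk, 2)) * (runif(choose(kk, 2)) < 0.5)
    A <- A + t(A)
    if (all(A == 0)) next
    netr <- make_network(A)
    resr <- core_periphery(netr, restarts = 60, seed = i)
    expect_equal(resr$quality, oracle_core_quality(A), tolerance = 1e-10)
  }
})

test_that("core-periphery handles empty and relabeled networks", {
  empty <- make_network(matrix(0, 5, 5))
  res <- core_periphery(empty, restarts = 10, seed = 1)
  expect_false(any(res$is_core))
  expect_true(is.na(res$quality))
  expect_error(core_periphery(make_network(matrix(0, 2, 2))), ">= 3 nodes")

  # quality is invariant to node relabeling
  set.seed(8)
  A <- matrix(0, 6, 6)
  A[upper.tri(A)] <- runif(15) * (runif(15) < 0.6)
  A <- A + t(A)
  perm <- sample(6)
  q1 <- core_periphery(make_network(A), restarts = 40, seed = 3)$quality
  q2 <- core_periphery(make_network(A[perm, perm]), restarts = 40,
                       seed = 4)$quality
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("modularity partition recovers structure and reports true quality", {
  # two disconnected triangles -> exactly two modules, one per triangle
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 0.2
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 0.2
  W <- pmax(W, t(W))
  net <- make_network(W)
  part <- modularity_partition(net, restarts = 20, seed = 6)
  expect_equal(max(part$labels), 2)
  expect_length(unique(part$labels[1:3]), 1)
  expect_length(unique(part$labels[4:6]), 1)
  expect_false(part$labels[1] == part$labels[4])

  # reported quality equals the objective recomputed from the labels
  Wsig <- net$weights * net$significant
  expect_equal(part$quality,
               symptomnet:::modularity_value(Wsig, part$labels, 1),
               tolerance = 1e-12)
  # and igraph's modularity agrees at gamma = 1
  g <- symptomnet:::as_igraph(net)
  expect_equal(part$quality,
               igraph::modularity(g, part$labels,
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-12)

  # isolated nodes become singleton modules; labels ordered by size
  W2 <- matrix(0, 5, 5)
  W2[1, 2] <- W2[2, 3] <- W2[1, 3] <- 0.2
  W2 <- pmax(W2, t(W2))
  part2 <- modularity_partition(make_network(W2), restarts = 10, seed = 2)
  expect_equal(unname(part2$labels), c(1, 1, 1, 2, 3))
})

test_that("more restarts never lower the attained modularity", {
  set.seed(13)
  A <- matrix(0, 8, 8)
  A[upper.tri(A)] <- runif(28) * (runif(28) < 0.5)
  A <- A + t(A)
  net <- make_network(A)
  q1 <- modularity_partition(net, restarts = 1, seed = 7)$quality
  q5 <- modularity_partition(net, restarts = 5, seed = 7)$quality
  q25 <- modularity_partition(net, restarts = 25, seed = 7)$quality
  expect_lte(q1, q5 + 1e-12)
  expect_lte(q5, q25 + 1e-12)
})

test_that("the node-metric table mirrors the 7-column report layout", {
  set.seed(99)
  m <- symptom_matrix(cbind(
    smt = rep(c(1, 0), c(528, 1)),           # near-degenerate, excluded
    a = rbinom(529, 1, 0.5),
    b = rbinom(529, 1, 0.4),
    c = rbinom(529, 1, 0.3)
  ))
  prev <- prevalence_summary(m)
  filt <- exclude_degenerate(m, 2)
  W <- matrix(0, 3, 3, dimnames = list(colnames(filt$matrix),
                                       colnames(filt$matrix)))
  W[1, 2] <- W[2, 1] <- 0.23
  net <- make_network(W, names = colnames(filt$matrix))
  tbl <- node_metric_table(net, prev, restarts = 10, seed = 1)

  expect_identical(tbl$variable, prev$variable)
  expect_true(is.na(tbl$degree[1]))         # excluded row
  fmt <- format_node_metric_table(tbl)
  expect_identical(ncol(fmt), 7L)
  expect_identical(fmt$no_pct[1], "528 (99.8)")
  expect_identical(unique(unlist(fmt[1, 3:7])), "-")
  expect_true(all(fmt$core_periphery[-1] %in% c("Core", "Periphery")))

  # empty network: all zero degrees, everyone periphery
  net0 <- make_network(matrix(0, 3, 3), names = colnames(filt$matrix))
  tbl0 <- node_metric_table(net0, prev, restarts = 5, seed = 1)
  expect_equal(tbl0$degree[-1], rep(0L, 3))
  expect_false(any(tbl0$is_core[-1]))

  # mismatched variable universe is an error
  bad_prev <- prev[prev$variable != "a", ]
  expect_error(node_metric_table(net, bad_prev), "missing")
})
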