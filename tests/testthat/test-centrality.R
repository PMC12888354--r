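test_that("degree centrality is k/(n-1)", {
  st <- star_graph(3)
  dc <- degree_centrality(st)
  expect_equal(unname(dc["hub"]), 1.0)
  expect_equal(unname(dc[c("leaf1", "leaf2", "leaf3")]), rep(1 / 3, 3))
  expect_equal(unname(degree_centrality(complete_graph(4))), rep(1, 4))
  iso <- graph_from_adj(matrix(FALSE, 3, 3))
  expect_equal(unname(degree_centrality(iso)), rep(0, 3))
})

test_that("closeness uses Wasserman-Faust scaling; isolated nodes undefined", {
  pg <- path_graph(3)
  cc <- closeness_centrality(pg)
  expect_equal(unname(cc["B"]), 1.0)
  expect_equal(unname(cc["A"]), 2 / 3)
  st <- star_graph(3)
  ccs <- closeness_centrality(st)
  expect_equal(unname(ccs["hub"]), 1.0)
  expect_equal(unname(ccs["leaf1"]), 0.6)
  # triangle + isolated node: isolated is NA, others scaled by (3-1)/(4-1)
  adj <- matrix(FALSE, 4, 4)
  adj[1:3, 1:3] <- TRUE
  g <- graph_from_adj(adj, c("A", "B", "C", "iso"))
  cci <- closeness_centrality(g)
  expect_true(is.na(cci["iso"]))
  expect_equal(unname(cci["A"]), (2 / 3) * (2 / 2))
})

test_that("betweenness excludes endpoints and normalizes by (n-1)(n-2)/2", {
  st <- star_graph(3)
  bc <- betweenness_centrality(st)
  expect_equal(unname(bc["hub"]), 1.0)
  expect_equal(unname(bc[-1]), rep(0, 3))
  expect_equal(unname(betweenness_centrality(complete_graph(4))), rep(0, 4))
  pg <- path_graph(3)
  expect_equal(unname(betweenness_centrality(pg)["B"]), 1.0)
})

test_that("eigenvector centrality matches closed forms and the fixed point", {
  k4 <- complete_graph(4)
  expect_equal(unname(eigenvector_centrality(k4)), rep(0.5, 4),
               tolerance = 1e-8)
  st <- star_graph(3)
  ec <- eigenvector_centrality(st)
  expect_equal(unname(ec["hub"]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(ec["leaf1"]), sqrt(1 / 6), tolerance = 1e-8)
  expect_equal(sum(ec^2), 1, tolerance = 1e-10)
  # A e = lambda e within 1e-8 on random graphs
  set.seed(11)
  for (rep in 1:10) {
    adj <- matrix(runif(49) < 0.4, 7, 7)
    adj <- adj | t(adj); diag(adj) <- FALSE
    if (!any(adj)) next
    g <- graph_from_adj(adj)
    e <- eigenvector_centrality(g)
    ae <- as.vector((adj * 1) %*% e)
    lambda <- sum(e * ae)
    expect_lt(max(abs(ae - lambda * e)), 1e-8)
  }
  # edgeless graph: zeros with warning
  expect_warning(z <- eigenvector_centrality(graph_from_adj(matrix(FALSE, 3, 3))),
                 "no edges")
  expect_equal(unname(z), rep(0, 3))
  # disconnected: the dominant component carries the mass
  adj <- matrix(FALSE, 5, 5)
  adj[1:3, 1:3] <- TRUE            # triangle
  adj[4, 5] <- adj[5, 4] <- TRUE   # lone dyad
  g2 <- graph_from_adj(adj, LETTERS[1:5])
  e2 <- eigenvector_centrality(g2)
  expect_gt(min(e2[1:3]), 0.5)
  expect_lt(max(e2[4:5]), 1e-6)
})

test_that("centralities agree with independent oracles on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    adj <- matrix(runif(n * n) < 0.5, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- graph_from_adj(adj)
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-12)
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-12)
    if (any(adj))
      expect_equal(eigenvector_centrality(g), oracle_eigenvector(g),
                   tolerance = 1e-6)
  }
})

test_that("node relabeling permutes every centrality vector identically", {
  set.seed(5)
  adj <- matrix(runif(36) < 0.45, 6, 6)
  adj <- adj | t(adj); diag(adj) <- FALSE
  g <- graph_from_adj(adj, LETTERS[1:6])
  perm <- sample(6)
  gp <- graph_from_adj(adj[perm, perm], LETTERS[1:6][perm])
  for (fn in list(degree_centrality, closeness_centrality,
                  betweenness_centrality, eigenvector_centrality)) {
    a <- fn(g); b <- fn(gp)
    expect_equal(a[sort(names(a))], b[sort(names(b))], tolerance = 1e-9)
  }
})

test_that("hypergraph centralities run on the two-section or bipartite view", {
  m <- as_fixture_matrix(c(0.5, 0.5, 0.5), c("A", "B", "C"))
  h <- build_hypergraph(m, 0.3)  # single hyperedge {A,B,C}
  expect_equal(unname(hypergraph_centrality(h, "degree")), rep(1, 3))
  # maximal-clique hypergraph degree == graph degree (two-section identity)
  for (seed in 1:5) {
    mm <- random_symmetric_matrix(7, seed + 50)
    g <- build_graph(mm, 0.5)
    hh <- build_hypergraph(g)
    expect_equal(hypergraph_centrality(hh, "degree"), degree_centrality(g))
  }
  # empty hypergraph: all degree zero
  h0 <- build_hypergraph(as_fixture_matrix(c(0, 0, 0), c("A", "B", "C")), 0.5)
  expect_equal(unname(hypergraph_centrality(h0, "degree")), rep(0, 3))
  # bipartite variant returns the node subset only
  bp <- hypergraph_centrality(h, "degree", representation = "bipartite")
  expect_identical(names(bp), c("A", "B", "C"))
  expect_true(all(bp > 0))
})

test_that("strength classification uses the stated bands, gaps to moderate", {
  expect_identical(classify_strength(c(0, 0.3, 0.35, 0.4, 0.5, 0.6, 0.65,
                                       0.7, 1)),
                   c("weak", "weak", "moderate", "moderate", "moderate",
                     "moderate", "moderate", "strong", "strong"))
  expect_identical(classify_strength(NA_real_), NA_character_)
  expect_error(classify_strength(1.2), "\\[0, 1\\]")
})

test_that("centrality reports mirror the published table layout", {
  st <- star_graph(3)
  rep_g <- centrality_report(st)
  expect_identical(names(rep_g),
                   c("node", "degree", "degree_strength", "closeness",
                     "closeness_strength", "betweenness",
                     "betweenness_strength", "eigenvector",
                     "eigenvector_strength"))
  expect_identical(rep_g$degree_strength[rep_g$node == "hub"], "strong")
  # edgeless graph report completes with zero eigenvector, no warning
  g0 <- graph_from_adj(matrix(FALSE, 3, 3))
  expect_silent(rep0 <- centrality_report(g0))
  expect_equal(rep0$eigenvector, rep(0, 3))
  expect_true(all(is.na(rep0$closeness)))
})
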