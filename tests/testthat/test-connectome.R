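# Spatial cell graphs and information-transfer robustness.

test_that("the linking rule follows the radius and mutual-kNN pruning", {
  expect_equal(nrow(build_cell_graph(data.frame(cx_um = numeric(0),
                                                cy_um = numeric(0)))$edges), 0)
  two <- function(d) build_cell_graph(
    data.frame(cx_um = c(0, d), cy_um = 0), link_radius_um = 60)
  expect_equal(nrow(two(50)$edges), 1)
  expect_equal(nrow(two(70)$edges), 0)
  # 10x10 grid at 50 um spacing, radius 60: interior degree 4
  grid <- expand.grid(cx_um = seq(0, 450, 50), cy_um = seq(0, 450, 50))
  g <- build_cell_graph(grid, link_radius_um = 60)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = 100)
  interior <- grid$cx_um > 0 & grid$cx_um < 450 & grid$cy_um > 0 & grid$cy_um < 450
  expect_true(all(deg[interior] == 4))
  # max_degree pruning caps a dense hub
  star <- data.frame(cx_um = c(0, 10 * cos(1:20)), cy_um = c(0, 10 * sin(1:20)))
  gs <- build_cell_graph(star, link_radius_um = 60, max_degree = 5)
  degs <- tabulate(c(gs$edges$from, gs$edges$to), nbins = 21)
  expect_true(all(degs <= 5))
})

test_that("global efficiency matches closed forms on canonical graphs", {
  complete <- build_cell_graph(data.frame(cx_um = c(0, 1, 2, 1),
                                          cy_um = c(0, 1, 0, -1)),
                               link_radius_um = 10)
  expect_equal(information_transfer(complete), 1.0)
  edgeless <- build_cell_graph(data.frame(cx_um = c(0, 100, 200),
                                          cy_um = 0), link_radius_um = 10)
  expect_equal(information_transfer(edgeless), 0.0)
  path3 <- build_cell_graph(data.frame(cx_um = c(0, 50, 100), cy_um = 0),
                            link_radius_um = 60)
  expect_equal(information_transfer(path3), (1 + 1 + 0.5) / 3)
  expect_equal(information_transfer(build_cell_graph(
    data.frame(cx_um = 0, cy_um = 0))), 0)
})

test_that("efficiency agrees with Floyd-Warshall brute force on random graphs", {
  set.seed(404)
  for (k in seq_len(200)) {
    n <- sample(2:8, 1)
    pts <- data.frame(cx_um = runif(n, 0, 100), cy_um = runif(n, 0, 100))
    g <- build_cell_graph(pts, link_radius_um = runif(1, 20, 80))
    adj <- matrix(0, n, n)
    if (nrow(g$edges) > 0) {
      adj[cbind(g$edges$from, g$edges$to)] <- 1
      adj[cbind(g$edges$to, g$edges$from)] <- 1
    }
    expect_equal(information_transfer(g), efficiency_oracle(adj),
                 tolerance = 1e-12)
  }
})

test_that("transfer curves start at 1, end at 0, and never increase", {
  set.seed(77)
  g <- random_cellgraph(20, side_um = 120, radius = 60)
  for (strategy in c("random", "pyknotic_first", "degree_targeted")) {
    cv <- node_removal_curve(g, strategy, steps = 10, n_replicates = 25,
                             seed = 9)
    expect_equal(cv$mean_transfer[1], 1)
    expect_equal(cv$mean_transfer[nrow(cv)], 0)
    expect_true(all(cv$mean_transfer >= 0 & cv$mean_transfer <= 1))
    expect_true(all(diff(cv$mean_transfer) <= 1e-12),
                info = strategy)
  }
})

test_that("every replicate curve is non-increasing under original-pair normalization", {
  # per-replicate monotonicity, not just the mean: one replicate at a time
  set.seed(31)
  for (k in 1:5) {
    g <- random_cellgraph(12, side_um = 100)
    for (s in c("random", "degree_targeted")) {
      cv <- node_removal_curve(g, s, steps = 12, n_replicates = 1, seed = k)
      expect_true(all(diff(cv$mean_transfer) <= 1e-12))
    }
  }
})

test_that("curves are deterministic for fixed seed and differ across seeds", {
  set.seed(55)
  g <- random_cellgraph(15)
  a <- node_removal_curve(g, "random", steps = 8, n_replicates = 10, seed = 3)
  b <- node_removal_curve(g, "random", steps = 8, n_replicates = 10, seed = 3)
  expect_identical(a, b)
})

test_that("degree-targeted removal of a star hub kills transfer in one step", {
  hub <- data.frame(cx_um = c(0, 50 * cos(1:6), 0) [1:7],
                    cy_um = c(0, 50 * sin(1:6), 0)[1:7])
  g <- build_cell_graph(hub[1:7, ], link_radius_um = 55)
  # force a pure star: keep only hub edges
  g$edges <- g$edges[g$edges$from == 1 | g$edges$to == 1, ]
  cv <- node_removal_curve(g, "degree_targeted", steps = 7, n_replicates = 1,
                           seed = 1)
  expect_equal(cv$mean_transfer[2], 0)  # hub removed at the first step
})

test_that("pyknotic-first on an all-viable graph reduces to random order", {
  pts <- data.frame(cx_um = runif(10, 0, 80), cy_um = runif(10, 0, 80),
                    status = "viable")
  g <- build_cell_graph(pts)
  a <- node_removal_curve(g, "pyknotic_first", steps = 5, n_replicates = 8,
                          seed = 2)
  b <- node_removal_curve(g, "random", steps = 5, n_replicates = 8, seed = 2)
  expect_equal(a$mean_transfer, b$mean_transfer)
})

test_that("targeted attack is at most as robust as random failure (AUC)", {
  set.seed(88)
  wins <- 0L
  for (k in seq_len(20)) {
    g <- random_cellgraph(18, side_um = 100, radius = 60)
    rep <- compare_strategies(g, seed = k, steps = 8, n_replicates = 10,
                              strategies = c("random", "degree_targeted"))
    auc <- setNames(rep$auc, rep$strategy)
    if (auc["degree_targeted"] <= auc["random"] + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("graph round-trips through CSV/GraphML export", {
  set.seed(66)
  g <- random_cellgraph(8)
  d <- tempfile()
  write_cell_graph(g, d)
  nodes <- read.csv(file.path(d, "nodes.csv"))
  edges <- read.csv(file.path(d, "edges.csv"))
  expect_equal(nrow(nodes), 8)
  expect_equal(nrow(edges), nrow(g$edges))
  ig <- igraph::read_graph(file.path(d, "graph.graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), 8)
  expect_equal(igraph::gsize(ig), nrow(g$edges))
})
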