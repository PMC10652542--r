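test_that("creation-mode forests have the right component arithmetic", {
  g1 <- build_graph_creation("only", 1, seed = 1)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)

  g5 <- build_graph_creation(paste0("t", 1:5), 1, seed = 2)
  expect_equal(igraph::ecount(g5), 4)
  expect_equal(igraph::components(g5)$no, 1)
  expect_true(igraph::is_forest(g5, mode = "all"))

  g6 <- build_graph_creation(paste0("t", 1:6), 2, seed = 3)
  expect_equal(igraph::components(g6)$no, 2)
  expect_equal(igraph::ecount(g6), 4)

  expect_error(build_graph_creation(paste0("t", 1:3), 4), "n_trees")
})

test_that("emulation-mode MST keeps short edges for collinear type means", {
  # means on a line at distances 1 and 10: the optimal tree uses both short
  # edges (weight 11), never the 11-length chord
  means <- rbind(a = c(0, 0), b = c(1, 0), c = c(11, 0))
  g <- build_graph_emulation(means, seed = 1)
  el <- igraph::as_edgelist(g)
  within_weight <- sum(apply(el, 1, function(e)
    sqrt(sum((means[e[1], ] - means[e[2], ])^2))))
  comm_sizes <- igraph::components(g)$csize
  if (length(comm_sizes) == 1) {
    expect_equal(within_weight, 11)
  } else {
    # if modularity split the nodes, each community tree is still minimal
    expect_lte(within_weight, 11)
  }
  g2 <- build_graph_emulation(means[1:2, ], seed = 1)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("within-community MST weight matches exhaustive enumeration", {
  for (seed in 1:50) {
    set.seed(seed)
    P <- sample(2:6, 1)
    means <- matrix(rnorm(P * 3, 0, 2), P,
                    dimnames = list(paste0("t", 1:P), NULL))
    g <- build_graph_emulation(means, seed = seed)
    comp <- igraph::components(g)
    el <- igraph::as_edgelist(g)
    for (cm in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == cm]
      if (length(members) < 2) next
      W <- as.matrix(dist(means[members, , drop = FALSE]))
      got <- sum(apply(el[el[, 1] %in% members & el[, 2] %in% members, ,
                          drop = FALSE], 1,
                       function(e) sqrt(sum((means[e[1], ] - means[e[2], ])^2))))
      expect_equal(got, oracle_mst_weight(W), tolerance = 1e-9)
    }
  }
})

test_that("DFS rooting orients forests into polyforests", {
  for (seed in 1:20) {
    P <- sample(3:7, 1)
    f <- build_graph_creation(paste0("t", 1:P), sample(1:2, 1), seed = seed)
    edges <- root_forest(f, seed = seed)
    expect_equal(nrow(edges), igraph::ecount(f))
    # each child has exactly one parent
    expect_equal(anyDuplicated(edges$child), 0L)
    # roots never appear as children
    n_roots <- P - nrow(edges)
    expect_equal(n_roots, igraph::components(f)$no)
  }
})

test_that("edge paths are pinned at both ends and have bridge variance", {
  mu_p <- c(0, 1, 2); mu_c <- c(3, 1, -1)
  for (seed in 1:10) {
    g <- sample_edge_path(mu_p, mu_c, changing_channels = c(1, 3), seed = seed)
    expect_lt(max(abs(g(0))), 1e-9)
    expect_equal(drop(g(1)), c(3, 0, -3), tolerance = 1e-9)
    expect_equal(drop(g(0.5))[2], 0)  # non-changing channel stays put
  }
  mids <- vapply(1:2000, function(s) {
    g <- sample_edge_path(0, 2, changing_channels = 1, n_knots = 9, seed = s)
    g(0.5)[1, 1] - 0.5 * 2
  }, 0)
  expect_lt(abs(var(mids) - 0.25), 0.04)
})

test_that("differentiation sampling honours leaves, Beta pseudotime, and endpoints", {
  m <- create_model(4, 10, seed = 11)
  tr <- build_trajectory(m, n_trees = 1, beta_alpha = 1, beta_beta = 1, seed = 11)
  leaves <- setdiff(tr$cell_types, tr$edges$parent)
  d <- sample_differentiation(tr, leaves[1], n = 500, seed = 1)
  expect_equal(d$child, rep(leaves[1], 500))
  expect_equal(max(abs(d$shift)), 0)
  expect_true(all(d$pseudotime >= 0 & d$pseudotime <= 1))

  # alpha = beta = 1: pseudotime is uniform
  root <- setdiff(tr$edges$parent, tr$edges$child)[1]
  d2 <- sample_differentiation(tr, root, n = 10000, seed = 2)
  expect_gt(suppressWarnings(
    ks.test(d2$pseudotime, "punif")$p.value), 0.01)

  # forced child at pseudotime ~ 1 lands on the child mean shift
  tr3 <- build_trajectory(m, n_trees = 1, stay_prob = 0,
                          beta_alpha = 1e6, beta_beta = 1,
                          change_frac = 0, seed = 11)
  p1 <- tr3$edges$parent[1]
  kids <- tr3$edges$child[tr3$edges$parent == p1]
  d3 <- sample_differentiation(tr3, p1, n = 2000, seed = 3)
  means <- t(vapply(m$gmms, function(g) drop(crossprod(g$weights, g$means)),
                    numeric(10)))
  rownames(means) <- m$cell_types
  for (kid in kids) {
    delta <- means[kid, ] - means[p1, ]
    got <- colMeans(d3$shift[d3$child == kid, , drop = FALSE])
    expect_lt(max(abs(got - delta)), 0.05)
  }
})

test_that("trajectory-enabled simulation interpolates between type means", {
  m <- create_model(3, 8, covariance_scale = 0.1, seed = 21)
  tr <- build_trajectory(m, stay_prob = 0, beta_alpha = 8, beta_beta = 0.4,
                         change_frac = 0, seed = 21)
  p <- tr$edges$parent[1]; k <- tr$edges$child[1]
  sim <- simulate_cells(m, 20000, trajectory = tr, seed = 22)
  sub <- sim[sim$cell_type == p & sim$child_type == k & sim$pseudotime > 0.97, ]
  expect_gt(nrow(sub), 50)
  means <- t(vapply(m$gmms, function(g) drop(crossprod(g$weights, g$means)),
                    numeric(8)))
  rownames(means) <- m$cell_types
  got <- colMeans(as.matrix(sub[, 1:8]))
  want <- pmax(means[k, ], 0)
  # slack covers residual (1 - t) * delta drift plus truncation bias near 0
  expect_lt(max(abs(got - want)), 4 * 0.35 / sqrt(nrow(sub)) + 0.08)
})
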