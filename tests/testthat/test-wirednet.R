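test_that("ring lattice construction gives the expected degrees and edges", {
  net <- build_regular(6, 1)
  expect_equal(sum(net$A), 12)
  expect_true(all(colSums(net$A) == 2))
  expect_true(all(rowSums(net$A) == 2))
  expect_true(all(diag(net$A) == 0))

  net200 <- build_regular(200, 2)
  expect_equal(sum(net200$A), 800)
  # closed form for the k = 2m ring: C = 3(m-1) / (2(2m-1))
  cl <- clustering_coefficient(net200$W)
  expect_equal(unname(cl$per_node), rep(0.5, 200), tolerance = 1e-12)

  expect_error(build_regular(4, 2), class = "serpens_invalid_parameter")
})

test_that("small-world rewiring preserves the edge count for all p", {
  for (p in c(0, 0.05, 0.5, 1)) {
    net <- build_ws(60, 2, p, seed = round(100 * p) + 1)
    expect_equal(sum(net$A), 240)
    expect_true(all(diag(net$A) == 0))
    expect_true(isTRUE(all.equal(net$A, t(net$A)))) # stored bidirectionally
  }
  expect_identical(build_ws(30, 2, 0, seed = 1)$W, build_regular(30, 2)$W)
})

test_that("small-world regime sits between regular and random", {
  cl_reg <- clustering_coefficient(build_regular(200, 2)$W)$avg
  cls <- sapply(1:25, function(s) {
    clustering_coefficient(build_ws(200, 2, 0.05, seed = s)$W)$avg
  })
  cl_rand <- sapply(1:25, function(s) {
    clustering_coefficient(build_ws(200, 2, 1, seed = 1000 + s)$W)$avg
  })
  expect_lt(mean(cls), cl_reg)
  expect_gt(mean(cls), mean(cl_rand))
  sp_ws <- mean(sapply(1:10, function(s) {
    shortest_path_length(build_ws(200, 2, 0.05, seed = s)$W)$avg
  }))
  sp_rand <- mean(sapply(1:10, function(s) {
    shortest_path_length(build_ws(200, 2, 1, seed = 1000 + s)$W)$avg
  }))
  # at m = 2 the small-world path settles near 2.03x the random-graph path
  expect_lt(sp_ws, 2.5 * sp_rand)
})

test_that("preferential attachment has the declared edge count and heavy tail", {
  net <- build_ba(200, 2, 1, seed = 3)
  expect_equal(sum(net$A), 2 * 198) # (n - m0) * m undirected edges, doubled
  tiny <- build_ba(3, 2, 1, seed = 4)
  expect_equal(sum(tiny$A), 2)
  expect_error(build_ba(100, 2, 2), class = "serpens_invalid_parameter")

  degs <- sapply(1:25, function(s) {
    d <- rowSums(build_ba(500, 2, 1, seed = s)$A)
    c(max = max(d), med = median(d))
  })
  expect_gt(mean(degs["max", ] > 5 * degs["med", ]), 0.9)
})

test_that("BA hubs exceed regular-network degrees under uniform weights", {
  reg_max <- node_degrees(build_regular(200, 2)$W)$max
  hits <- sapply(1:40, function(s) {
    node_degrees(build_ba(200, 2, 1, seed = s)$W)$max > reg_max
  })
  expect_gte(mean(hits), 0.95)
})

test_that("weight schemes satisfy their normalization contracts", {
  net <- build_ws(100, 2, 0.1, seed = 9)
  uni <- assign_weights(net, "uniform")
  expect_identical(uni$W, net$A * 1)

  rnd <- assign_weights(net, "random", seed = 10)
  s <- colSums(abs(rnd$W))
  has_in <- colSums(net$A) > 0
  expect_true(all(abs(s[has_in] - 1) < 1e-9))
  expect_true(all(rnd$W >= -1 & rnd$W <= 1))
  # support unchanged
  expect_identical((rnd$W != 0) * 1L, unclass(net$A))
  # re-normalizing is idempotent
  renorm <- sweep(abs(rnd$W), 2, pmax(colSums(abs(rnd$W)), 1e-300), `/`)
  expect_equal(abs(rnd$W)[, has_in], renorm[, has_in], tolerance = 1e-12)
  # every connected node has |w| in-degree exactly 1 under random weights
  expect_equal(unname(node_degrees(rnd$W)$per_node[has_in]),
               rep(1, sum(has_in)), tolerance = 1e-9)
})

test_that("hand-normalization examples hold", {
  # raw (1, -3) on one target -> (0.25, -0.75)
  raw <- c(1, -3)
  expect_equal(raw / sum(abs(raw)), c(0.25, -0.75))
})

test_that("role assignment flags the requested number of interface nodes", {
  net <- build_wired_network("ws", "random", n = 200, seed = 5)
  expect_equal(sum(net$roles == "interface"), 26)
  expect_equal(sum(net$roles == "hidden"), 174)
  spread <- assign_roles(net, 10, strategy = "spread")
  expect_equal(sum(spread$roles == "interface"), 10)
  hubs <- assign_roles(net, 5, strategy = "hubs")
  deg <- colSums(abs(net$W))
  expect_true(min(deg[hubs$roles == "interface"]) >=
    max(deg[hubs$roles == "hidden"]))
})

test_that("clustering coefficient matches the brute-force triad oracle", {
  W3 <- matrix(1, 3, 3)
  diag(W3) <- 0
  expect_equal(clustering_coefficient(W3)$per_node, rep(1, 3))
  expect_equal(clustering_coefficient(matrix(0, 4, 4))$avg, 0)

  set.seed(42)
  for (g in all_digraphs(3)) {
    expect_equal(clustering_coefficient(g)$per_node, oracle_clustering(g),
      tolerance = 1e-9
    )
  }
  for (n in 4:6) {
    for (r in 1:40) {
      W <- random_weighted_digraph(n)
      expect_equal(clustering_coefficient(W)$per_node, oracle_clustering(W),
        tolerance = 1e-9
      )
    }
  }
  for (r in 1:30) {
    W <- random_weighted_digraph(12)
    expect_equal(clustering_coefficient(W)$per_node, oracle_clustering(W),
      tolerance = 1e-9
    )
  }
})

test_that("shortest paths use inverse weights and match Floyd-Warshall", {
  W <- matrix(0, 2, 2)
  W[1, 2] <- 0.5
  sp <- shortest_path_length(W)
  expect_equal(sp$avg, 2)
  expect_equal(sp$n_unreachable, 1)

  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- 1
  W3[2, 3] <- 1
  # d(1 -> 3) = 2 via the two unit-length hops
  expect_equal(shortest_path_length(W3)$avg, (1 + 1 + 2) / 3)

  set.seed(7)
  for (r in 1:30) {
    W <- random_weighted_digraph(12)
    expect_equal(shortest_path_length(W)$avg, oracle_avg_shortest_path(W),
      tolerance = 1e-9
    )
  }
  expect_error(shortest_path_length(matrix(0, 3, 3)),
    class = "serpens_disconnected"
  )
})

test_that("all measures are invariant under node permutation", {
  set.seed(11)
  W <- random_weighted_digraph(10)
  perm <- sample(10)
  Wp <- W[perm, perm]
  expect_equal(sort(clustering_coefficient(W)$per_node),
    sort(clustering_coefficient(Wp)$per_node),
    tolerance = 1e-12
  )
  expect_equal(shortest_path_length(W)$avg, shortest_path_length(Wp)$avg,
    tolerance = 1e-12
  )
  expect_equal(sort(node_degrees(W)$per_node), sort(node_degrees(Wp)$per_node),
    tolerance = 1e-12
  )
})

test_that("networks round-trip through the edge-list files", {
  net <- build_wired_network("ba", "random", n = 40, n_interface = 8, seed = 3)
  path <- file.path(withr::local_tempdir(), "net")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$W, net$W, tolerance = 1e-15)
  expect_identical(back$roles, net$roles)
  expect_identical(back$topology, net$topology)
})
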