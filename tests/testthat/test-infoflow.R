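test_that("KSG mutual information matches Gaussian closed forms", {
  withr::with_seed(1, {
    x <- rnorm(5000)
    y <- rnorm(5000)
    rho <- 0.8
    y2 <- rho * x + sqrt(1 - rho^2) * rnorm(5000)
  })
  expect_lt(abs(ksg_mutual_information(x, y)), 0.03)
  expect_lt(abs(ksg_mutual_information(x, y2) - (-0.5 * log(1 - rho^2))), 0.05)

  expect_warning(mi0 <- ksg_mutual_information(rep(1, 200), rnorm(200)), "constant")
  expect_equal(mi0, 0)
  expect_warning(mi_dup <- ksg_mutual_information(x[1:500], x[1:500]), "degenerate")
  expect_true(is.finite(mi_dup))
  expect_error(ksg_mutual_information(1:10, 1:10), class = "serpens_invalid_parameter")
})

test_that("KSG transfer entropy matches the AR closed form and is directional", {
  fx <- gaussian_var_pair(0.5, 0.5, 8000, seed = 2)
  expect_lt(abs(ksg_transfer_entropy(fx$y, fx$x) - fx$te_yx), 0.05)
  expect_lt(abs(ksg_transfer_entropy(fx$x, fx$y)), 0.02)

  indep <- gaussian_var_pair(0.5, 0, 8000, seed = 3)
  expect_lt(abs(ksg_transfer_entropy(indep$y, indep$x)), 0.02)

  expect_warning(te0 <- ksg_transfer_entropy(rnorm(600), rep(2, 600)), "constant")
  expect_equal(te0, 0)
  expect_error(ksg_transfer_entropy(rnorm(100), rnorm(100)),
    class = "serpens_invalid_parameter"
  )
  expect_error(ksg_transfer_entropy(rnorm(600), rnorm(600), l = 2),
    class = "serpens_invalid_parameter"
  )
})

test_that("KSG estimators track the closed form across seeds (mean error)", {
  errs <- sapply(1:8, function(s) {
    f <- gaussian_var_pair(0.5, 0.5, 5000, seed = s)
    abs(ksg_transfer_entropy(f$y, f$x) - f$te_yx)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("shuffled sources carry no transfer entropy", {
  fx <- gaussian_var_pair(0.5, 0.6, 4000, seed = 4)
  te_coupled <- ksg_transfer_entropy(fx$y, fx$x)
  shuf <- sapply(1:20, function(s) {
    ks <- withr::with_seed(100 + s, sample(fx$y))
    ksg_transfer_entropy(ks, fx$x)
  })
  expect_gte(mean(shuf < te_coupled), 0.95)
})

test_that("a planted driver has the top outgoing TE edges", {
  panel <- driven_panel(n_nodes = 8, targets = 2:4, coupling = 0.8,
                        n = 2000, seed = 5)
  res <- serpens:::pairwise_te_mi_cpp(panel$X, 4L, FALSE)
  te <- res$te
  out_edges <- te[1, -1]
  top3 <- order(te[1, ], decreasing = TRUE)[1:3]
  expect_setequal(top3, panel$targets)
  # i.i.d.-ish nodes have near-zero TE among themselves
  expect_lt(max(te[5:8, 5:8]), 0.05)
})

test_that("information networks are deterministic and carry role structure", {
  fx <- switching_traj(2, 80, n_joints = 6, seed = 6)
  # stand-in neural panel: reuse the fixture joints as x series
  traj <- tibble::tibble(time = seq(0, by = 0.1, length.out = nrow(fx$theta)))
  for (j in 1:6) traj[[paste0("x", j)]] <- fx$theta[, j]
  attr(traj, "roles") <- c("interface", "interface", rep("hidden", 4))
  attr(traj, "sample_dt") <- 0.1
  labeling <- list(episodes = tibble::tibble(
    label = 1L, start = 1L, end = 800L, start_time = 0, duration = 80
  ))
  a <- estimate_info_network(traj, labeling, 1L, min_samples = 300,
                             max_samples = 600)
  b <- estimate_info_network(traj, labeling, 1L, min_samples = 300,
                             max_samples = 600)
  expect_identical(a$te_matrix, b$te_matrix)
  expect_equal(diag(a$te_matrix), rep(0, 6), ignore_attr = TRUE)
  expect_true(isTRUE(all.equal(a$mi_matrix, t(a$mi_matrix))))
  expect_error(
    estimate_info_network(traj, labeling, 1L, min_samples = 1e5),
    class = "serpens_short_segment"
  )
})

test_that("Otsu binarization splits two-valued matrices exactly", {
  M <- matrix(0.1, 6, 6)
  M[1:3, 4:6] <- 0.9
  diag(M) <- 0
  B <- binarize_otsu_matrix(M)
  expect_equal(B[1:3, 4:6], matrix(1L, 3, 3), ignore_attr = TRUE)
  expect_equal(B[4:6, 1:3], matrix(0L, 3, 3), ignore_attr = TRUE)
  expect_true(all(diag(B) == 0))
  expect_error(binarize_otsu_matrix(matrix(0.5, 4, 4)),
    class = "serpens_degenerate"
  )
})

test_that("binarization recovers planted block structure from noisy values", {
  fx <- planted_blockmodel(30, 3, 0.9, 0.05, seed = 7)
  withr::with_seed(8, {
    M <- fx$B * (3 + rnorm(900, sd = 0.3)) + (1 - fx$B) * abs(rnorm(900, sd = 0.3))
  })
  diag(M) <- 0
  B <- binarize_otsu_matrix(M)
  off <- row(B) != col(B)
  expect_gte(mean(B[off] == fx$B[off]), 0.95)
})

test_that("info-network measures reuse the weighted measures correctly", {
  TE <- matrix(0, 4, 4)
  TE[1, 2] <- 0.4
  TE[2, 3] <- 0.2
  TE[3, 1] <- 0.1
  TE[2, 1] <- 0.3
  m <- info_network_measures(TE)
  expect_equal(m$clustering_per_node, oracle_clustering(TE), tolerance = 1e-9)
  expect_equal(m$avg_shortest_path, oracle_avg_shortest_path(TE), tolerance = 1e-9)
  # doubling TE halves path lengths, leaves the rescaled clustering alone
  m2 <- info_network_measures(TE * 2)
  expect_equal(m2$avg_shortest_path, m$avg_shortest_path / 2, tolerance = 1e-12)
  expect_equal(m2$avg_clustering, m$avg_clustering, tolerance = 1e-12)
  # all-zero TE: no clustering, path undefined but signalled
  m0 <- network_measures(matrix(0, 4, 4))
  expect_equal(m0$avg_clustering, 0)
  expect_true(is.na(m0$avg_shortest_path))
})

test_that("body influence averages role-crossing TE pairs", {
  te <- matrix(0.2, 5, 5)
  diag(te) <- 0
  inet <- structure(
    list(
      te_matrix = te, roles = c("interface", "interface", rep("hidden", 3)),
      pattern_label = 1L, duration = 100
    ),
    class = "info_network"
  )
  infl <- body_influence(inet)
  expect_equal(infl$te_hidden_to_interface, 0.2)
  expect_equal(infl$te_interface_to_hidden, 0.2)

  te2 <- te
  te2[3:5, 1:2] <- 0.6 # elevate hidden -> interface block
  inet$te_matrix <- te2
  infl2 <- body_influence(inet)
  expect_gt(infl2$te_hidden_to_interface, infl2$te_interface_to_hidden)

  inet$te_matrix <- te * 0
  infl0 <- body_influence(inet)
  expect_equal(infl0$te_hidden_to_interface, 0)
})
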