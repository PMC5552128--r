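sine_matrix <- function(n_joints, n = 600, phase = rep(0, n_joints),
                        amp = rep(1, n_joints), noise = 0, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(0, by = 0.1, length.out = n)
    th <- sapply(seq_len(n_joints), function(j) {
      amp[j] * sin(2 * pi * 0.5 * t + phase[j])
    })
    th + matrix(rnorm(length(th), sd = noise), n)
  })
}

test_that("feature dimension is k(k-1)/2 and correlations hit their limits", {
  for (k in c(2, 5, 14)) {
    f <- windowed_correlation_features(sine_matrix(k, noise = 0.01),
      window = 10, shift = 0.5, sample_dt = 0.1
    )
    expect_equal(ncol(f$R), k * (k - 1) / 2)
    expect_true(all(f$R >= -1 & f$R <= 1))
  }
  # identical sinusoids: every pairwise correlation 1 in every window
  f1 <- windowed_correlation_features(sine_matrix(4),
    window = 10, shift = 1, sample_dt = 0.1
  )
  expect_true(all(abs(f1$R - 1) < 1e-9))
  # anti-phase pair: r = -1
  f2 <- windowed_correlation_features(
    sine_matrix(2, phase = c(0, pi)),
    window = 10, shift = 1, sample_dt = 0.1
  )
  expect_true(all(abs(f2$R + 1) < 1e-6))
})

test_that("zero-variance joints yield correlation 0 and are flagged", {
  th <- sine_matrix(3)
  th[, 2] <- 0.7
  expect_equal(
    windowed_correlation_features(th, 10, 1, sample_dt = 0.1)$n_degenerate > 0,
    TRUE
  )
  f <- windowed_correlation_features(th, 10, 1, sample_dt = 0.1)
  expect_true(all(f$R[, 1] == 0)) # pair (1,2)
})

test_that("feature columns permute with joint order but labels do not change", {
  fx <- switching_traj(3, 60, n_joints = 6, seed = 4)
  perm <- c(3, 1, 6, 4, 2, 5)
  f_orig <- windowed_correlation_features(fx$theta, 10, 0.5, sample_dt = 0.1)
  f_perm <- windowed_correlation_features(fx$theta[, perm], 10, 0.5,
    sample_dt = 0.1
  )
  expect_equal(sort(f_orig$R[10, ]), sort(f_perm$R[10, ]), tolerance = 1e-12)
  emb_o <- embed_laplacian_eigenmaps(f_orig, k_nn = 60)
  emb_p <- embed_laplacian_eigenmaps(f_perm, k_nn = 60)
  lab_o <- cluster_dbscan(emb_o, 0.16, 10)
  lab_p <- cluster_dbscan(emb_p, 0.16, 10)
  expect_gt(adjusted_rand(lab_o, lab_p), 0.99)
})

test_that("embedding separates well-separated blobs and respects its contract", {
  withr::with_seed(5, {
    centers <- matrix(rnorm(3 * 20, sd = 6), 3, 20)
    pts <- centers[rep(1:3, each = 60), ] + matrix(rnorm(180 * 20, sd = 0.1), 180)
  })
  emb <- embed_laplacian_eigenmaps(pts, k_nn = 20, out_dim = 3)
  expect_equal(dim(emb), c(180, 3))
  lab_true <- rep(1:3, each = 60)
  within <- sapply(1:3, function(b) {
    m <- colMeans(emb[lab_true == b, , drop = FALSE])
    median(sqrt(rowSums(sweep(emb[lab_true == b, ], 2, m)^2)))
  })
  cents <- t(sapply(1:3, function(b) colMeans(emb[lab_true == b, , drop = FALSE])))
  expect_gt(min(dist(cents)), 5 * max(within))
})

test_that("duplicate feature rows embed to identical coordinates", {
  withr::with_seed(6, pts <- matrix(rnorm(80 * 5), 80, 5))
  pts2 <- rbind(pts, pts[1:5, ])
  emb <- embed_laplacian_eigenmaps(pts2, k_nn = 10)
  expect_equal(emb[81:85, ], emb[1:5, ], tolerance = 1e-6)
})

test_that("DBSCAN separates dense blobs, marks sparse bridges as noise", {
  withr::with_seed(7, {
    blob1 <- matrix(rnorm(100, sd = 0.02), 50, 2)
    blob2 <- matrix(rnorm(100, sd = 0.02), 50, 2) + 2
    bridge <- cbind(seq(0.5, 1.5, length.out = 3), seq(0.5, 1.5, length.out = 3))
  })
  lab <- cluster_dbscan(rbind(blob1, blob2, bridge), eps = 0.16, min_pts = 10)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  expect_equal(lab[101:103], rep(0L, 3))
  expect_equal(length(unique(lab[1:50])), 1)

  same <- matrix(1, 30, 2)
  expect_equal(cluster_dbscan(same, 0.16, 10), rep(1L, 30))
  few <- matrix(rnorm(8), 4, 2)
  expect_equal(cluster_dbscan(few, 0.16, 10), rep(0L, 4))
})

test_that("episodes partition the label sequence and conserve total time", {
  ep <- episodes_and_durations(c(1L, 1L, 1L, 2L, 2L, 1L), shift = 1)
  expect_equal(ep$label, c(1L, 2L, 1L))
  expect_equal(ep$duration, c(3, 2, 1))

  one <- episodes_and_durations(rep(4L, 10), shift = 0.5)
  expect_equal(nrow(one), 1)
  expect_equal(one$duration, 5)

  alt <- episodes_and_durations(rep(c(1L, 2L), 10), shift = 0.5)
  expect_true(all(alt$duration == 0.5))

  withr::with_seed(8, labs <- sample(0:3, 200, replace = TRUE))
  ep2 <- episodes_and_durations(labs, shift = 0.5)
  expect_equal(sum(ep2$duration), 100) # total episode time conserved
  expect_equal(ep2$start[1], 1)
  expect_true(all(ep2$start[-1] == head(ep2$end, -1) + 1))
})

test_that("Otsu threshold matches the exhaustive-scan oracle", {
  x <- c(1, 1, 1, 10, 10, 10)
  thr <- otsu_threshold(x)
  expect_gt(thr, 1)
  expect_lt(thr, 10)

  withr::with_seed(9, {
    bi <- c(rnorm(300, 5, 0.5), rnorm(300, 15, 0.5))
  })
  thr_b <- otsu_threshold(bi)
  # oracle splits the bimodal sample near the midpoint; histogram threshold
  # must land within one bin width of it
  bin_w <- diff(range(bi)) / 256
  expect_lt(abs(thr_b - oracle_otsu(bi)), 3 * bin_w)
  expect_gt(thr_b, 7)
  expect_lt(thr_b, 13)

  expect_gt(otsu_threshold(c(2, 8)), 2)
  expect_lt(otsu_threshold(c(2, 8)), 8)
  expect_error(otsu_threshold(rep(3, 5)), class = "serpens_degenerate")
})

test_that("patterns classify stable by their longest episode; noise never does", {
  ep <- tibble::tibble(
    label = c(1L, 1L, 0L), start = c(1L, 61L, 461L), end = c(60L, 460L, 470L),
    start_time = c(0, 30, 230), duration = c(30, 200, 5)
  )
  cls <- classify_patterns(ep, threshold = 101.5)
  expect_true(cls$patterns$stable[cls$patterns$label == 1])
  expect_equal(cls$summary$n_patterns, 1)

  noisy <- tibble::tibble(
    label = 0L, start = 1L, end = 1000L, start_time = 0, duration = 500
  )
  cls2 <- classify_patterns(noisy, threshold = 10)
  expect_false(any(cls2$patterns$stable))
  expect_equal(unlist(cls2$summary), c(n_patterns = 0, n_stable = 0, max_duration = 0))
})

test_that("the pipeline recovers planted switching patterns and switch times", {
  fx <- switching_traj(3, 120, seed = 21)
  nw <- floor((120 * 4 - 10) / 0.5) + 1
  beh <- analyze_behavior(fx$theta,
    sample_dt = fx$sample_dt,
    window = 10, shift = 0.5, k_nn = round(0.09 * nw)
  )
  expect_equal(beh$summary$n_patterns, 3)
  expect_equal(beh$summary$n_stable, 3)
  # every planted switch has a label boundary within one window length
  w <- beh$windows
  boundaries <- w$start_time[which(diff(w$label) != 0) + 1]
  for (ts in fx$switch_times) {
    expect_lt(min(abs(boundaries - ts)), 10)
  }
  # single pattern: one cluster, full-length episode
  fx1 <- switching_traj(1, 200, n_episodes = 1, seed = 22)
  # a single episode yields one duration; the Otsu step warns and defaults
  expect_warning(
    beh1 <- analyze_behavior(fx1$theta,
      sample_dt = 0.1, window = 10,
      shift = 0.5, k_nn = 35
    ),
    "degenerate"
  )
  expect_equal(beh1$summary$n_patterns, 1)
  expect_equal(nrow(beh1$episodes), 1)
})
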