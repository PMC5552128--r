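# Brute-force oracles, written independently of the package implementations.

# Weighted directed clustering coefficient by explicit triad enumeration:
# for node i, sum over all ordered pairs (j, h) of the geometric-mean-weight
# products of every directed closed triad through i, over the number of
# possible triads.
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wa <- abs(W)
  diag(Wa) <- 0
  mx <- max(Wa)
  if (mx == 0) {
    return(rep(0, n))
  }
  Wh <- (Wa / mx)^(1 / 3)
  A <- (Wa > 0) * 1
  ci <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        # all 8 directed triangle orientations through (i, j, h)
        num <- num + (Wh[i, j] + Wh[j, i]) * (Wh[i, h] + Wh[h, i]) *
          (Wh[j, h] + Wh[h, j])
      }
    }
    k_tot <- sum(A[i, ]) + sum(A[, i])
    k_bi <- sum(A[i, ] * A[, i])
    den <- 2 * (k_tot * (k_tot - 1) - 2 * k_bi)
    ci[i] <- if (den > 0) num / den else 0
  }
  ci
}

# Floyd-Warshall all-pairs shortest paths on inverse absolute weights.
oracle_avg_shortest_path <- function(W) {
  n <- nrow(W)
  Wa <- abs(W)
  diag(Wa) <- 0
  D <- matrix(Inf, n, n)
  D[Wa > 0] <- 1 / Wa[Wa > 0]
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  offdiag <- D[row(D) != col(D)]
  finite <- offdiag[is.finite(offdiag)]
  if (length(finite) == 0) {
    return(NA_real_)
  }
  mean(finite)
}

# Exhaustive-scan Otsu oracle: try every candidate cut between sorted
# distinct values, maximize between-class variance directly on the data.
oracle_otsu <- function(x) {
  vals <- sort(unique(x))
  cands <- (vals[-1] + vals[-length(vals)]) / 2
  score <- vapply(cands, function(tc) {
    lo <- x[x <= tc]
    hi <- x[x > tc]
    length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
  }, 1.0)
  cands[which.max(score)]
}

random_weighted_digraph <- function(n, p_edge = 0.4) {
  W <- matrix(runif(n^2, -1, 1) * (runif(n^2) < p_edge), n, n)
  diag(W) <- 0
  W
}

# all digraphs on `n` nodes (adjacency bit patterns), unit weights
all_digraphs <- function(n) {
  slots <- which(row(diag(n)) != col(diag(n)))
  m <- length(slots)
  lapply(0:(2^m - 1), function(code) {
    W <- matrix(0, n, n)
    W[slots] <- bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) > 0
    W
  })
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

small_test_net <- function(n = 20, seed = 1) {
  net <- build_ws(n, 2, 0.1, seed = seed)
  net <- assign_weights(net, "random", seed = seed + 1)
  assign_roles(net, n_interface = min(26, n %/% 2), seed = seed + 2)
}
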