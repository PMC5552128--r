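#' Infinite relational model block discovery
#'
#' Nonparametric Bayesian partition of the nodes of a binary relation:
#' assignments follow a Chinese-restaurant-process prior with concentration
#' `gamma`, and links between (ordered) block pairs are Bernoulli with a
#' Beta(1, `beta`) prior on each block-pair link probability, so larger
#' `beta` expects sparser/noisier within-block relations. Inference is
#' collapsed Gibbs sampling over node assignments followed by a greedy
#' maximum-a-posteriori sweep; the highest-posterior sampled partition is
#' returned, with blocks relabeled in order of first appearance.
#'
#' @param B Square binary matrix with zero diagonal (e.g. from
#'   [binarize_otsu_matrix()]).
#' @param gamma_irm CRP concentration (default 1).
#' @param beta_irm Link-noise hyper-parameter (default 7).
#' @param n_sweeps Gibbs sweeps (default 100).
#' @param seed RNG seed.
#' @return List with `partition` (integer block per node), `n_blocks`,
#'   `log_posterior`, and `trace` (best log posterior per sweep).
#' @export
irm_fit <- function(B, gamma_irm = 1, beta_irm = 7, n_sweeps = 100,
                    seed = NULL) {
  if (!is.matrix(B) || nrow(B) != ncol(B)) stop_invalid("B must be square")
  if (any(B != 0 & B != 1)) stop_invalid("B must be binary")
  B <- unclass(B) * 1L
  diag(B) <- 0L
  n <- nrow(B)

  bp <- 1 # Beta prior pseudo-counts for link / non-link
  bm <- beta_irm
  lbeta0 <- lbeta(bp, bm)

  loglik <- function(z) {
    # aggregate link counts between blocks
    zi <- factor(z, levels = sort(unique(z)))
    N1 <- rowsum(t(rowsum(B, zi)), zi) # links a -> b (t() twice)
    sizes <- as.vector(table(zi))
    Ntot <- outer(sizes, sizes)
    diag(Ntot) <- sizes * (sizes - 1L)
    sum(lbeta(N1 + bp, Ntot - N1 + bm) - lbeta0)
  }
  logprior <- function(z) {
    sizes <- as.vector(table(z))
    length(sizes) * log(gamma_irm) + sum(lgamma(sizes)) -
      sum(log(gamma_irm + seq_len(n) - 1))
  }

  with_seed(seed, {
    z <- seq_len(n) # singleton start: merging moves face no entropy barrier
    best <- list(z = z, lp = loglik(z) + logprior(z))
    trace <- numeric(n_sweeps)
    for (sweep in seq_len(n_sweeps)) {
      for (i in seq_len(n)) {
        blocks <- sort(unique(z[-i]))
        new_block <- max(z) + 1L
        cand <- c(blocks, new_block)
        sizes <- vapply(blocks, function(b) sum(z[-i] == b), 1L)
        lw <- vapply(seq_along(cand), function(ci) {
          zz <- z
          zz[i] <- cand[ci]
          prior <- if (ci <= length(blocks)) log(sizes[ci]) else log(gamma_irm)
          prior + loglik(zz)
        }, 1.0)
        lw <- lw - max(lw)
        z[i] <- cand[sample.int(length(cand), 1, prob = exp(lw))]
        z <- match(z, sort(unique(z))) # compact labels
      }
      lp <- loglik(z) + logprior(z)
      if (lp > best$lp) best <- list(z = z, lp = lp)
      trace[sweep] <- best$lp
    }
    # greedy MAP polish from the best sampled partition
    z <- best$z
    lp <- best$lp
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(n)) {
        blocks <- sort(unique(z[-i]))
        cand <- c(blocks, max(z) + 1L)
        scores <- vapply(cand, function(b) {
          zz <- z
          zz[i] <- b
          zz <- match(zz, sort(unique(zz)))
          loglik(zz) + logprior(zz)
        }, 1.0)
        bi <- which.max(scores)
        if (scores[bi] > lp + 1e-12) {
          z[i] <- cand[bi]
          z <- match(z, sort(unique(z)))
          lp <- scores[bi]
          improved <- TRUE
        }
      }
    }
    part <- match(z, unique(z)) # relabel by first appearance
    list(
      partition = part,
      n_blocks = max(part),
      log_posterior = lp,
      trace = trace
    )
  })
}

#' Block-ordered view of a relation with block-mean TE overlay
#'
#' Reorders a matrix so that IRM blocks form a diagonal sequence of
#' submatrices, and summarizes a value matrix (typically TE) as
#' block-to-block means.
#'
#' @param M Square matrix to reorder (binary relation or TE).
#' @param partition Block assignment from [irm_fit()].
#' @param values Optional value matrix for the block-mean overlay; defaults
#'   to `M`.
#' @return List with `order` (node permutation), `M_ordered`, and
#'   `block_means` (blocks by blocks matrix of mean values over ordered
#'   node pairs, diagonal pairs excluded).
#' @export
irm_block_view <- function(M, partition, values = NULL) {
  values <- values %||% M
  ord <- order(partition)
  K <- max(partition)
  bm <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      ia <- which(partition == a)
      ib <- which(partition == b)
      V <- values[ia, ib, drop = FALSE]
      if (a == b) {
        if (length(ia) > 1) bm[a, b] <- mean(V[row(V) != col(V)])
      } else {
        bm[a, b] <- mean(V)
      }
    }
  }
  list(order = ord, M_ordered = M[ord, ord], block_means = bm)
}
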