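#' Synthetic fixtures with known ground truth
#'
#' Generators used to validate each analysis stage without running the full
#' simulator: a bivariate Gaussian autoregressive pair with analytically
#' known transfer entropy, planted stochastic block models for the IRM, and
#' switching multivariate sinusoid trajectories for the behavior pipeline.
#' Every fixture's ground truth is a deterministic function of its
#' parameters and seed.
#'
#' @name synthvalid
NULL

#' Gaussian AR pair with closed-form transfer entropy
#'
#' Generates `X_{t+1} = a_x * X_t + c_y * Y_t + e_x` with `Y` and `e_x`
#' i.i.d. standard normal, and computes the analytic TE in both directions
#' from the stationary covariance (Gaussian entropies via determinants, an
#' oracle independent of the KSG estimator). `TE(Y -> X) =
#' 0.5 * log(1 + c_y^2)` for unit noise; `TE(X -> Y) = 0` (no feedback).
#'
#' @param a_x AR coefficient, `|a_x| < 1`.
#' @param c_y Coupling from Y into X.
#' @param n Series length.
#' @param seed RNG seed.
#' @return A list with `x`, `y`, `te_yx`, `te_xy` (nats), and the
#'   parameters.
#' @export
gaussian_var_pair <- function(a_x, c_y, n, seed = NULL) {
  if (abs(a_x) >= 1) stop_invalid("non-stationary AR parameter |a_x| >= 1")
  dat <- with_seed(seed, {
    y <- rnorm(n)
    e <- rnorm(n)
    x <- numeric(n)
    x[1] <- rnorm(1, sd = sqrt((1 + c_y^2) / (1 - a_x^2)))
    for (t in seq_len(n - 1)) {
      x[t + 1] <- a_x * x[t] + c_y * y[t] + e[t]
    }
    list(x = x, y = y)
  })
  list(
    x = dat$x, y = dat$y,
    te_yx = gaussian_var_te(a_x, c_y),
    te_xy = 0,
    a_x = a_x, c_y = c_y, n = n, seed = seed
  )
}

#' @rdname gaussian_var_pair
#' @details `gaussian_var_te()` is the covariance-algebra oracle: it builds
#'   the stationary covariance of `(X_{t+1}, X_t, Y_t)` and evaluates the
#'   Gaussian conditional-entropy determinant ratio
#'   `0.5 * log( det(S_{x+,x}) * det(S_{x,y}) / (det(S_x) * det(S_{x+,x,y})) )`.
#' @export
gaussian_var_te <- function(a_x, c_y) {
  vx <- (1 + c_y^2) / (1 - a_x^2) # stationary var(X)
  # order: (X_{t+1}, X_t, Y_t); var(Y) = 1, X_t independent of Y_t
  S <- matrix(c(
    vx, a_x * vx, c_y,
    a_x * vx, vx, 0,
    c_y, 0, 1
  ), 3, 3, byrow = TRUE)
  det2 <- function(idx) det(S[idx, idx, drop = FALSE])
  0.5 * log(det2(c(1, 2)) * det2(c(2, 3)) / (det2(2) * det(S)))
}

#' Planted stochastic block model
#'
#' Binary directed adjacency with `blocks` equal planted blocks: link
#' probability `p_in` within a block and `p_out` between blocks; zero
#' diagonal.
#'
#' @param n Nodes.
#' @param blocks Number of planted blocks.
#' @param p_in,p_out Within/between link probabilities, `p_in > p_out`.
#' @param seed RNG seed.
#' @return List with `B` (adjacency) and `partition` (planted blocks).
#' @export
planted_blockmodel <- function(n, blocks, p_in, p_out, seed = NULL) {
  if (p_in <= p_out) stop_invalid("planted blockmodel needs p_in > p_out")
  part <- rep(seq_len(blocks), length.out = n)
  part <- sort(part)
  with_seed(seed, {
    same <- outer(part, part, `==`)
    P <- ifelse(same, p_in, p_out)
    B <- matrix(as.integer(runif(n * n) < P), n, n)
    diag(B) <- 0L
    list(B = B, partition = part, p_in = p_in, p_out = p_out, seed = seed)
  })
}

#' Switching multivariate sinusoid trajectory
#'
#' Emulates a joint-angle record that switches between planted movement
#' patterns: each pattern is a distinct traveling-wave configuration (its
#' own per-joint phase offset, and amplitude) plus small Gaussian noise.
#' Dwell times longer than twice the analysis window are recoverable by the
#' behavior pipeline; shorter dwells may be missed (documented limitation).
#'
#' @param patterns Number of distinct patterns.
#' @param dwell_times Dwell duration(s) in seconds: recycled across
#'   episodes.
#' @param n_episodes Number of episodes (pattern switches + 1); patterns
#'   cycle in order.
#' @param n_joints Number of joints (default 14).
#' @param sample_dt Sampling period (s).
#' @param freq Base oscillation frequency (Hz).
#' @param noise_sd Additive angle noise (rad).
#' @param seed RNG seed.
#' @return List with `theta` (samples by joints), `labels_true` (per
#'   sample), `switch_times`, `sample_dt`.
#' @export
switching_traj <- function(patterns, dwell_times, n_episodes = patterns + 1,
                           n_joints = 14, sample_dt = 0.1, freq = 0.5,
                           noise_sd = 0.03, seed = NULL) {
  dwells <- rep_len(dwell_times, n_episodes)
  pat_seq <- rep_len(seq_len(patterns), n_episodes)
  with_seed(seed, {
    # pattern-specific traveling-wave configs: per-joint phase increments
    # kept well separated so planted patterns are genuinely distinct
    phase_inc <- sample(seq(0.4, 2.4, length.out = patterns))
    amp <- sample(seq(0.3, 0.6, length.out = patterns))
    global_phase <- runif(patterns, 0, 2 * pi)
    total <- sum(dwells)
    times <- seq(0, total - sample_dt, by = sample_dt)
    labels <- integer(length(times))
    theta <- matrix(0, length(times), n_joints)
    t_edge <- cumsum(c(0, dwells))
    for (ep in seq_len(n_episodes)) {
      sel <- times >= t_edge[ep] & times < t_edge[ep + 1]
      p <- pat_seq[ep]
      ph <- outer(2 * pi * freq * times[sel] + global_phase[p],
                  phase_inc[p] * seq_len(n_joints), `+`)
      theta[sel, ] <- amp[p] * sin(ph)
      labels[sel] <- p
    }
    theta <- theta + matrix(rnorm(length(theta), sd = noise_sd), nrow(theta))
    list(
      theta = theta, labels_true = labels,
      switch_times = t_edge[-c(1, length(t_edge))],
      sample_dt = sample_dt, patterns = patterns, seed = seed
    )
  })
}

#' Driven panel fixture for directed information flow
#'
#' A small panel where node 1 drives a set of target nodes with lag one;
#' all other nodes are independent AR(1) noise. Used to check that high
#' outgoing TE identifies the planted driver.
#'
#' @param n_nodes Panel size.
#' @param targets Indices driven by node 1.
#' @param coupling Driver coupling strength.
#' @param n Samples.
#' @param seed RNG seed.
#' @return List with `X` (samples by nodes) and `targets`.
#' @export
driven_panel <- function(n_nodes = 10, targets = 2:4, coupling = 0.8,
                         n = 2000, seed = NULL) {
  with_seed(seed, {
    X <- matrix(rnorm(n * n_nodes), n, n_nodes)
    for (t in 2:n) {
      X[t, ] <- 0.3 * X[t - 1, ] + X[t, ]
      X[t, targets] <- X[t, targets] + coupling * X[t - 1, 1]
    }
    list(X = X, targets = targets, coupling = coupling, seed = seed)
  })
}
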