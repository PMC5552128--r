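#' Bonhoeffer-van der Pol oscillator parameters
#'
#' The per-neuron dynamics are
#' `tau * dx/dt = c * (x - x^3/3 - y + z) + delta * (Sf - x)` and
#' `tau * dy/dt = (1/c) * (x - b*y + a) + eps * Sf`,
#' where `z` is a tonic input setting the oscillatory regime and `Sf` is the
#' coupling input of [coupling_term()]. Defaults are the study conditions:
#' `a = 0.7`, `b = -0.2`, `c = 2`, `delta = 0.01` (excitatory gain),
#' `eps = 0.015` (inhibitory gain), tonic input on the grid
#' 0.4/0.45/0.5/0.55.
#'
#' @param a,b,c Dimensionless shape parameters.
#' @param z Tonic input.
#' @param delta,eps Excitatory/inhibitory coupling gains.
#' @param alpha Sensor ratio in `[0, 1]`: weight of bodily sensory feedback
#'   in the coupling input of interface neurons (0 = pure network drive,
#'   1 = pure sensory drive).
#' @param tau Time constant (s).
#' @param dt Integration step (s).
#' @param sample_dt State sampling period for analysis output (s).
#' @return A `bvp_params` list.
#' @export
bvp_params <- function(a = 0.7, b = -0.2, c = 2.0, z = 0.4,
                       delta = 0.01, eps = 0.015, alpha = 0,
                       tau = 1, dt = 0.01, sample_dt = 0.1) {
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must be in [0, 1]")
  if (dt <= 0) stop_invalid("dt must be positive")
  structure(
    list(
      a = a, b = b, c = c, z = z, delta = delta, eps = eps,
      alpha = alpha, tau = tau, dt = dt, sample_dt = sample_dt
    ),
    class = "bvp_params"
  )
}

# index (1-based muscle id, or NA) of the muscle driven by each neuron
interface_assignment <- function(net) {
  iface <- which(net$roles == "interface")
  assign <- rep(NA_integer_, net$n)
  assign[iface] <- seq_along(iface)
  assign
}

#' Coupling input for each neuron
#'
#' The network term for neuron `i` is `(1/K_i) * sum_j w_ji * x_j` over its
#' `K_i` presynaptic neighbors (0 if it has none). Hidden neurons receive
#' that term as-is; interface neurons blend it with their muscle's sensory
#' feedback: `Sf = alpha * I + (1 - alpha) * network term`.
#'
#' @param x Activation vector (one per neuron).
#' @param net A `wired_network` with roles assigned.
#' @param sensory Sensory feedback vector, one entry per interface neuron
#'   (in interface order); may be `NULL` when `alpha = 0`.
#' @param alpha Sensor ratio.
#' @return Numeric vector `Sf`, one entry per neuron.
#' @export
coupling_term <- function(x, net, sensory = NULL, alpha = 0) {
  K <- colSums(net$A)
  net_term <- as.vector(crossprod(net$W, x))
  net_term <- ifelse(K > 0, net_term / K, 0)
  assign <- interface_assignment(net)
  sf <- net_term
  is_if <- !is.na(assign)
  if (any(is_if)) {
    if (is.null(sensory)) {
      if (alpha > 0) stop_invalid("sensory input required when alpha > 0")
    } else {
      sf[is_if] <- alpha * sensory[assign[is_if]] + (1 - alpha) * net_term[is_if]
    }
  }
  sf
}

#' Oscillator state derivatives
#'
#' @param x,y State vectors.
#' @param sf Coupling input (from [coupling_term()]).
#' @param p A `bvp_params`.
#' @return List with `dx` and `dy`.
#' @export
bvp_derivatives <- function(x, y, sf, p) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite oscillator state", class = "serpens_divergence")
  }
  dx <- (p$c * (x - x^3 / 3 - y + p$z) + p$delta * (sf - x)) / p$tau
  dy <- ((x - p$b * y + p$a) / p$c + p$eps * sf) / p$tau
  list(dx = dx, dy = dy)
}

#' Nullcline intersection of an uncoupled oscillator
#'
#' Solves `x - x^3/3 - y + z = 0` and `x - b*y + a = 0` for the equilibrium
#' of a single uncoupled neuron; used for equilibrium checks.
#'
#' @param p A `bvp_params`.
#' @return List with `x` and `y` at the intersection.
#' @export
bvp_equilibrium <- function(p) {
  # substitute y = (x + a)/b into the cubic nullcline
  f <- function(x) x - x^3 / 3 - (x + p$a) / p$b + p$z
  root <- stats::uniroot(f, c(-10, 10), tol = 1e-14)$root
  list(x = root, y = (root + p$a) / p$b)
}

#' Simulate the oscillator network open-loop
#'
#' Runs the network with no body in the loop (the spontaneous-activation
#' regime: the sensor ratio plays no role because no sensory signal exists).
#' Initial states are drawn i.i.d. uniform on `[-0.1, 0.1]`.
#'
#' @param net A `wired_network`.
#' @param p A `bvp_params`.
#' @param duration Run length (s).
#' @param seed Seed for the initial state.
#' @param keep_y Keep recovery variables in the output.
#' @return A trajectory tibble: `time`, `x1..xn` (and `y1..yn`).
#' @export
simulate_free <- function(net, p = bvp_params(), duration = 100,
                          seed = NULL, keep_y = TRUE) {
  stopifnot(duration > 0)
  init <- with_seed(seed, list(
    x = runif(net$n, -0.1, 0.1), y = runif(net$n, -0.1, 0.1)
  ))
  body <- build_snake()
  p_free <- p
  p_free$alpha <- 0
  out <- run_coupled_cpp(
    net$W, interface_muscle_0based(net),
    bvp_list(p_free), body$params, init$x, init$y,
    duration, p$dt, max(1L, round(p$sample_dt / p$dt)),
    use_body = FALSE
  )
  if (out$diverged) warn("oscillator state diverged; trajectory truncated")
  neural_tibble(out, keep_y = keep_y)
}

# ---- internal glue ----

bvp_list <- function(p) {
  list(
    a = p$a, b = p$b, c = p$c, z = p$z, delta = p$delta, eps = p$eps,
    alpha = p$alpha, tau = p$tau
  )
}

interface_muscle_0based <- function(net) {
  assign <- interface_assignment(net)
  ifelse(is.na(assign), -1L, as.integer(assign - 1L))
}

neural_tibble <- function(out, keep_y = TRUE) {
  n <- ncol(out$x)
  xs <- tibble::as_tibble(out$x, .name_repair = ~ paste0("x", seq_len(n)))
  res <- dplyr::bind_cols(tibble::tibble(time = as.vector(out$time)), xs)
  if (keep_y) {
    ys <- tibble::as_tibble(out$y, .name_repair = ~ paste0("y", seq_len(n)))
    res <- dplyr::bind_cols(res, ys)
  }
  res
}
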