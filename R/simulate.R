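#' Run one closed-loop brain-body simulation
#'
#' Couples a wired oscillator network to the planar snake body: at every
#' integration step the body's muscle stretch is read out as sensory
#' feedback, blended into the interface neurons' coupling input by the
#' sensor ratio `alpha`, the oscillators advance one RK4 step, interface
#' activations set muscle rest-length commands, and the body advances one
#' overdamped step. Deterministic for a fixed seed.
#'
#' @param net A `wired_network` with exactly as many interface neurons as
#'   the body has muscles.
#' @param p A [bvp_params()] (its `alpha` is the sensor ratio).
#' @param body A [build_snake()] model.
#' @param duration Simulated time (s).
#' @param burn_in Initial stretch (s) flagged for exclusion from analysis;
#'   retained in the trajectory.
#' @param seed Seed for the random initial oscillator state.
#' @param keep_y Keep recovery variables.
#' @return A `coupled_trajectory`: a tibble with columns `time`,
#'   `x1..xn` (+ `y*`), `theta1..`, `L1..`, `head_x`, `head_y`, `heading`,
#'   carrying the configuration as attributes.
#' @export
run_coupled_simulation <- function(net, p = bvp_params(), body = build_snake(),
                                   duration = 2000, burn_in = 50,
                                   seed = NULL, keep_y = FALSE) {
  n_if <- sum(net$roles == "interface")
  if (n_if != body$n_muscles) {
    stop_invalid(
      "network has %d interface neurons but body has %d muscles",
      n_if, body$n_muscles
    )
  }
  init <- with_seed(seed, list(
    x = runif(net$n, -0.1, 0.1), y = runif(net$n, -0.1, 0.1)
  ))
  out <- run_coupled_cpp(
    net$W, interface_muscle_0based(net),
    bvp_list(p), body$params, init$x, init$y,
    duration, p$dt, max(1L, round(p$sample_dt / p$dt)),
    use_body = TRUE
  )
  if (out$diverged) {
    warn("simulation diverged; partial trajectory returned")
  }
  traj <- neural_tibble(out, keep_y = keep_y)
  nj <- ncol(out$theta)
  nm <- ncol(out$muscle_len)
  traj <- dplyr::bind_cols(
    traj,
    tibble::as_tibble(out$theta, .name_repair = ~ paste0("theta", seq_len(nj))),
    tibble::as_tibble(out$muscle_len, .name_repair = ~ paste0("L", seq_len(nm))),
    tibble::tibble(
      head_x = out$head[, 1], head_y = out$head[, 2], heading = out$head[, 3]
    )
  )
  structure(traj,
    class = c("coupled_trajectory", class(traj)),
    burn_in = burn_in,
    roles = net$roles,
    alpha = p$alpha, z = p$z,
    topology = net$topology, weight_scheme = net$weight_scheme,
    seed = seed,
    sample_dt = p$sample_dt,
    diverged = out$diverged
  )
}

#' Extract sub-matrices from a trajectory
#'
#' @param traj A trajectory tibble.
#' @param what `"x"`, `"y"` or `"theta"`.
#' @param drop_burn_in Drop the flagged burn-in stretch.
#' @return A numeric matrix (samples by series) with a `time` attribute.
#' @export
trajectory_matrix <- function(traj, what = c("x", "theta", "y"),
                              drop_burn_in = TRUE) {
  what <- match.arg(what)
  cols <- grep(paste0("^", what, "[0-9]+$"), names(traj), value = TRUE)
  if (length(cols) == 0) stop_invalid("trajectory has no '%s' columns", what)
  keep <- rep(TRUE, nrow(traj))
  if (drop_burn_in && !is.null(attr(traj, "burn_in"))) {
    keep <- traj$time >= attr(traj, "burn_in")
  }
  m <- as.matrix(traj[keep, cols])
  attr(m, "time") <- traj$time[keep]
  m
}
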