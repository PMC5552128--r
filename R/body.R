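#' Planar snake-like musculoskeletal body
#'
#' A simplified two-dimensional articulated chain standing in for a
#' snake-like robot: `n_links` rigid links joined by `n_links - 1` hinge
#' joints, actuated by two-joint antagonist muscles (one left, one right per
#' adjacent joint pair, so `2 * (n_joints - 1)` muscles; 26 for the default
#' 15-link body). Muscles are linear spring-dampers whose rest length is
#' modulated by the motor command; joint dynamics are overdamped; net motion
#' of the head comes from a viscous anisotropic-friction ground model (low
#' drag along a link, high drag sideways), so traveling body waves produce
#' net translation.
#'
#' Geometry is abstracted into two constants: the muscle rest length `L0`
#' (the span of two link-to-link gaps) and a geometry factor `kappa`, the
#' fractional muscle-length change per radian of mean bend of the two spanned
#' joints: `L = L0 * (1 - side * kappa * (theta_q + theta_{q+1}) / 2)`.
#'
#' @param n_links Number of body links (default 15).
#' @param link_len,link_width,link_height,gap,mass Link dimensions (m) and
#'   mass (kg); defaults 0.1, 0.1, 0.1, 0.02 and 0.6.
#' @param kappa Geometry factor (1/rad).
#' @param k_s,k_d Muscle spring stiffness (N/m) and damping (N s/m).
#' @param b_visc Joint viscous resistance (N m s/rad) of the overdamped
#'   angular update.
#' @param joint_limit Maximum |joint angle| (rad).
#' @param gain_motor Motor gain `g`: commanded rest length is
#'   `L0 * (1 + g * tanh(x))`.
#' @param sigma_sensory Sensory gain: feedback is
#'   `sigma * (L - L0) / L0`, clipped to `[-2, 2]`.
#' @param c_t,c_n,c_rot Ground drag coefficients: tangential, normal
#'   (N s/m per link) and rotational (N m s/rad per link).
#' @return A `body_model` object.
#' @export
build_snake <- function(n_links = 15, link_len = 0.1, link_width = 0.1,
                        link_height = 0.1, gap = 0.02, mass = 0.6,
                        kappa = 0.4, k_s = 200, k_d = 2, b_visc = 0.5,
                        joint_limit = pi / 3, gain_motor = 0.4,
                        sigma_sensory = 1.5, c_t = 0.1, c_n = 10,
                        c_rot = 0.05) {
  if (n_links < 3) stop_invalid("a snake body needs at least 3 links")
  n_joints <- n_links - 1
  n_spans <- n_joints - 1
  muscles <- tibble::tibble(
    muscle = seq_len(2 * n_spans),
    side = rep(c("left", "right"), each = n_spans),
    joint_a = rep(seq_len(n_spans), 2),
    joint_b = rep(seq_len(n_spans) + 1, 2)
  )
  structure(
    list(
      n_links = n_links, n_joints = n_joints, n_muscles = 2 * n_spans,
      muscles = muscles,
      params = list(
        n_links = n_links, link_len = link_len, link_width = link_width,
        link_height = link_height, gap = gap, mass = mass,
        L0 = 2 * (link_len + gap), kappa = kappa, k_s = k_s, k_d = k_d,
        b_visc = b_visc, joint_limit = joint_limit,
        gain_motor = gain_motor, sigma_sensory = sigma_sensory,
        c_t = c_t, c_n = c_n, c_rot = c_rot
      )
    ),
    class = "body_model"
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf(
    "<body_model> %d links, %d hinge joints, %d two-joint muscles (L0 = %.2f m)\n",
    x$n_links, x$n_joints, x$n_muscles, x$params$L0
  ))
  invisible(x)
}

new_body_state <- function(model, theta = NULL) {
  theta <- theta %||% rep(0, model$n_joints)
  structure(
    list(
      theta = theta,
      theta_dot = rep(0, model$n_joints),
      head = c(x = 0, y = 0, heading = 0),
      muscle_len = muscle_length(list(theta = theta), model)
    ),
    class = "body_state"
  )
}

#' Geometric muscle lengths for a body state
#'
#' Left and right muscles over the same joint pair are exact mirror images:
#' bending toward a side shortens that side's muscle and lengthens its
#' antagonist by the same amount. Lengths are clamped at `0.1 * L0` (with a
#' warning) if a command/geometry combination would make them non-positive.
#'
#' @param state A `body_state` (or any list with a `theta` vector).
#' @param model A `body_model`.
#' @return Numeric vector of muscle lengths (m), ordered left then right.
#' @export
muscle_length <- function(state, model) {
  p <- model$params
  th <- state$theta
  side <- ifelse(model$muscles$side == "left", 1, -1)
  bend <- (th[model$muscles$joint_a] + th[model$muscles$joint_b]) / 2
  L <- p$L0 * (1 - side * p$kappa * bend)
  if (any(L < 0.1 * p$L0)) {
    warn("muscle length clamped at 0.1 * L0")
    L <- pmax(L, 0.1 * p$L0)
  }
  L
}

#' Map interface-neuron activations to muscle rest-length commands
#'
#' Muscle `m` is driven by the `m`-th interface neuron (muscle order along
#' the body, left side then right). The activation is squashed with `tanh`
#' and scaled by the motor gain into a target rest length.
#'
#' @param x_interface Activations, one per muscle.
#' @param model A `body_model`.
#' @return List with `u` (squashed commands in `[-1, 1]`) and `rest_len`
#'   (target rest lengths, m).
#' @export
motor_map <- function(x_interface, model) {
  stopifnot(length(x_interface) == model$n_muscles)
  p <- model$params
  u <- tanh(x_interface)
  list(u = u, rest_len = p$L0 * (1 + p$gain_motor * u))
}

#' Sensory feedback from muscle stretch
#'
#' @param state A `body_state`.
#' @param model A `body_model`.
#' @return One feedback value per muscle/interface neuron:
#'   `sigma * (L - L0) / L0`, clipped to `[-2, 2]`.
#' @export
sensory_readout <- function(state, model) {
  p <- model$params
  L <- muscle_length(state, model)
  pmin(pmax(p$sigma_sensory * (L - p$L0) / p$L0, -2), 2)
}

#' Advance the body by one (or more) overdamped steps
#'
#' Spring-damper muscle tensions are mapped to generalized joint torques,
#' joints move against viscous resistance with hard angle limits, and the
#' head pose advances by solving the per-step force/torque balance of the
#' anisotropic ground drag.
#'
#' @param model A `body_model`.
#' @param state A `body_state`.
#' @param rest_len Commanded muscle rest lengths (from [motor_map()]).
#' @param dt Time step (s).
#' @param n_steps Number of sub-steps to take.
#' @return The advanced `body_state`.
#' @export
body_step <- function(model, state, rest_len, dt, n_steps = 1) {
  stopifnot(dt > 0)
  out <- body_step_cpp(
    state$theta, state$theta_dot, unname(state$head), rest_len,
    model$params, dt, n_steps
  )
  structure(
    list(
      theta = out$theta, theta_dot = out$theta_dot,
      head = setNames(out$head, c("x", "y", "heading")),
      muscle_len = out$muscle_len
    ),
    class = "body_state"
  )
}
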