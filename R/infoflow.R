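#' KSG mutual information estimate
#'
#' Kraskov-Stogbauer-Grassberger k-nearest-neighbor estimator (algorithm 1)
#' of the mutual information between two continuous series, in nats.
#'
#' @param x,y Numeric vectors of equal length (at least 100 samples).
#' @param k_neighbors Neighbor count `k` (default 4).
#' @return Estimated MI (nats). Constant input yields 0 with a warning;
#'   duplicated joint samples (e.g. `y` identical to `x`) are flagged as
#'   degenerate but still return a finite value.
#' @export
ksg_mutual_information <- function(x, y, k_neighbors = 4) {
  stopifnot(length(x) == length(y))
  if (length(x) < 100) stop_invalid("need at least 100 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant series: mutual information set to 0")
    return(0)
  }
  if (anyDuplicated(cbind(x, y)) > 0 || abs(cor(x, y)) > 1 - 1e-10) {
    warn("degenerate joint distribution: KSG estimate has no finite limit")
  }
  ksg_mi_cpp(as.double(x), as.double(y), as.integer(k_neighbors))
}

#' KSG transfer entropy estimate
#'
#' Transfer entropy from a source to a target series with history lengths
#' `l = k = 1`: the conditional mutual information
#' `I(target_{t+1}; source_t | target_t)`, estimated with the KSG
#' conditional estimator in the max-norm. Units are nats. Small negative
#' estimates are an expected finite-sample property of the estimator and are
#' returned as-is.
#'
#' @param source,target Aligned numeric series (at least 500 samples after
#'   embedding).
#' @param l,k_hist Source/target history lengths; only 1 is supported (the
#'   study condition).
#' @param k_neighbors KSG neighbor count (default 4).
#' @return Estimated TE (nats).
#' @export
ksg_transfer_entropy <- function(source, target, l = 1, k_hist = 1,
                                 k_neighbors = 4) {
  stopifnot(length(source) == length(target))
  if (l != 1 || k_hist != 1) stop_invalid("only history lengths l = k = 1 are supported")
  n <- length(target)
  if (n - 1 < 500) stop_invalid("need at least 500 samples after embedding")
  if (sd(target) == 0) {
    warn("constant target: transfer entropy set to 0")
    return(0)
  }
  ksg_cmi_cpp(
    target[-1], source[-n], target[-n],
    as.integer(k_neighbors)
  )
}

#' Estimate the information network of one movement pattern
#'
#' Restricts the neuron activation series to the union of all episodes of
#' one movement-pattern label and estimates pairwise transfer entropy
#' (`te_matrix[j, i]` = TE from neuron `j` to neuron `i`) and mutual
#' information between all retained neurons. For large networks a node
#' subset can be analysed (`max_nodes`): all interface neurons are kept and
#' hidden neurons are subsampled deterministically.
#'
#' @param traj A `coupled_trajectory`.
#' @param labeling A `window_labeling` for the same trajectory.
#' @param label The movement-pattern label whose episodes form the segment.
#' @param min_samples Minimum analysis samples; shorter segments abort with
#'   a `serpens_short_segment` condition.
#' @param max_samples Cap on samples used (evenly strided when exceeded).
#' @param max_nodes Cap on analysed neurons.
#' @param k_neighbors KSG neighbor count.
#' @param compute_mi Also estimate the MI matrix.
#' @param seed Seed for the hidden-neuron subsample.
#' @return An `info_network`: `te_matrix`, `mi_matrix`, `nodes` (original
#'   indices), `roles`, `pattern_label`, `duration` (total segment s),
#'   `n_samples`.
#' @export
estimate_info_network <- function(traj, labeling, label,
                                  min_samples = 500, max_samples = 800,
                                  max_nodes = Inf, k_neighbors = 4,
                                  compute_mi = TRUE, seed = NULL) {
  x <- trajectory_matrix(traj, "x", drop_burn_in = FALSE)
  times <- attr(x, "time")
  eps <- dplyr::filter(labeling$episodes, .data$label == !!label)
  if (nrow(eps) == 0) stop_invalid("no episodes with label %s", label)
  keep <- rep(FALSE, length(times))
  for (r in seq_len(nrow(eps))) {
    keep <- keep | (times >= eps$start_time[r] &
      times < eps$start_time[r] + eps$duration[r])
  }
  if (sum(keep) < min_samples) {
    abort(sprintf(
      "segment too short for information-network estimation (%d < %d samples)",
      sum(keep), min_samples
    ), class = "serpens_short_segment")
  }
  idx <- which(keep)
  if (length(idx) > max_samples) {
    idx <- idx[round(seq(1, length(idx), length.out = max_samples))]
  }
  roles <- attr(traj, "roles") %||% rep("hidden", ncol(x))
  nodes <- seq_len(ncol(x))
  if (length(nodes) > max_nodes) {
    iface <- which(roles == "interface")
    hidden <- which(roles == "hidden")
    n_hid <- max(0L, as.integer(max_nodes) - length(iface))
    hid_sel <- with_seed(seed, sample(hidden, min(n_hid, length(hidden))))
    nodes <- sort(c(iface, hid_sel))
  }
  X <- x[idx, nodes, drop = FALSE]
  res <- pairwise_te_mi_cpp(X, as.integer(k_neighbors), compute_mi)
  te <- res$te
  mi <- res$mi
  dimnames(te) <- dimnames(mi) <- list(nodes, nodes)
  structure(
    list(
      te_matrix = te, mi_matrix = if (compute_mi) mi else NULL,
      nodes = nodes, roles = roles[nodes],
      pattern_label = label,
      duration = sum(eps$duration),
      n_samples = length(idx),
      k_neighbors = k_neighbors
    ),
    class = "info_network"
  )
}

#' @export
print.info_network <- function(x, ...) {
  cat(sprintf(
    "<info_network> pattern %s: %d neurons, segment %.1f s (%d samples), mean TE %.4f nats\n",
    x$pattern_label, length(x$nodes), x$duration, x$n_samples,
    mean(x$te_matrix[row(x$te_matrix) != col(x$te_matrix)])
  ))
  invisible(x)
}

#' Otsu binarization of an information matrix
#'
#' Thresholds the off-diagonal entries (the Otsu histogram threshold) into a
#' binary relation for block-model analysis.
#'
#' @param M Square numeric matrix (e.g. an MI matrix), or an `info_network`
#'   (its MI matrix is used, falling back to TE).
#' @return Binary matrix with zero diagonal.
#' @export
binarize_otsu_matrix <- function(M) {
  if (inherits(M, "info_network")) M <- M$mi_matrix %||% M$te_matrix
  off <- M[row(M) != col(M)]
  thr <- otsu_threshold(off) # errors on constant input
  B <- (M > thr) * 1L
  diag(B) <- 0L
  B
}

#' Complex-network measures of an information network
#'
#' Applies the weighted directed clustering coefficient and inverse-weight
#' shortest paths to the TE matrix, with negative TE estimates clamped to 0
#' for measurement (they are retained raw in the matrix).
#'
#' @param inet An `info_network` (or TE matrix).
#' @return A `network_measures` list.
#' @export
info_network_measures <- function(inet) {
  W <- if (inherits(inet, "info_network")) inet$te_matrix else inet
  network_measures(pmax(W, 0))
}

#' Body-network influence summary
#'
#' Mean transfer entropy over all hidden-to-interface ordered neuron pairs
#' and over all interface-to-hidden pairs, quantifying how strongly the body
#' couples into the network during one movement pattern.
#'
#' @param inet An `info_network`.
#' @param roles Optional role vector (defaults to the one stored).
#' @return A tibble: `pattern_label`, `duration`, `te_hidden_to_interface`,
#'   `te_interface_to_hidden`.
#' @export
body_influence <- function(inet, roles = NULL) {
  roles <- roles %||% inet$roles
  te <- inet$te_matrix
  hid <- roles == "hidden"
  ifc <- roles == "interface"
  tibble::tibble(
    pattern_label = inet$pattern_label,
    duration = inet$duration,
    te_hidden_to_interface = mean(te[hid, ifc]),
    te_interface_to_hidden = mean(te[ifc, hid])
  )
}

#' @rdname info_network_measures
#' @param x An `info_network`.
#' @param ... Unused.
#' @export
glance.info_network <- function(x, ...) {
  m <- info_network_measures(x)
  dplyr::bind_cols(
    body_influence(x),
    tibble::tibble(
      avg_clustering = m$avg_clustering,
      avg_shortest_path = m$avg_shortest_path,
      max_degree = m$max_degree
    )
  )
}
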