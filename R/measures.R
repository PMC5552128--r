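#' Complex-network measures for weighted directed networks
#'
#' Measures are computed on absolute weights `|W|`: information is taken to
#' flow along an edge regardless of the sign of its weight.
#'
#' * **Clustering coefficient**: the weighted directed (Fagiolo-style) form.
#'   With `What = |W| / max|W|` (so that coefficients are bounded by 1),
#'   `C_i = [ (What^(1/3) + t(What)^(1/3))^3 ]_ii / (2 * (k_tot*(k_tot-1) - 2*k_bi))`
#'   where `k_tot` is a node's total (in + out) unweighted degree and `k_bi`
#'   its number of reciprocated partners. Nodes with an undefined denominator
#'   (`k_tot <= 1` or all partners reciprocated in a dyad-only pattern) get
#'   `C_i = 0` and are still counted in the average.
#' * **Average shortest path length**: edge lengths are inverse absolute
#'   weights `1/|w|`; a stronger connection is a shorter step. The average is
#'   over all ordered reachable pairs; unreachable pairs are excluded and
#'   counted in `n_unreachable`.
#' * **Node degree**: `degree_i = sum_j |w_ji|`, the total absolute incoming
#'   weight.
#'
#' @param W Square weight matrix with zero diagonal (`W[j, i]` = influence of
#'   `j` on `i`), or a `wired_network`/`info_network` object.
#' @return `network_measures(W)` returns a list with elements
#'   `clustering_per_node`, `avg_clustering`, `avg_shortest_path`,
#'   `n_unreachable`, `degree_per_node`, `max_degree`.
#' @name network-measures
NULL

as_weight_matrix <- function(W) {
  if (inherits(W, "wired_network")) W <- W$W
  if (inherits(W, "info_network")) W <- pmax(W$te_matrix, 0)
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop_invalid("W must be a square matrix")
  }
  W
}

#' @rdname network-measures
#' @export
clustering_coefficient <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  Wa <- abs(W)
  diag(Wa) <- 0
  A <- (Wa > 0) * 1
  mx <- max(Wa)
  if (mx == 0) {
    return(list(per_node = rep(0, n), avg = 0))
  }
  Wh <- (Wa / mx)^(1 / 3)
  S <- Wh + t(Wh)
  num <- diag(S %*% S %*% S) / 2
  k_tot <- rowSums(A) + colSums(A)
  k_bi <- diag(A %*% A)
  den <- k_tot * (k_tot - 1) - 2 * k_bi
  ci <- ifelse(den > 0, num / den, 0)
  list(per_node = ci, avg = mean(ci))
}

#' @rdname network-measures
#' @export
shortest_path_length <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  Wa <- abs(W)
  diag(Wa) <- 0
  idx <- which(Wa > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort("average shortest path undefined: network has no edges",
      class = "serpens_disconnected"
    )
  }
  # edge j -> i has length 1/|w_ji|
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1], to = idx[, 2], weight = 1 / Wa[idx]),
    directed = TRUE, vertices = data.frame(name = seq_len(n))
  )
  D <- igraph::distances(g, mode = "out")
  diag(D) <- NA
  finite <- is.finite(D)
  n_unreach <- sum(!finite & !is.na(D))
  if (!any(finite, na.rm = TRUE)) {
    abort("average shortest path undefined: no reachable pairs",
      class = "serpens_disconnected"
    )
  }
  list(avg = mean(D[which(finite)]), n_unreachable = n_unreach)
}

#' @rdname network-measures
#' @export
node_degrees <- function(W) {
  W <- as_weight_matrix(W)
  Wa <- abs(W)
  diag(Wa) <- 0
  deg <- colSums(Wa)
  list(per_node = deg, max = max(deg))
}

#' @rdname network-measures
#' @export
network_measures <- function(W) {
  W <- as_weight_matrix(W)
  cl <- clustering_coefficient(W)
  sp <- tryCatch(shortest_path_length(W),
    serpens_disconnected = function(e) list(avg = NA_real_, n_unreachable = NA_integer_)
  )
  dg <- node_degrees(W)
  structure(
    list(
      clustering_per_node = cl$per_node,
      avg_clustering = cl$avg,
      avg_shortest_path = sp$avg,
      n_unreachable = sp$n_unreachable,
      degree_per_node = dg$per_node,
      max_degree = dg$max
    ),
    class = "network_measures"
  )
}

#' @export
print.network_measures <- function(x, ...) {
  cat(sprintf(
    "<network_measures> C-bar = %.4f, avg path = %.4f (%s unreachable), max degree = %.4f\n",
    x$avg_clustering, x$avg_shortest_path,
    ifelse(is.na(x$n_unreachable), "NA", x$n_unreachable), x$max_degree
  ))
  invisible(x)
}
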