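#' Wired oscillator networks
#'
#' A *wired network* is the fixed, generated connectivity among oscillators:
#' a signed weight matrix `W` (`W[j, i]` is the influence of node `j` on node
#' `i`), its binary support `A`, per-node roles (`"interface"` neurons talk to
#' the body, `"hidden"` neurons only to other neurons), and the generator
#' provenance (topology tag, parameters, seed).
#'
#' Four topologies are provided: a ring-lattice regular network, the
#' Watts-Strogatz small-world rewiring of that ring, a random network (the
#' small-world construction at rewiring probability 1), and a scale-free
#' network grown by smoothed preferential attachment. All generators produce
#' undirected graphs stored bidirectionally in `W`.
#'
#' @param n Number of nodes.
#' @param m Regular/small-world: neighbors on each side of the ring.
#'   Scale-free: edges added per new node.
#' @param p Rewiring probability in `[0, 1]`.
#' @param m0 Scale-free: size of the seed set of initially unconnected nodes;
#'   requires `m < m0`.
#' @param seed Optional integer seed; when given, generation is reproducible
#'   and the caller's RNG state is untouched.
#' @return A `wired_network` object.
#' @name wirednet
NULL

new_wired_network <- function(W, topology, weight_scheme = "uniform",
                              params = list(), seed = NULL,
                              roles = NULL) {
  n <- nrow(W)
  diag(W) <- 0
  structure(
    list(
      n = n,
      W = W,
      A = (W != 0) * 1L,
      roles = roles %||% rep("hidden", n),
      topology = topology,
      weight_scheme = weight_scheme,
      params = params,
      seed = seed
    ),
    class = "wired_network"
  )
}

#' @export
print.wired_network <- function(x, ...) {
  cat(sprintf(
    "<wired_network> %s (%s weights): %d nodes, %d directed edges, %d interface\n",
    x$topology, x$weight_scheme, x$n, sum(x$A), sum(x$roles == "interface")
  ))
  invisible(x)
}

#' @rdname wirednet
#' @export
build_regular <- function(n, m) {
  if (n <= 2 * m) {
    stop_invalid("build_regular() needs n > 2m (got n = %d, m = %d)", n, m)
  }
  W <- matrix(0, n, n)
  for (k in seq_len(m)) {
    idx <- seq_len(n)
    nb <- ((idx - 1 + k) %% n) + 1
    W[cbind(idx, nb)] <- 1
    W[cbind(nb, idx)] <- 1
  }
  new_wired_network(W, "regular", params = list(m = m))
}

#' @rdname wirednet
#' @export
build_ws <- function(n, m, p, seed = NULL) {
  if (p < 0 || p > 1) stop_invalid("rewiring probability must be in [0, 1]")
  base <- build_regular(n, m)
  with_seed(seed, {
    # operate on the undirected ring edges (i, i+k); rewiring keeps the
    # undirected edge count n*m, hence 2*n*m directed entries
    S <- base$W # symmetric 0/1
    for (k in seq_len(m)) {
      for (i in seq_len(n)) {
        j <- ((i - 1 + k) %% n) + 1
        if (S[i, j] == 0) next # may have been rewired away already
        if (runif(1) < p) {
          candidates <- which(S[i, ] == 0)
          candidates <- setdiff(candidates, i)
          if (length(candidates) == 0) next
          jnew <- candidates[sample.int(length(candidates), 1)]
          S[i, j] <- S[j, i] <- 0
          S[i, jnew] <- S[jnew, i] <- 1
        }
      }
    }
    new_wired_network(S, if (p >= 1) "random" else "ws",
      params = list(m = m, p = p), seed = seed
    )
  })
}

#' @rdname wirednet
#' @export
build_ba <- function(n, m0, m, seed = NULL) {
  if (m >= m0) stop_invalid("build_ba() requires m < m0 (got m = %d, m0 = %d)", m, m0)
  if (m0 >= n) stop_invalid("build_ba() requires m0 < n")
  with_seed(seed, {
    S <- matrix(0, n, n)
    deg <- rep(0, n) # undirected degree among the first `present` nodes
    present <- m0 # seed nodes start disconnected; (k+1) smoothing
    for (v in (m0 + 1):n) {
      prob <- deg[seq_len(present)] + 1
      targets <- sample.int(present, size = m, replace = FALSE,
                            prob = prob / sum(prob))
      for (t in targets) {
        S[v, t] <- S[t, v] <- 1
        deg[t] <- deg[t] + 1
        deg[v] <- deg[v] + 1
      }
      present <- present + 1
    }
    new_wired_network(S, "ba", params = list(m0 = m0, m = m), seed = seed)
  })
}

#' Assign connection weights to a wired network
#'
#' Under the `"uniform"` scheme every existing edge has weight 1. Under the
#' `"random"` scheme weights are drawn i.i.d. uniform on `[-1, 1]` and then,
#' for each node with at least one incoming edge, rescaled so the absolute
#' incoming weights sum to one.
#'
#' @param net A `wired_network`.
#' @param scheme `"uniform"` or `"random"`.
#' @inheritParams wirednet
#' @return The network with `W` replaced.
#' @export
assign_weights <- function(net, scheme = c("uniform", "random"), seed = NULL) {
  scheme <- match.arg(scheme)
  A <- net$A
  if (scheme == "uniform") {
    W <- A * 1
  } else {
    W <- with_seed(seed, {
      raw <- matrix(runif(net$n^2, -1, 1), net$n, net$n) * A
      colsum <- colSums(abs(raw))
      empty <- colsum == 0 & colSums(A) > 0 # measure-zero: raw weights all 0
      if (any(colSums(A) == 0)) {
        inform(sprintf(
          "%d node(s) with zero in-degree: no incoming weights to normalize",
          sum(colSums(A) == 0)
        ))
      }
      scale <- ifelse(colsum > 0, 1 / colsum, 0)
      sweep(raw, 2, scale, `*`)
    })
  }
  net$W <- W
  net$A <- (W != 0) * 1L
  net$weight_scheme <- scheme
  net
}

#' Assign interface/hidden roles
#'
#' Flags `n_interface` nodes as interface neurons (those coupled to muscles);
#' the rest are hidden. Placement strategies: `"random"` (uniform among
#' nodes), `"hubs"` (highest incoming |w| degree first), `"spread"` (evenly
#' spaced by node index).
#'
#' @param net A `wired_network`.
#' @param n_interface Number of interface neurons (default 26).
#' @param strategy Placement strategy.
#' @inheritParams wirednet
#' @export
assign_roles <- function(net, n_interface = 26,
                         strategy = c("random", "hubs", "spread"),
                         seed = NULL) {
  strategy <- match.arg(strategy)
  if (n_interface > net$n) stop_invalid("n_interface exceeds network size")
  idx <- switch(strategy,
    random = with_seed(seed, sample.int(net$n, n_interface)),
    hubs = order(colSums(abs(net$W)), decreasing = TRUE)[seq_len(n_interface)],
    spread = unique(round(seq(1, net$n, length.out = n_interface)))
  )
  roles <- rep("hidden", net$n)
  roles[idx] <- "interface"
  net$roles <- roles
  net
}

#' Build one of the study's standard wired networks
#'
#' Convenience wrapper: topology + weights + roles in one call, using the
#' study's default size (200 nodes, 26 interface neurons) and generator
#' parameters (regular `m = 2`; small-world `p` 0.01 or 0.05; random `p = 1`;
#' scale-free `m0 = 2`, `m = 1`).
#'
#' @param topology One of `"regular"`, `"ws"`, `"random"`, `"ba"`.
#' @param weights `"uniform"` or `"random"`.
#' @param n,n_interface Network size and number of interface nodes.
#' @param p Rewiring probability for `"ws"` (ignored otherwise).
#' @param role_strategy Interface placement (see [assign_roles()]).
#' @inheritParams wirednet
#' @export
build_wired_network <- function(topology = c("ws", "regular", "random", "ba"),
                                weights = c("random", "uniform"),
                                n = 200, n_interface = 26, p = 0.05,
                                role_strategy = "random", seed = NULL) {
  topology <- match.arg(topology)
  weights <- match.arg(weights)
  net <- switch(topology,
    regular = build_regular(n, m = 2),
    ws = build_ws(n, m = 2, p = p, seed = seed),
    random = build_ws(n, m = 2, p = 1, seed = seed),
    ba = build_ba(n, m0 = 2, m = 1, seed = derive_seed(seed %||% 0, 7))
  )
  net <- assign_weights(net, weights, seed = derive_seed(seed %||% 0, 11))
  assign_roles(net, n_interface,
    strategy = role_strategy,
    seed = derive_seed(seed %||% 0, 13)
  )
}

#' Edge table of a wired or information network
#'
#' @param x A `wired_network`.
#' @param ... Unused.
#' @return A tibble with one row per directed edge: `from`, `to`, `weight`.
#' @export
tidy.wired_network <- function(x, ...) {
  idx <- which(x$W != 0, arr.ind = TRUE)
  tibble::tibble(
    from = idx[, 1], to = idx[, 2],
    weight = x$W[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' One-row summary of a wired network
#'
#' @param x A `wired_network`.
#' @param ... Unused.
#' @return A tibble with node/edge counts and the complex-network measures.
#' @export
glance.wired_network <- function(x, ...) {
  m <- network_measures(x$W)
  tibble::tibble(
    topology = x$topology, weight_scheme = x$weight_scheme,
    n_nodes = x$n, n_edges = sum(x$A),
    n_interface = sum(x$roles == "interface"),
    avg_clustering = m$avg_clustering,
    avg_shortest_path = m$avg_shortest_path,
    max_degree = m$max_degree
  )
}
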