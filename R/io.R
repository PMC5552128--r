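#' Save and load networks and trajectories
#'
#' Networks are persisted as a plain-text edge list (`from`, `to`, `weight`)
#' next to a JSON header carrying node count, roles, topology tag, weight
#' scheme, generator parameters and seed; trajectories as CSV with a JSON
#' sidecar for their attributes. All files are plain text and round-trip the
#' numeric values at full precision.
#'
#' @param net A `wired_network`.
#' @param path File stem: `write_network()` writes `<path>.edges.csv` and
#'   `<path>.json`; `write_trajectory()` writes `<path>.csv` and
#'   `<path>.json`.
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name serpens-io
NULL

#' @rdname serpens-io
#' @export
write_network <- function(net, path) {
  readr::write_csv(tidy(net), paste0(path, ".edges.csv"))
  jsonlite::write_json(
    list(
      n = net$n, roles = net$roles, topology = net$topology,
      weight_scheme = net$weight_scheme, params = net$params,
      seed = net$seed
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname serpens-io
#' @export
read_network <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- readr::read_csv(paste0(path, ".edges.csv"),
    show_col_types = FALSE
  )
  W <- matrix(0, hdr$n, hdr$n)
  W[cbind(edges$from, edges$to)] <- edges$weight
  net <- new_wired_network(W, hdr$topology, hdr$weight_scheme,
    params = as.list(hdr$params), seed = hdr$seed
  )
  net$roles <- hdr$roles
  net
}

#' @rdname serpens-io
#' @param traj A trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), paste0(path, ".csv"))
  meta <- list(
    burn_in = attr(traj, "burn_in"), roles = attr(traj, "roles"),
    alpha = attr(traj, "alpha"), z = attr(traj, "z"),
    topology = attr(traj, "topology"),
    weight_scheme = attr(traj, "weight_scheme"),
    seed = attr(traj, "seed"), sample_dt = attr(traj, "sample_dt")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname serpens-io
#' @export
read_trajectory <- function(path) {
  traj <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(traj,
    class = c("coupled_trajectory", class(traj)),
    burn_in = meta$burn_in, roles = meta$roles, alpha = meta$alpha,
    z = meta$z, topology = meta$topology,
    weight_scheme = meta$weight_scheme, seed = meta$seed,
    sample_dt = meta$sample_dt
  )
}

#' @rdname serpens-io
#' @param inet An `info_network`.
#' @export
write_info_network <- function(inet, path) {
  readr::write_csv(
    tibble::as_tibble(inet$te_matrix, .name_repair = "minimal"),
    paste0(path, ".te.csv")
  )
  if (!is.null(inet$mi_matrix)) {
    readr::write_csv(
      tibble::as_tibble(inet$mi_matrix, .name_repair = "minimal"),
      paste0(path, ".mi.csv")
    )
  }
  jsonlite::write_json(
    list(
      nodes = inet$nodes, roles = inet$roles,
      pattern_label = inet$pattern_label, duration = inet$duration,
      n_samples = inet$n_samples, k_neighbors = inet$k_neighbors
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
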