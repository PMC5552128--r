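#' Experiment configuration
#'
#' Bundles every knob of one experimental condition: network topology and
#' weighting, oscillator parameters (tonic input `z`, sensor ratio `alpha`),
#' body, run length, and the behavior/information-flow analysis parameters.
#' The study's standard grids are `alpha` in
#' `c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)` and `z` in
#' `c(0.4, 0.45, 0.5, 0.55)`; the reference run length is 2000 s with the
#' first 50 s excluded from analysis.
#'
#' @param topology,weights,p Network condition (see
#'   [build_wired_network()]).
#' @param n_nodes,n_interface Network size.
#' @param alpha,z Sensor ratio and tonic input.
#' @param duration,burn_in Run length and analysis exclusion (s).
#' @param window,shift,k_nn,eps_db,min_pts Behavior-analysis parameters
#'   (see [analyze_behavior()]).
#' @param infonet Also estimate per-pattern information networks (slower).
#' @param info_max_nodes,info_max_samples,info_min_samples Information
#'   network estimation caps (see [estimate_info_network()]).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(topology = "ws", weights = "random", p = 0.05,
                              n_nodes = 200, n_interface = 26,
                              alpha = 0.3, z = 0.4,
                              duration = 2000, burn_in = 50,
                              window = 10, shift = 0.5, k_nn = 350,
                              eps_db = 0.16, min_pts = 10,
                              infonet = FALSE, info_max_nodes = 40,
                              info_max_samples = 800,
                              info_min_samples = 400) {
  structure(
    list(
      topology = topology, weights = weights, p = p,
      n_nodes = n_nodes, n_interface = n_interface,
      alpha = alpha, z = z, duration = duration, burn_in = burn_in,
      window = window, shift = shift, k_nn = k_nn,
      eps_db = eps_db, min_pts = min_pts,
      infonet = infonet, info_max_nodes = info_max_nodes,
      info_max_samples = info_max_samples,
      info_min_samples = info_min_samples
    ),
    class = "experiment_config"
  )
}

#' Run one configured experiment end to end
#'
#' Builds the wired network, runs the closed-loop simulation, applies the
#' behavior pipeline and (optionally) estimates per-pattern information
#' networks.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed; all randomness (network, initial state, node
#'   subsampling) derives from it.
#' @param threshold Optional fixed stability threshold (s).
#' @return List with `behavior` (a `window_labeling`), `net_summary`,
#'   `patterns` (per-pattern tibble incl. information-network measures when
#'   requested), and `episodes`.
#' @export
run_experiment <- function(config, seed = 1, threshold = NULL) {
  net <- build_wired_network(
    topology = config$topology, weights = config$weights,
    n = config$n_nodes, n_interface = config$n_interface, p = config$p,
    seed = derive_seed(seed, 1)
  )
  p <- bvp_params(z = config$z, alpha = config$alpha)
  traj <- run_coupled_simulation(net, p,
    duration = config$duration,
    burn_in = config$burn_in, seed = derive_seed(seed, 2)
  )
  # adapt neighbor count to short runs: keep roughly the reference
  # neighbors-to-windows ratio (350 of ~3900)
  n_windows <- floor(
    (config$duration - config$burn_in - config$window) / config$shift
  ) + 1
  k_nn <- min(config$k_nn, max(10L, round(0.09 * n_windows)))
  beh <- analyze_behavior(traj,
    window = config$window, shift = config$shift,
    k_nn = k_nn, eps_db = config$eps_db, min_pts = config$min_pts,
    threshold = threshold
  )
  pat <- beh$patterns |>
    dplyr::filter(.data$label != 0L) |>
    dplyr::mutate(alpha = config$alpha, z = config$z, seed = seed)
  if (config$infonet && nrow(pat) > 0) {
    inets <- purrr::map(pat$label, function(lb) {
      tryCatch(
        estimate_info_network(traj, beh, lb,
          min_samples = config$info_min_samples,
          max_samples = config$info_max_samples,
          max_nodes = config$info_max_nodes,
          seed = derive_seed(seed, 3, lb)
        ),
        serpens_short_segment = function(e) NULL
      )
    })
    keep <- !vapply(inets, is.null, TRUE)
    if (any(keep)) {
      stats_tbl <- purrr::map(inets[keep], glance) |> purrr::list_rbind()
      pat <- dplyr::left_join(
        pat,
        dplyr::rename(stats_tbl, label = "pattern_label"),
        by = "label"
      )
    }
  }
  list(
    behavior = beh,
    patterns = pat,
    episodes = beh$episodes,
    net_summary = glance(net),
    seed = seed
  )
}

#' Run a grid of conditions with repeats
#'
#' Enumerates the cross-product of the supplied `alpha` and `z` values, runs
#' `n_repeats` seeded simulations per condition, and aggregates the behavior
#' summaries (and per-pattern information-network records when the base
#' config requests them).
#'
#' @param config Base [experiment_config()].
#' @param alphas,zs Condition grids.
#' @param n_repeats Seeded repeats per condition.
#' @param base_seed Base seed; per-run seeds derive deterministically.
#' @param pooled_threshold Pool all episode durations of the batch and use
#'   one Otsu stability threshold for every run (matching a batch-level
#'   classification); otherwise each run uses its own threshold.
#' @return An `experiment_summary`: list with `runs` (per-run tibble),
#'   `conditions` (per-condition means/sds), `patterns` (per-pattern
#'   records), `threshold`.
#' @export
run_grid <- function(config = experiment_config(), alphas = c(0, 0.3, 0.7, 1),
                     zs = 0.4, n_repeats = 5, base_seed = 1,
                     pooled_threshold = TRUE) {
  grid <- tidyr::expand_grid(alpha = alphas, z = zs, repeat_id = seq_len(n_repeats))
  results <- purrr::pmap(grid, function(alpha, z, repeat_id) {
    cfg <- config
    cfg$alpha <- alpha
    cfg$z <- z
    run_experiment(cfg, seed = derive_seed(base_seed, which(alphas == alpha),
                                           which(zs == z), repeat_id))
  })
  threshold <- NA_real_
  if (pooled_threshold) {
    all_dur <- purrr::map(results, ~ .x$episodes$duration) |> unlist()
    threshold <- tryCatch(otsu_threshold(all_dur),
      serpens_degenerate = function(e) NA_real_
    )
    if (!is.na(threshold)) {
      results <- purrr::map(results, function(r) {
        cls <- classify_patterns(r$episodes, threshold)
        r$patterns <- r$patterns |>
          dplyr::select(-dplyr::any_of("stable")) |>
          dplyr::left_join(
            dplyr::select(cls$patterns, "label", "stable"),
            by = "label"
          )
        r$summary_cls <- cls$summary
        r
      })
    }
  }
  runs <- purrr::map2(results, seq_len(nrow(grid)), function(r, i) {
    s <- r$summary_cls %||% r$behavior$summary
    dplyr::bind_cols(grid[i, ], s)
  }) |> purrr::list_rbind()
  conditions <- runs |>
    dplyr::group_by(.data$alpha, .data$z) |>
    dplyr::summarise(
      mean_patterns = mean(.data$n_patterns),
      sd_patterns = sd(.data$n_patterns),
      mean_stable = mean(.data$n_stable),
      sd_stable = sd(.data$n_stable),
      mean_max_duration = mean(.data$max_duration),
      sd_max_duration = sd(.data$max_duration),
      .groups = "drop"
    )
  patterns <- purrr::map(results, "patterns") |> purrr::list_rbind()
  structure(
    list(
      runs = runs, conditions = conditions, patterns = patterns,
      threshold = threshold,
      manifest = list(
        config = config, alphas = alphas, zs = zs,
        n_repeats = n_repeats, base_seed = base_seed
      )
    ),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf(
    "<experiment_summary> %d runs over %d condition(s); pooled threshold %.1f s\n",
    nrow(x$runs), nrow(x$conditions), x$threshold
  ))
  print(x$conditions)
  invisible(x)
}

#' Correlate information-network structure with pattern duration
#'
#' Pearson correlation of movement-pattern episode duration against the
#' information-network clustering coefficient, average shortest path, and
#' hidden-to-interface transfer entropy, across pattern instances.
#'
#' @param patterns Per-pattern records (the `patterns` element of an
#'   [run_grid()] result with `infonet = TRUE`, or any tibble with columns
#'   `duration`/`max_duration` and the measure columns).
#' @param duration_col Column holding the pattern duration.
#' @return A tibble: `measure`, `r`, `n`.
#' @export
correlate_structure_duration <- function(patterns,
                                         duration_col = "duration") {
  measures <- intersect(
    c("avg_clustering", "avg_shortest_path", "te_hidden_to_interface",
      "te_interface_to_hidden"),
    names(patterns)
  )
  if (nrow(patterns) < 3) stop_invalid("need at least 3 pattern instances")
  dur <- patterns[[duration_col]]
  purrr::map(measures, function(m) {
    v <- patterns[[m]]
    ok <- is.finite(v) & is.finite(dur)
    r <- if (sum(ok) >= 3 && sd(v[ok]) > 0 && sd(dur[ok]) > 0) {
      cor(dur[ok], v[ok])
    } else {
      NA_real_
    }
    tibble::tibble(measure = m, r = r, n = sum(ok))
  }) |> purrr::list_rbind()
}
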