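#' Windowed joint-angle correlation features
#'
#' Slides a window of length `window` seconds along the joint-angle series in
#' steps of `shift` seconds and, in each window, computes the Pearson
#' correlation of every joint pair. With `k` joints this gives a
#' `k*(k-1)/2`-dimensional feature vector per window (91 dimensions for the
#' default 14-joint body); repetitive movement patterns map to recurring
#' feature vectors. A joint with zero variance inside a window yields
#' correlation 0 there (flagged via the `n_degenerate` attribute).
#'
#' @param traj A trajectory tibble (burn-in is dropped using its `burn_in`
#'   attribute) or a numeric matrix of joint angles (samples by joints) with
#'   sampling period `sample_dt`.
#' @param window Window length (s).
#' @param shift Window shift (s).
#' @param sample_dt Sampling period (s); taken from the trajectory attribute
#'   when `traj` is a trajectory.
#' @return A `feature_matrix`: list with `R` (windows by pairs matrix),
#'   `start_times`, `window`, `shift`, `n_joints`.
#' @export
windowed_correlation_features <- function(traj, window = 10, shift = 0.5,
                                          sample_dt = NULL) {
  if (is.matrix(traj)) {
    theta <- traj
    t0 <- 0
    if (is.null(sample_dt)) stop_invalid("sample_dt required for matrix input")
  } else {
    sample_dt <- sample_dt %||% attr(traj, "sample_dt") %||% 0.1
    theta <- trajectory_matrix(traj, "theta", drop_burn_in = TRUE)
    t0 <- attr(theta, "time")[1]
  }
  n <- nrow(theta)
  k <- ncol(theta)
  w_n <- max(2L, round(window / sample_dt))
  s_n <- max(1L, round(shift / sample_dt))
  if (n < w_n) stop_invalid("series shorter than one window")
  starts <- seq(1L, n - w_n + 1L, by = s_n)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2]) # row-major pair order (1,2),(1,3),...
  pairs <- pairs[ord, , drop = FALSE]
  n_degenerate <- 0L
  R <- matrix(0, length(starts), nrow(pairs))
  for (wi in seq_along(starts)) {
    sub <- theta[starts[wi]:(starts[wi] + w_n - 1L), , drop = FALSE]
    cm <- suppressWarnings(cor(sub))
    vals <- cm[pairs]
    bad <- !is.finite(vals)
    if (any(bad)) {
      n_degenerate <- n_degenerate + sum(bad)
      vals[bad] <- 0
    }
    R[wi, ] <- vals
  }
  structure(
    list(
      R = R,
      start_times = t0 + (starts - 1L) * sample_dt,
      window = window, shift = shift, n_joints = k,
      n_degenerate = n_degenerate
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d windows x %d joint-pair correlations (window %gs, shift %gs)\n",
    nrow(x$R), ncol(x$R), x$window, x$shift
  ))
  invisible(x)
}

#' Laplacian-eigenmap embedding of feature vectors
#'
#' Builds a symmetrized k-nearest-neighbor graph (binary weights, Euclidean
#' metric) over the feature vectors and embeds them with the eigenvectors of
#' the normalized graph Laplacian, keeping the `out_dim` non-trivial
#' eigenvectors with smallest eigenvalues. A disconnected neighbor graph is
#' repaired by adding the single nearest cross-component link (repeated as
#' needed) before embedding. Deterministic up to eigenvector sign, which is
#' fixed by making the first nonzero coordinate positive. Coordinates are
#' reported on a fixed scale (see `scale_rms`), so a fixed clustering
#' radius has the same meaning across runs of different length and
#' sampling.
#'
#' @param features A `feature_matrix` or a numeric matrix (rows = points).
#' @param k_nn Number of nearest neighbors (capped at `n - 1`).
#' @param out_dim Embedding dimension.
#' @param scale_rms Geometric-mean root-mean-square of the embedding
#'   coordinates (default 3.2). This fixes the resolution convention: with
#'   the default, the standard density-clustering radius 0.16 corresponds
#'   to about 1/20 of the coordinate spread, the regime in which dwell
#'   regions separate from transition paths.
#' @param t_diff Diffusion time: coordinate `d` is weighted by
#'   `lambda_d^t_diff` (eigenvalues of the normalized adjacency), which
#'   continuously suppresses localized low-eigenvalue modes relative to the
#'   cluster-separating near-1 modes (diffusion-map weighting).
#' @return Numeric matrix (points by `out_dim`).
#' @export
embed_laplacian_eigenmaps <- function(features, k_nn = 350, out_dim = 3,
                                      scale_rms = 3.2, t_diff = 14) {
  Fm <- if (inherits(features, "feature_matrix")) features$R else features
  n <- nrow(Fm)
  if (n <= out_dim + 1) stop_invalid("too few points to embed")
  k_nn <- min(k_nn, n - 1L)
  D <- as.matrix(stats::dist(Fm))
  # kNN adjacency (ties at the k-th distance all included, so duplicate
  # points are treated symmetrically), symmetrized by OR
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    thr <- sort(d)[k_nn]
    A[i, d <= thr] <- TRUE
  }
  A <- A | t(A)
  diag(A) <- FALSE
  # repair disconnected components with nearest cross-links
  comp <- connected_components(A)
  n_repair <- 0L
  while (max(comp) > 1L) {
    in1 <- comp == 1L
    Dx <- D[in1, !in1, drop = FALSE]
    hit <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    i <- which(in1)[hit[1]]
    j <- which(!in1)[hit[2]]
    A[i, j] <- A[j, i] <- TRUE
    n_repair <- n_repair + 1L
    comp <- connected_components(A)
  }
  if (n_repair > 0) {
    inform(sprintf("neighbor graph disconnected: added %d cross-link(s)", n_repair))
  }
  Asp <- Matrix::Matrix(A * 1, sparse = TRUE)
  deg <- Matrix::rowSums(Asp)
  dis <- 1 / sqrt(deg)
  M <- Matrix::Diagonal(x = dis) %*% Asp %*% Matrix::Diagonal(x = dis)
  nev <- out_dim + 1L
  eg <- top_eigenpairs(M, nev)
  emb <- dis * eg$vectors # generalized eigenvectors of L u = lambda D u
  lam <- eg$values[-1L]
  emb <- emb[, -1L, drop = FALSE] # drop the trivial constant eigenvector
  w <- pmax(lam, 0)^t_diff
  w <- w / max(w)
  for (d in seq_len(ncol(emb))) {
    v <- emb[, d]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
    rms <- sqrt(mean(v^2))
    if (rms > 0) v <- v / rms
    emb[, d] <- v * w[d]
  }
  # fixed resolution convention: geometric-mean coordinate RMS = scale_rms.
  # A feature cloud whose global spread is comparable to its local noise
  # floor (the median step between consecutive windows) carries no pattern
  # structure; compress it proportionally instead of inflating noise to
  # full scale, so a structureless run reports one pattern, not fragments.
  sub <- Fm[round(seq(1, n, length.out = min(n, 400))), , drop = FALSE]
  spread <- median(stats::dist(sub))
  noise_floor <- median(sqrt(rowSums((Fm[-1, , drop = FALSE] -
    Fm[-n, , drop = FALSE])^2)))
  ratio <- spread / max(noise_floor, 1e-12)
  structure_gain <- min(1, max(0, (ratio - 5) / 15))
  emb <- emb * structure_gain * scale_rms / prod(w)^(1 / length(w))
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  emb
}

# Largest-algebraic eigenpairs of a symmetric (sparse) matrix, robust to
# the occasional dsyevr failure on otherwise fine inputs.
top_eigenpairs <- function(M, nev) {
  n <- nrow(M)
  dense <- function() {
    eg <- eigen(as.matrix(M), symmetric = TRUE)
    list(
      values = eg$values[seq_len(nev)],
      vectors = eg$vectors[, seq_len(nev), drop = FALSE]
    )
  }
  arp <- function() {
    res <- igraph::arpack(
      function(v, extra) as.vector(M %*% v),
      sym = TRUE,
      options = list(
        n = n, nev = nev, ncv = min(n, max(20L, 4L * nev)),
        which = "LA", maxiter = 5000
      )
    )
    ord <- order(res$values, decreasing = TRUE)[seq_len(nev)]
    list(values = res$values[ord], vectors = res$vectors[, ord, drop = FALSE])
  }
  if (n < 300) {
    tryCatch(dense(), error = function(e) arp())
  } else {
    tryCatch(arp(), error = function(e) dense())
  }
}

connected_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Density-based clustering (DBSCAN) of embedded windows
#'
#' Standard DBSCAN with the Euclidean metric. Windows not assigned to any
#' dense cluster get the reserved noise label `0` and are reported as the
#' unstable movement pattern.
#'
#' @param embedding Numeric matrix (points by dims).
#' @param eps Neighborhood radius (default 0.16).
#' @param min_pts Minimum neighborhood size (including the point itself) for
#'   a core point (default 10).
#' @return Integer label vector; `0` marks noise.
#' @export
cluster_dbscan <- function(embedding, eps = 0.16, min_pts = 10) {
  n <- nrow(embedding)
  adj <- as.matrix(stats::dist(embedding)) <= eps # includes self on diagonal
  core <- rowSums(adj) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (s in which(core)) {
    if (labels[s] != 0L) next
    cl <- cl + 1L
    labels[s] <- cl
    frontier <- s
    while (length(frontier) > 0) {
      reach <- colSums(adj[frontier, , drop = FALSE]) > 0 & labels == 0L
      nb <- which(reach)
      labels[nb] <- cl # core points expand; border points are only claimed
      frontier <- nb[core[nb]]
    }
  }
  labels
}

#' Episodes of constant movement-pattern label
#'
#' Maximal runs of a constant label become episodes with duration
#' `run length * shift` seconds.
#'
#' @param labels Time-ordered integer label vector (0 = noise).
#' @param shift Window shift (s), the time between consecutive labels.
#' @param start_times Optional window start times.
#' @return A tibble: `label`, `start`, `end` (window indices), `start_time`,
#'   `duration` (s).
#' @export
episodes_and_durations <- function(labels, shift, start_times = NULL) {
  n <- length(labels)
  if (n == 0) {
    return(tibble::tibble(
      label = integer(), start = integer(), end = integer(),
      start_time = numeric(), duration = numeric()
    ))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  start_times <- start_times %||% ((seq_len(n) - 1) * shift)
  tibble::tibble(
    label = r$values,
    start = starts, end = ends,
    start_time = start_times[starts],
    duration = r$lengths * shift
  )
}

#' Otsu threshold of a sample
#'
#' Histogram-based threshold maximizing the between-class variance over 256
#' bins spanning the observed range; used both for episode-duration
#' stability classification and for binarizing mutual-information matrices.
#'
#' @param x Numeric values (at least two distinct).
#' @param n_bins Number of histogram bins.
#' @return The threshold (same units as `x`).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    abort("Otsu threshold undefined: fewer than two distinct values",
      class = "serpens_degenerate"
    )
  }
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # the maximum is a plateau when the histogram has an empty gap; take the
  # plateau midpoint (the conventional choice for symmetric bimodal data)
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(edges[best + 1L])
}

#' Stability classification of movement patterns
#'
#' A pattern is *stable* when its longest episode lasts at least the
#' threshold; the noise label is never stable.
#'
#' @param episodes Episode tibble from [episodes_and_durations()].
#' @param threshold Duration threshold (s), typically from
#'   [otsu_threshold()] on the episode durations.
#' @return List with `patterns` (tibble: `label`, `n_episodes`,
#'   `total_duration`, `max_duration`, `stable`) and `summary` (tibble:
#'   `n_patterns`, `n_stable`, `max_duration`).
#' @export
classify_patterns <- function(episodes, threshold) {
  pat <- episodes |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_episodes = dplyr::n(),
      total_duration = sum(.data$duration),
      max_duration = max(.data$duration),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      stable = .data$label != 0L & .data$max_duration >= threshold
    )
  real <- dplyr::filter(pat, .data$label != 0L)
  list(
    patterns = pat,
    summary = tibble::tibble(
      n_patterns = nrow(real),
      n_stable = sum(real$stable),
      max_duration = if (nrow(real) > 0) max(real$max_duration) else 0
    )
  )
}

#' Full behavior-analysis chain for one trajectory
#'
#' Windowed joint-angle correlations, Laplacian-eigenmap embedding, DBSCAN
#' clustering into movement patterns, episode extraction, and Otsu
#' stable/unstable classification (the Otsu threshold can be supplied, e.g.
#' when pooled over a whole experiment batch).
#'
#' @param traj A trajectory tibble (or joint-angle matrix plus `sample_dt`).
#' @param window,shift Feature window length and shift (s).
#' @param k_nn Eigenmap neighbors.
#' @param eps_db,min_pts DBSCAN parameters.
#' @param out_dim Embedding dimension.
#' @param threshold Optional fixed stability threshold (s); default: Otsu on
#'   this run's episode durations.
#' @param sample_dt Sampling period for matrix input.
#' @return A `window_labeling`: list with `windows` (tibble: `start_time`,
#'   `label`, `stable`), `embedding`, `episodes`, `patterns`, `summary`,
#'   `threshold` and the analysis parameters.
#' @export
analyze_behavior <- function(traj, window = 10, shift = 0.5, k_nn = 350,
                             eps_db = 0.16, min_pts = 10, out_dim = 3,
                             threshold = NULL, sample_dt = NULL) {
  feats <- windowed_correlation_features(traj, window, shift, sample_dt)
  emb <- embed_laplacian_eigenmaps(feats, k_nn = k_nn, out_dim = out_dim)
  labels <- cluster_dbscan(emb, eps = eps_db, min_pts = min_pts)
  eps_list <- episodes_and_durations(labels, feats$shift, feats$start_times)
  thr <- threshold
  if (is.null(thr)) {
    thr <- tryCatch(otsu_threshold(eps_list$duration),
      serpens_degenerate = function(e) {
        warn("degenerate episode durations; all patterns classified stable")
        0
      }
    )
  }
  cls <- classify_patterns(eps_list, thr)
  stable_labels <- cls$patterns$label[cls$patterns$stable]
  structure(
    list(
      windows = tibble::tibble(
        start_time = feats$start_times,
        label = labels,
        stable = labels %in% stable_labels
      ),
      embedding = emb,
      episodes = eps_list,
      patterns = cls$patterns,
      summary = cls$summary,
      threshold = thr,
      params = list(
        window = window, shift = shift, k_nn = k_nn,
        eps_db = eps_db, min_pts = min_pts, out_dim = out_dim
      )
    ),
    class = "window_labeling"
  )
}

#' @export
print.window_labeling <- function(x, ...) {
  cat(sprintf(
    "<window_labeling> %d windows: %d pattern(s), %d stable (threshold %.1f s), max episode %.1f s\n",
    nrow(x$windows), x$summary$n_patterns, x$summary$n_stable,
    x$threshold, x$summary$max_duration
  ))
  invisible(x)
}

#' @rdname analyze_behavior
#' @param x A `window_labeling`.
#' @param ... Unused.
#' @export
tidy.window_labeling <- function(x, ...) x$windows

#' @rdname analyze_behavior
#' @export
glance.window_labeling <- function(x, ...) {
  dplyr::bind_cols(x$summary, tibble::tibble(threshold = x$threshold))
}
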