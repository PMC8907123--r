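#' Simulate complete spatial randomness (CSR) in a window
#'
#' Places exactly `n` points i.i.d. uniform over the window by rejection
#' sampling from its bounding box. This is the null model against which
#' clustering of gold particles is judged, and the generator used for the
#' Monte-Carlo null ([csr_null()]).
#'
#' @param window an [az_window()].
#' @param n number of points (>= 0).
#' @param seed integer seed; the same seed reproduces the same pattern. The
#'   caller's RNG stream is left untouched.
#' @param face,label passed to [point_pattern()].
#' @return a [point_pattern()] with `n` points.
#' @export
simulate_csr <- function(window, n, seed = NULL,
                         face = "P_face", label = "simulated") {
  stopifnot(inherits(window, "az_window"), n >= 0)
  with_seed(seed, {
    xy <- runif_in_window(n, window)
    point_pattern(xy[, 1], xy[, 2], window, face = face, label = label,
                  check = FALSE)
  })
}

# rejection sampler: n uniform points in the window; axis-aligned
# rectangles are sampled directly (no rejection)
runif_in_window <- function(n, window) {
  bb <- window_bbox(window)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  if (is_axis_rect(window))
    return(cbind(stats::runif(n, bb$xmin, bb$xmax),
                 stats::runif(n, bb$ymin, bb$ymax)))
  out <- matrix(numeric(0), ncol = 2)
  # acceptance rate = area(window)/area(bbox); draw in batches
  frac <- max(polygon_area(window) /
                ((bb$xmax - bb$xmin) * (bb$ymax - bb$ymin)), 0.05)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac) + 10L
    x <- stats::runif(m, bb$xmin, bb$xmax)
    y <- stats::runif(m, bb$ymin, bb$ymax)
    keep <- point_in_polygon(x, y, window)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# n Gaussian offspring of a parent, resampled until inside the window
# (i.e. the offspring distribution is conditioned on the window, so target
# counts are met exactly)
gauss_in_window <- function(n, centre, sd, window, max_retries = 10000L) {
  out <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < n) {
    m <- (n - nrow(out)) * 2L + 5L
    x <- stats::rnorm(m, centre[1], sd)
    y <- stats::rnorm(m, centre[2], sd)
    keep <- point_in_polygon(x, y, window)
    out <- rbind(out, cbind(x[keep], y[keep]))
    tries <- tries + 1L
    if (tries > max_retries)
      stop("could not place points inside the window (spread too large?)",
           call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a clustered (parent-offspring) point pattern
#'
#' A Thomas-style cluster process conditioned on the window: `n_parents`
#' parent centres are CSR in the window; each parent receives
#' Poisson(`offspring_mean`) offspring displaced by an isotropic Gaussian
#' with standard deviation `spread_sd`, resampled until inside the window.
#' The ground-truth parent assignment is retained as attribute `"parent"`.
#'
#' @param window an [az_window()].
#' @param n_parents number of cluster centres (>= 1).
#' @param offspring_mean mean points per cluster.
#' @param spread_sd cluster spread (nm), > 0.
#' @param seed integer seed.
#' @param min_separation optional minimum distance (nm) between parent
#'   centres, enforced by resampling (bounded retries, then a warning).
#' @return a [point_pattern()]; attribute `"parent"` holds the per-point
#'   parent index, attribute `"parents"` the parent coordinates.
#' @export
simulate_clustered <- function(window, n_parents, offspring_mean, spread_sd,
                               seed = NULL, min_separation = 0) {
  stopifnot(inherits(window, "az_window"), n_parents >= 1, spread_sd > 0)
  with_seed(seed, {
    parents <- runif_in_window(n_parents, window)
    if (min_separation > 0 && n_parents > 1) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        d <- stats::dist(parents)
        if (min(d) >= min_separation) { ok <- TRUE; break }
        parents <- runif_in_window(n_parents, window)
      }
      if (!ok)
        warning("window too small for the requested parent separation; ",
                "using the last draw", call. = FALSE)
    }
    counts <- stats::rpois(n_parents, offspring_mean)
    pts <- lapply(seq_len(n_parents), function(i) {
      if (counts[i] == 0) return(NULL)
      cbind(gauss_in_window(counts[i], parents[i, ], spread_sd, window),
            parent = i)
    })
    pts <- do.call(rbind, pts)
    if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
    p <- point_pattern(pts[, 1], pts[, 2], window, label = "simulated",
                       check = FALSE)
    attr(p, "parent") <- as.integer(pts[, 3])
    attr(p, "parents") <- parents
    p
  })
}

#' Simulate channel/vesicle topography scenes
#'
#' Generates ground-truth calcium-channel and docked-vesicle coordinates in
#' an active-zone window under one of four topography models:
#'
#' * `"random"` — channels and vesicle centres independently CSR.
#' * `"perimeter_release"` — channels form clusters; each vesicle sits at
#'   the perimeter of a channel cluster (convex hull dilated by
#'   `offset_nm`); several vesicles may share a cluster.
#' * `"one_to_one"` — clustered channels with at most one vesicle docked per
#'   cluster, each vesicle assigned to a distinct cluster.
#' * `"exclusion_zone"` — unclustered (CSR) channels conditioned on lying at
#'   least `exclusion_radius_nm` from every vesicle centre.
#'
#' @param window an [az_window()].
#' @param model one of `"random"`, `"perimeter_release"`, `"one_to_one"`,
#'   `"exclusion_zone"`.
#' @param params named list of model parameters; unset entries take the
#'   defaults of [topography_defaults()]. Relevant entries: `n_channels`,
#'   `n_vesicles`, `vesicle_radius_nm`, `n_clusters`,
#'   `channels_per_cluster`, `cluster_spread_nm`, `offset_nm` (perimeter
#'   dilation, default 10 nm), `exclusion_radius_nm` (default 50 nm),
#'   `max_retries`.
#' @param seed integer seed.
#' @return an object of class `topography_scene` with components `channels`
#'   (matrix), `vesicles` (matrix with columns x, y, radius), `window`,
#'   `model`, `params`, and `channel_cluster` (ground-truth cluster index,
#'   `NA` for unclustered models).
#' @export
simulate_topography <- function(window,
                                model = c("random", "perimeter_release",
                                          "one_to_one", "exclusion_zone"),
                                params = list(), seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(window, "az_window"))
  p <- utils::modifyList(topography_defaults(), params)
  # the one-to-one default cannot exceed the cluster count; an explicit
  # n_vesicles above it is still an error (checked in the generator)
  if (model == "one_to_one" && !("n_vesicles" %in% names(params)))
    p$n_vesicles <- min(p$n_vesicles, p$n_clusters)
  with_seed(seed, {
    scene <- switch(model,
      random = .topo_random(window, p),
      perimeter_release = .topo_perimeter(window, p, one_to_one = FALSE),
      one_to_one = .topo_perimeter(window, p, one_to_one = TRUE),
      exclusion_zone = .topo_exclusion(window, p))
    scene$window <- window
    scene$model <- model
    scene$params <- p
    class(scene) <- "topography_scene"
    scene
  })
}

#' Default topography-scene parameters
#'
#' Scaled to a typical complete active zone (~0.1 um^2): about two dozen
#' channels organised in ~3 clusters of ~10 channels, and a handful of
#' docked vesicles of ~20 nm radius. The exclusion-zone radius defaults to
#' 50 nm and the perimeter docking offset to 10 nm.
#'
#' @return named list of defaults consumed by [simulate_topography()].
#' @export
topography_defaults <- function() {
  list(n_channels = 30L, n_vesicles = 5L, vesicle_radius_nm = 20,
       n_clusters = 3L, channels_per_cluster = 10,
       cluster_spread_nm = 20, offset_nm = 10,
       exclusion_radius_nm = 50, max_retries = 10000L)
}

.topo_random <- function(window, p) {
  list(channels = runif_in_window(p$n_channels, window),
       vesicles = cbind(runif_in_window(p$n_vesicles, window),
                        radius = rep(p$vesicle_radius_nm, p$n_vesicles)),
       channel_cluster = rep(NA_integer_, p$n_channels))
}

.topo_perimeter <- function(window, p, one_to_one) {
  k <- p$n_clusters
  nv <- p$n_vesicles
  if (one_to_one && nv > k)
    stop("one_to_one model requires n_vesicles <= n_clusters", call. = FALSE)
  centres <- runif_in_window(k, window)
  counts <- pmax(1L, stats::rpois(k, p$channels_per_cluster))
  ch <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(gauss_in_window(counts[i], centres[i, ], p$cluster_spread_nm,
                          window, p$max_retries), cluster = i)))
  assign_cluster <- if (one_to_one) sample(k, nv) else
    sample(k, nv, replace = TRUE)
  ves <- t(vapply(assign_cluster, function(i) {
    .perimeter_point(ch[ch[, 3] == i, 1:2, drop = FALSE], p$offset_nm,
                     window, p$max_retries)
  }, numeric(2)))
  if (nv == 0) ves <- matrix(numeric(0), ncol = 2)
  list(channels = ch[, 1:2, drop = FALSE],
       vesicles = cbind(ves, radius = rep(p$vesicle_radius_nm, nv)),
       channel_cluster = as.integer(ch[, 3]),
       vesicle_cluster = assign_cluster)
}

# random point on the convex hull of a cluster dilated outward by `offset`;
# retried until inside the window
.perimeter_point <- function(pts, offset, window, max_retries) {
  ctr <- colMeans(pts)
  for (try in seq_len(max_retries)) {
    th <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    # support of the cluster in direction u, measured from its centre
    r <- if (nrow(pts) >= 2)
      max((pts[, 1] - ctr[1]) * u[1] + (pts[, 2] - ctr[2]) * u[2]) else 0
    cand <- ctr + (r + offset) * u
    if (point_in_polygon(cand[1], cand[2], window)) return(cand)
  }
  stop("could not place a vesicle at the cluster perimeter inside the window",
       call. = FALSE)
}

.topo_exclusion <- function(window, p) {
  ves <- runif_in_window(p$n_vesicles, window)
  R <- p$exclusion_radius_nm
  out <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < p$n_channels) {
    cand <- runif_in_window(p$n_channels - nrow(out), window)
    if (nrow(ves) > 0) {
      d2min <- apply(cand, 1, function(q)
        min((ves[, 1] - q[1])^2 + (ves[, 2] - q[2])^2))
      cand <- cand[d2min >= R^2, , drop = FALSE]
    }
    out <- rbind(out, cand)
    tries <- tries + 1L
    if (tries > p$max_retries)
      stop("exclusion-zone placement infeasible: window saturated by vesicle zones",
           call. = FALSE)
  }
  list(channels = out[seq_len(p$n_channels), , drop = FALSE],
       vesicles = cbind(ves, radius = rep(p$vesicle_radius_nm, p$n_vesicles)),
       channel_cluster = rep(NA_integer_, p$n_channels))
}

#' @export
print.topography_scene <- function(x, ...) {
  cat(sprintf("topography_scene '%s': %d channels, %d vesicles in window '%s'\n",
              x$model, nrow(x$channels), nrow(x$vesicles),
              x$window$region_id))
  invisible(x)
}

#' Virtual-labeling configuration
#'
#' Describes how ground-truth channel positions turn into observed gold
#' particles: each channel is detected with probability `efficiency`
#' (independent Bernoulli thinning), detected particles are displaced by an
#' isotropic Gaussian of sd `jitter_sd` nm (modelling the combined
#' antibody + gold linkage error; resampled to stay in the window),
#' Poisson background at `background_rate` particles/um^2 is added, and an
#' optional `aggregation` component replaces some background singles with
#' antibody-aggregation clumps (the artefact mode seen with poorly behaved
#' secondary antibodies).
#'
#' @param efficiency detection probability in \[0, 1\].
#' @param jitter_sd localisation jitter sd in nm (>= 0).
#' @param background_rate non-specific labeling rate, particles/um^2 (>= 0).
#' @param aggregation `NULL`, or a list with `clump_count`, `clump_size`,
#'   `clump_spread` (nm).
#' @return an object of class `labeling_config`.
#' @export
labeling_config <- function(efficiency = 1, jitter_sd = 0,
                            background_rate = 0, aggregation = NULL) {
  stopifnot(efficiency >= 0, efficiency <= 1, jitter_sd >= 0,
            background_rate >= 0)
  if (!is.null(aggregation))
    stopifnot(all(c("clump_count", "clump_size", "clump_spread") %in%
                    names(aggregation)))
  structure(list(efficiency = efficiency, jitter_sd = jitter_sd,
                 background_rate = background_rate,
                 aggregation = aggregation),
            class = "labeling_config")
}

#' Apply the virtual-labeling model to ground truth
#'
#' @param truth a `topography_scene` (its channels are labelled) or a
#'   [point_pattern()].
#' @param config a [labeling_config()].
#' @param seed integer seed.
#' @param label marker name for the output pattern.
#' @return a [point_pattern()] of observed particles; attribute `"is_background"`
#'   flags the background (non-specific) points.
#' @export
virtual_labeling <- function(truth, config = labeling_config(), seed = NULL,
                             label = "virtual") {
  stopifnot(inherits(config, "labeling_config"))
  if (inherits(truth, "topography_scene")) {
    xy <- truth$channels
    window <- truth$window
  } else if (inherits(truth, "point_pattern")) {
    xy <- coords(truth)
    window <- truth$window
  } else stop("truth must be a topography_scene or point_pattern",
              call. = FALSE)
  with_seed(seed, {
    n <- nrow(xy)
    keep <- if (n > 0) stats::runif(n) < config$efficiency else logical(0)
    obs <- xy[keep, , drop = FALSE]
    if (config$jitter_sd > 0 && nrow(obs) > 0) {
      obs <- t(apply(obs, 1, function(q)
        gauss_in_window(1L, q, config$jitter_sd, window)[1, ]))
    }
    n_bg <- stats::rpois(1, config$background_rate *
                           polygon_area(window) / NM2_PER_UM2)
    bg <- matrix(numeric(0), ncol = 2)
    agg <- config$aggregation
    if (!is.null(agg) && agg$clump_count > 0) {
      n_clump <- min(agg$clump_count, n_bg)
      n_bg <- n_bg - n_clump
      ctrs <- runif_in_window(n_clump, window)
      bg <- do.call(rbind, lapply(seq_len(n_clump), function(i)
        gauss_in_window(agg$clump_size, ctrs[i, ], agg$clump_spread, window)))
      if (is.null(bg)) bg <- matrix(numeric(0), ncol = 2)
    }
    if (n_bg > 0) bg <- rbind(bg, runif_in_window(n_bg, window))
    all_xy <- rbind(obs, bg)
    p <- point_pattern(all_xy[, 1], all_xy[, 2], window, label = label,
                       check = FALSE)
    attr(p, "is_background") <- c(rep(FALSE, nrow(obs)), rep(TRUE, nrow(bg)))
    p
  })
}
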