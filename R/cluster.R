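#' Cluster-detection configuration
#'
#' Parameters for gold-particle cluster detection. The defaults follow the
#' standard SDS-FRL practice: DBSCAN with a minimum of 3 particles per
#' cluster and a neighbourhood radius (epsilon) resolved per AZ as
#' mean NND + 2 SD. The alternative `fixed_radius` method links particles
#' lying within a fixed radius (e.g. 100 nm) into connected components.
#'
#' @param method `"dbscan"` or `"fixed_radius"`.
#' @param min_points minimum particles per cluster (>= 1), default 3.
#' @param epsilon_rule `"nnd_mean_plus_2sd"` (per-pattern) or `"fixed"`.
#' @param epsilon_nm radius in nm used when `epsilon_rule = "fixed"`,
#'   default 100.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(method = c("dbscan", "fixed_radius"),
                           min_points = 3L,
                           epsilon_rule = c("nnd_mean_plus_2sd", "fixed"),
                           epsilon_nm = 100) {
  method <- match.arg(method)
  epsilon_rule <- match.arg(epsilon_rule)
  stopifnot(min_points >= 1)
  if (epsilon_rule == "fixed" && epsilon_nm <= 0)
    stop("epsilon_nm must be positive", call. = FALSE)
  structure(list(method = method, min_points = as.integer(min_points),
                 epsilon_rule = epsilon_rule, epsilon_nm = epsilon_nm),
            class = "cluster_config")
}

#' Resolve the DBSCAN epsilon for a pattern
#'
#' Under the `nnd_mean_plus_2sd` rule, epsilon = mean NND + 2 x SD of the
#' per-particle NNDs, computed per AZ (sample SD, n - 1 denominator). Under
#' the `fixed` rule the configured radius is returned unchanged. A pooled
#' epsilon for cross-AZ comparability can be obtained with
#' [pooled_epsilon()].
#'
#' @param pattern a [point_pattern()] (>= 2 points for the NND rule).
#' @param config a [cluster_config()].
#' @return epsilon in nm.
#' @export
resolve_epsilon <- function(pattern, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  if (config$epsilon_rule == "fixed") return(config$epsilon_nm)
  s <- mean_nnd(pattern)
  s$mean + 2 * s$sd
}

#' Pooled epsilon across the AZs of a dataset
#'
#' mean + 2 SD of the per-particle NNDs pooled over every AZ pattern with
#' >= 2 particles, for analyses that want one epsilon per dataset instead of
#' one per AZ.
#'
#' @param dataset a [replica_dataset()] or list of patterns.
#' @return epsilon in nm.
#' @export
pooled_epsilon <- function(dataset) {
  pats <- if (inherits(dataset, "replica_dataset"))
    patterns_by_class(dataset, "AZ") else dataset
  nnds <- unlist(lapply(Filter(function(p) npoints(p) >= 2, pats),
                        function(p) nnd_vector(coords(p))))
  if (length(nnds) < 2)
    stop("pooled_epsilon needs at least 2 pooled NND values", call. = FALSE)
  mean(nnds) + 2 * stats::sd(nnds)
}

#' Detect particle clusters in one pattern
#'
#' `dbscan_cluster()` implements standard DBSCAN semantics: a particle is a
#' core point when at least `min_points` particles (counting itself) lie
#' within epsilon; clusters are the connected components of core points
#' under epsilon-reachability, plus border points, which join the cluster of
#' their lowest-index core neighbour (deterministic tie-break); remaining
#' particles are noise (label -1). Cluster labels are renumbered by each
#' cluster's lowest member index, so labels are reproducible and
#' permutation-invariant up to renumbering.
#'
#' `fixed_radius_cluster()` links all particles within `epsilon_nm` into
#' connected components; components smaller than `min_points` become noise.
#' With `min_points = 1` this is exactly the components of the epsilon-ball
#' graph.
#'
#' `detect_clusters()` dispatches on `config$method`.
#'
#' @param pattern a [point_pattern()].
#' @param config a [cluster_config()].
#' @param epsilon optional explicit epsilon (nm), overriding the rule.
#' @return an object of class `cluster_result`: `labels` (per particle,
#'   -1 = noise), `n_clusters`, `particles_per_cluster`,
#'   `cluster_hull_area` (nm^2, 0 for degenerate hulls), `epsilon_used`,
#'   `method`, `region_id`.
#' @export
detect_clusters <- function(pattern, config = cluster_config(),
                            epsilon = NULL) {
  stopifnot(inherits(config, "cluster_config"))
  if (config$method == "dbscan") dbscan_cluster(pattern, config, epsilon)
  else fixed_radius_cluster(pattern, config, epsilon)
}

#' @rdname detect_clusters
#' @export
dbscan_cluster <- function(pattern, config = cluster_config(),
                           epsilon = NULL) {
  stopifnot(inherits(pattern, "point_pattern"),
            inherits(config, "cluster_config"))
  n <- npoints(pattern)
  if (n == 0)
    return(.cluster_result(integer(0), pattern, NA_real_, "dbscan"))
  if (n < config$min_points) {
    eps <- epsilon %||% if (n >= 2) resolve_epsilon(pattern, config) else NA_real_
    return(.cluster_result(rep(-1L, n), pattern, eps, "dbscan"))
  }
  eps <- epsilon %||% resolve_epsilon(pattern, config)
  D <- as.matrix(stats::dist(coords(pattern)))
  adj <- D <= eps  # includes self (diagonal TRUE)
  core <- rowSums(adj) >= config$min_points
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {           # index order fixes all tie-breaks
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(adj[j, ])
      for (k in nb) {
        if (labels[k] == -1L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  .cluster_result(.renumber(labels), pattern, eps, "dbscan")
}

#' @rdname detect_clusters
#' @export
fixed_radius_cluster <- function(pattern, config = cluster_config(
                                   method = "fixed_radius",
                                   epsilon_rule = "fixed"),
                                 epsilon = NULL) {
  stopifnot(inherits(pattern, "point_pattern"),
            inherits(config, "cluster_config"))
  n <- npoints(pattern)
  eps <- epsilon %||% if (config$epsilon_rule == "fixed") config$epsilon_nm
                      else resolve_epsilon(pattern, config)
  if (n == 0)
    return(.cluster_result(integer(0), pattern, eps, "fixed_radius"))
  D <- as.matrix(stats::dist(coords(pattern)))
  adj <- D <= eps
  # connected components by union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in which(adj[i, (i + 1L):n]) + i)
    { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  comp <- vapply(seq_len(n), find, 0L)
  labels <- match(comp, unique(comp))
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < config$min_points])] <- -1L
  .cluster_result(.renumber(labels), pattern, eps, "fixed_radius")
}

# renumber non-noise labels by lowest member index
.renumber <- function(labels) {
  ids <- unique(labels[labels != -1L])
  if (!length(ids)) return(labels)
  first <- vapply(ids, function(g) min(which(labels == g)), 0L)
  ids <- ids[order(first)]
  out <- labels
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

.cluster_result <- function(labels, pattern, eps, method) {
  ids <- sort(unique(labels[labels != -1L]))
  sizes <- vapply(ids, function(g) sum(labels == g), 0L)
  hulls <- vapply(ids, function(g)
    hull_area(coords(pattern)[labels == g, , drop = FALSE]), 0)
  structure(list(labels = labels,
                 n_clusters = length(ids),
                 particles_per_cluster = sizes,
                 cluster_hull_area = hulls,
                 epsilon_used = eps,
                 method = method,
                 region_id = pattern$window$region_id),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result (%s, eps = %.1f nm): %d cluster(s), %d noise of %d particles\n",
    x$method, x$epsilon_used, x$n_clusters, sum(x$labels == -1L),
    length(x$labels)))
  invisible(x)
}

#' Convex-hull area of a set of points
#'
#' Shoelace area of the convex hull; 0 for fewer than 3 points or collinear
#' sets (degenerate hulls are not an error).
#'
#' @param xy n x 2 coordinate matrix (nm).
#' @return area in nm^2.
#' @export
hull_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  abs(.shoelace_signed(xy[h, 1], xy[h, 2]))
}

#' Summarise cluster detections and scale particle counts to channels
#'
#' Pools one or many per-AZ [detect_clusters()] results and converts
#' particles per cluster into estimated channels per cluster by dividing by
#' the labeling efficiency (mean and SEM scale identically: with the
#' reference efficiency of 0.64, 6.8 +/- 0.3 particles per cluster becomes
#' 10.6 +/- 0.5 channels).
#'
#' @param results a `cluster_result` or list of them (one per AZ).
#' @param efficiency labeling efficiency in (0, 1].
#' @return a list with `per_cluster` (data frame: region_id, cluster,
#'   n_particles, hull_area_nm2, est_channels) and `summary` (data frame
#'   with n_az, clusters-per-AZ mean/SEM, particles-per-cluster mean/SEM,
#'   channels-per-cluster mean/SEM, n_clusters).
#' @export
cluster_summary <- function(results, efficiency = 1) {
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]", call. = FALSE)
  if (inherits(results, "cluster_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "cluster_result")))
  per <- do.call(rbind, lapply(results, function(r) {
    if (r$n_clusters == 0) return(NULL)
    data.frame(region_id = r$region_id,
               cluster = seq_len(r$n_clusters),
               n_particles = r$particles_per_cluster,
               hull_area_nm2 = r$cluster_hull_area,
               est_channels = r$particles_per_cluster / efficiency,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(region_id = character(0), cluster = integer(0),
                      n_particles = integer(0), hull_area_nm2 = numeric(0),
                      est_channels = numeric(0))
  ncl <- vapply(results, function(r) r$n_clusters, 0L)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  summ <- data.frame(
    n_az = length(results),
    clusters_per_az_mean = mean(ncl),
    clusters_per_az_sem = sem(ncl),
    n_clusters = sum(ncl),
    particles_per_cluster_mean = if (nrow(per)) mean(per$n_particles) else NA_real_,
    particles_per_cluster_sem = sem(per$n_particles),
    channels_per_cluster_mean = if (nrow(per)) mean(per$est_channels) else NA_real_,
    channels_per_cluster_sem = sem(per$est_channels),
    efficiency = efficiency)
  list(per_cluster = per, summary = summ)
}
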