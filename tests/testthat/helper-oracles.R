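# Independent brute-force oracles, deliberately written with different
# algorithms/code paths than the package implementations they check.

# winding-number point-in-polygon (package uses even-odd ray casting)
oracle_winding <- function(x, y, poly, tol = 1e-9) {
  px <- poly$x; py <- poly$y
  n <- length(px)
  vapply(seq_along(x), function(i) {
    # boundary check first
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      vx <- px[k2] - px[k]; vy <- py[k2] - py[k]
      L2 <- vx^2 + vy^2
      t <- if (L2 > 0) min(1, max(0, ((x[i] - px[k]) * vx + (y[i] - py[k]) * vy) / L2)) else 0
      if ((x[i] - (px[k] + t * vx))^2 + (y[i] - (py[k] + t * vy))^2 <= tol^2)
        return(TRUE)
    }
    wn <- 0
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      cross <- (px[k2] - px[k]) * (y[i] - py[k]) - (x[i] - px[k]) * (py[k2] - py[k])
      if (py[k] <= y[i]) {
        if (py[k2] > y[i] && cross > 0) wn <- wn + 1
      } else {
        if (py[k2] <= y[i] && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, TRUE)
}

# fan-triangulation area of a convex polygon
oracle_fan_area <- function(x, y) {
  a <- 0
  for (k in 2:(length(x) - 1)) {
    a <- a + abs((x[k] - x[1]) * (y[k + 1] - y[1]) -
                   (x[k + 1] - x[1]) * (y[k] - y[1])) / 2
  }
  a
}

# all-pairs nearest-neighbour distances by explicit double loop
oracle_nnd <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# unsmoothed binned pair-count estimate of g(r) without edge correction:
# pairs with distance in [r - dr/2, r + dr/2] over the CSR expectation
oracle_g_binned <- function(xy, area, r, dr) {
  n <- nrow(xy)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d >= r - dr / 2 && d < r + dr / 2) cnt <- cnt + 1
  }
  lambda <- n / area
  cnt / (lambda^2 * area * 2 * pi * r * dr)
}

# kernel pair-sum g(r), no edge correction, straight double loop
oracle_g_kernel <- function(xy, area, r, bw) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    s <- s + stats::dnorm(r - d, sd = bw)
  }
  lambda <- n / area
  s / (lambda^2 * area * 2 * pi * r)
}

# brute-force DBSCAN by transitive closure of the eps-graph of core points;
# border points join the cluster of their lowest-index core neighbour
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  adj <- D <= eps
  core <- which(rowSums(adj) >= min_pts)
  labels <- rep(-1L, n)
  if (!length(core)) return(labels)
  # reachability closure among core points
  reach <- adj[core, core, drop = FALSE]
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, length(core))
  cl <- 0L
  for (i in seq_along(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    comp[which(reach[i, ])] <- cl
    comp[i] <- cl
  }
  labels[core] <- comp
  for (i in setdiff(seq_len(n), core)) {
    nb_core <- core[adj[i, core]]
    if (length(nb_core)) labels[i] <- labels[min(nb_core)]
  }
  labels
}

# canonical partition signature: clusters as sorted member-index lists,
# sorted by first member; used to compare labelings up to renumbering
partition_signature <- function(labels) {
  ids <- unique(labels[labels != -1L])
  cl <- lapply(ids, function(g) sort(which(labels == g)))
  cl <- cl[order(vapply(cl, min, 0L))]
  list(clusters = cl, noise = sort(which(labels == -1L)))
}

# union-find connected components of the eps-ball graph
oracle_components <- function(xy, eps) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  D <- as.matrix(stats::dist(xy))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && D[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  match(comp, unique(comp))
}
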