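#' Polygonal analysis windows
#'
#' An `az_window` is a simple (non-self-intersecting) closed polygon in the
#' replica plane, with coordinates in nanometres. It demarcates either an
#' active zone (`region_class = "AZ"`) or surrounding membrane
#' (`region_class = "extra_AZ"`) and is the window against which every point
#' pattern is analysed. The closing edge from the last vertex back to the
#' first is implicit; do not repeat the first vertex.
#'
#' @param x,y numeric vertex coordinates in nm (>= 3 vertices).
#' @param region_id character identifier, unique within a dataset.
#' @param region_class `"AZ"` or `"extra_AZ"`.
#' @return An object of class `az_window` with components `x`, `y`,
#'   `region_id`, `region_class`.
#' @examples
#' w <- az_window(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), "az1")
#' polygon_area(w)  # 1e6 nm^2 = 0.001 um^2
#' @export
az_window <- function(x, y, region_id = "region1",
                      region_class = c("AZ", "extra_AZ")) {
  region_class <- match.arg(region_class)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("a window polygon needs at least 3 vertices", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("window vertices must be finite", call. = FALSE)
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
    if (length(x) < 3L)
      stop("a window polygon needs at least 3 distinct vertices", call. = FALSE)
  }
  w <- structure(list(x = x, y = y,
                      region_id = as.character(region_id),
                      region_class = region_class),
                 class = "az_window")
  if (.self_intersects(x, y))
    stop("polygon is self-intersecting", call. = FALSE)
  if (.shoelace_signed(x, y) == 0)
    stop("degenerate polygon: zero area", call. = FALSE)
  w
}

#' @export
print.az_window <- function(x, ...) {
  cat(sprintf("az_window '%s' (%s): %d vertices, area %.4g um^2\n",
              x$region_id, x$region_class, length(x$x),
              polygon_area(x) / 1e6))
  invisible(x)
}

.shoelace_signed <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# proper-crossing test between every non-adjacent edge pair (O(n^2));
# windows have at most a few hundred vertices so this is cheap
.self_intersects <- function(x, y) {
  n <- length(x)
  if (n <= 3L) return(FALSE)
  p1x <- x; p1y <- y
  j <- c(2:n, 1L)
  p2x <- x[j]; p2y <- y[j]
  seg_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
    d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
    d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
    d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
    (d1 * d2 < 0) & (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    ks <- ks[!(i == 1L & ks == n)]  # skip edges adjacent through the closure
    if (!length(ks)) next
    if (any(seg_cross(p1x[i], p1y[i], p2x[i], p2y[i],
                      p1x[ks], p1y[ks], p2x[ks], p2y[ks])))
      return(TRUE)
  }
  FALSE
}

#' Polygon area by the shoelace formula
#'
#' Orientation-independent (absolute value of the signed area).
#'
#' @param poly an [az_window()].
#' @return area in nm^2.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "az_window"))
  abs(.shoelace_signed(poly$x, poly$y))
}

#' Polygon centroid (area-weighted)
#'
#' @param poly an [az_window()].
#' @return numeric `c(x, y)` in nm.
#' @export
polygon_centroid <- function(poly) {
  stopifnot(inherits(poly, "az_window"))
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Point-in-polygon test
#'
#' Even-odd ray-casting test; points on the boundary (within `tol` nm of any
#' edge) count as inside, so particles digitised exactly on an AZ outline are
#' not lost.
#'
#' @param x,y numeric coordinate vectors (nm), recycled to common length.
#' @param poly an [az_window()].
#' @param tol boundary tolerance in nm.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  stopifnot(inherits(poly, "az_window"))
  px <- poly$x; py <- poly$y
  n <- length(px)
  j <- c(2:n, 1L)
  npts <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), npts); y <- rep_len(as.numeric(y), npts)
  inside <- logical(npts)
  on_edge <- logical(npts)
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- px[j[k]]; y2 <- py[j[k]]
    # crossing-number update
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xin <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      upd <- which(crosses)[xin > x[crosses]]
      inside[upd] <- !inside[upd]
    }
    # distance to the segment for the boundary test
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((x - x1) * vx + (y - y1) * vy) / L2)) else 0
    dx <- x - (x1 + t * vx); dy <- y - (y1 + t * vy)
    on_edge <- on_edge | (dx * dx + dy * dy <= tol * tol)
  }
  inside | on_edge
}

#' Minimum distance from points to the polygon boundary
#'
#' @param x,y numeric coordinates (nm).
#' @param poly an [az_window()].
#' @return numeric vector of distances in nm.
#' @export
dist_to_boundary <- function(x, y, poly) {
  stopifnot(inherits(poly, "az_window"))
  px <- poly$x; py <- poly$y
  n <- length(px)
  j <- c(2:n, 1L)
  npts <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), npts); y <- rep_len(as.numeric(y), npts)
  d2 <- rep(Inf, npts)
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; vx <- px[j[k]] - x1; vy <- py[j[k]] - y1
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((x - x1) * vx + (y - y1) * vy) / L2)) else 0
    dx <- x - (x1 + t * vx); dy <- y - (y1 + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Distance from an interior origin to the boundary along given directions
#'
#' For each direction (`ux`, `uy`) (need not be normalised), returns the
#' smallest positive `t` at which `origin + t * u / |u|` meets the polygon
#' boundary. For a window that is star-shaped about `origin` this is the
#' unique boundary crossing, used by the centre-periphery index.
#'
#' @param origin numeric `c(x, y)` in nm, inside the polygon.
#' @param ux,uy direction components.
#' @param poly an [az_window()].
#' @return numeric vector of distances (nm); `NA` where a ray misses (should
#'   not happen for interior origins).
#' @export
ray_boundary_distance <- function(origin, ux, uy, poly) {
  stopifnot(inherits(poly, "az_window"))
  nr <- max(length(ux), length(uy))
  ux <- rep_len(as.numeric(ux), nr); uy <- rep_len(as.numeric(uy), nr)
  L <- sqrt(ux^2 + uy^2)
  bad <- L == 0
  ux <- ifelse(bad, 1, ux / ifelse(bad, 1, L))
  uy <- ifelse(bad, 0, uy / ifelse(bad, 1, L))
  px <- poly$x; py <- poly$y
  n <- length(px)
  j <- c(2:n, 1L)
  ox <- origin[1]; oy <- origin[2]
  tmin <- rep(Inf, nr)
  for (k in seq_len(n)) {
    ax <- px[k]; ay <- py[k]
    ex <- px[j[k]] - ax; ey <- py[j[k]] - ay
    denom <- ux * ey - uy * ex
    ok <- abs(denom) > 1e-12
    s <- ((ax - ox) * ey - (ay - oy) * ex) / denom  # ray parameter
    r <- ((ax - ox) * uy - (ay - oy) * ux) / denom  # edge parameter
    hit <- ok & s > 1e-9 & r >= -1e-9 & r <= 1 + 1e-9
    tmin[hit] <- pmin(tmin[hit], s[hit])
  }
  tmin[!is.finite(tmin)] <- NA_real_
  tmin
}

#' Test whether a window is star-shaped about a point
#'
#' Checks that the first boundary crossing along the ray from `origin` to
#' each vertex (and each edge midpoint) occurs at that vertex/midpoint, i.e.
#' the whole segment is visible from `origin`.
#'
#' @param poly an [az_window()].
#' @param origin numeric `c(x, y)`; defaults to the centroid.
#' @return logical scalar.
#' @export
is_star_shaped <- function(poly, origin = polygon_centroid(poly)) {
  stopifnot(inherits(poly, "az_window"))
  n <- length(poly$x)
  j <- c(2:n, 1L)
  tx <- c(poly$x, (poly$x + poly$x[j]) / 2)
  ty <- c(poly$y, (poly$y + poly$y[j]) / 2)
  dx <- tx - origin[1]; dy <- ty - origin[2]
  d <- sqrt(dx^2 + dy^2)
  keep <- d > 1e-9
  if (!any(keep)) return(TRUE)
  hit <- ray_boundary_distance(origin, dx[keep], dy[keep], poly)
  all(!is.na(hit) & hit >= d[keep] - max(1e-6, 1e-9 * max(d)))
}

#' Scale a window about the origin
#'
#' @param poly an [az_window()].
#' @param k positive scale factor.
#' @return a new `az_window`.
#' @export
scale_window <- function(poly, k) {
  stopifnot(inherits(poly, "az_window"), k > 0)
  az_window(poly$x * k, poly$y * k, poly$region_id, poly$region_class)
}

#' Rectangular and disc windows
#'
#' Convenience constructors for common windows: `rect_window()` builds an
#' axis-aligned rectangle, `disc_window()` a regular `n_vertices`-gon
#' approximation to a disc.
#'
#' @param width,height rectangle side lengths in nm.
#' @param radius disc radius in nm.
#' @param centre numeric `c(x, y)` in nm.
#' @param n_vertices number of polygon vertices approximating the disc.
#' @param region_id,region_class passed to [az_window()].
#' @return an `az_window`.
#' @export
rect_window <- function(width, height = width, centre = c(0, 0),
                        region_id = "rect", region_class = "AZ") {
  hw <- width / 2; hh <- height / 2
  az_window(centre[1] + c(-hw, hw, hw, -hw),
            centre[2] + c(-hh, -hh, hh, hh),
            region_id, region_class)
}

#' @rdname rect_window
#' @export
disc_window <- function(radius, centre = c(0, 0), n_vertices = 128L,
                        region_id = "disc", region_class = "AZ") {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  az_window(centre[1] + radius * cos(th), centre[2] + radius * sin(th),
            region_id, region_class)
}

# TRUE for 4-vertex axis-aligned rectangles (enables exact samplers)
is_axis_rect <- function(poly) {
  if (length(poly$x) != 4L) return(FALSE)
  xs <- sort(unique(poly$x)); ys <- sort(unique(poly$y))
  length(xs) == 2L && length(ys) == 2L &&
    all(table(poly$x) == 2L) && all(table(poly$y) == 2L)
}

#' Bounding box of a window
#'
#' @param poly an [az_window()].
#' @return list with `xmin`, `xmax`, `ymin`, `ymax` (nm).
#' @export
window_bbox <- function(poly) {
  stopifnot(inherits(poly, "az_window"))
  list(xmin = min(poly$x), xmax = max(poly$x),
       ymin = min(poly$y), ymax = max(poly$y))
}
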