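#' Point patterns of gold particles in a window
#'
#' A `point_pattern` binds particle coordinates (nm) to one analysis window.
#' Every point must lie inside or on the boundary of the window (boundary
#' tolerance 1e-9 nm). Duplicate coordinates are permitted — two gold
#' particles can be digitised at the same pixel — but are counted in the
#' validity report ([pattern_validity()]).
#'
#' @param x,y numeric particle coordinates in nm.
#' @param window an [az_window()].
#' @param face fracture face: `"P_face"`, `"E_face"` or `"cross_fracture"`.
#'   Intracellular-epitope antibodies label the P-face; E-face particles are
#'   background.
#' @param label marker name, e.g. `"CaV2.1"`.
#' @param check if `FALSE`, skip the containment check (used internally by
#'   generators whose construction guarantees containment).
#' @return An object of class `point_pattern`.
#' @examples
#' w <- rect_window(1000)
#' p <- point_pattern(c(-100, 0, 100), c(0, 50, -50), w)
#' npoints(p)
#' @export
point_pattern <- function(x, y, window,
                          face = c("P_face", "E_face", "cross_fracture"),
                          label = "unknown", check = TRUE) {
  face <- match.arg(face)
  stopifnot(inherits(window, "az_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("particle coordinates must be finite", call. = FALSE)
  if (check && length(x) > 0 && !all(point_in_polygon(x, y, window)))
    stop(sprintf("%d point(s) outside window '%s'",
                 sum(!point_in_polygon(x, y, window)), window$region_id),
         call. = FALSE)
  structure(list(x = x, y = y, window = window, face = face, label = label),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d '%s' particles (%s) in window '%s'\n",
              length(x$x), x$label, x$face, x$window$region_id))
  invisible(x)
}

#' Number of points in a pattern
#' @param p a [point_pattern()].
#' @return integer count.
#' @export
npoints <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  length(p$x)
}

#' Coordinates of a pattern as a matrix
#' @param p a [point_pattern()].
#' @return n x 2 numeric matrix with columns `x`, `y`.
#' @export
coords <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  cbind(x = p$x, y = p$y)
}

#' Validity report for a point pattern
#'
#' Checks the containment invariant and counts duplicated coordinates
#' (exact ties, which are kept in the pattern but flagged here).
#'
#' @param p a [point_pattern()].
#' @return list with `n`, `n_duplicates`, `all_inside`, `density_per_um2`.
#' @export
pattern_validity <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  n <- npoints(p)
  dup <- if (n > 1) sum(duplicated(cbind(p$x, p$y))) else 0L
  list(n = n,
       n_duplicates = as.integer(dup),
       all_inside = n == 0 || all(point_in_polygon(p$x, p$y, p$window)),
       density_per_um2 = n / (polygon_area(p$window) / NM2_PER_UM2))
}

#' Replica datasets: a collection of point patterns
#'
#' Bundles the per-region patterns of one replica (or one experiment) with
#' free-text metadata. Region ids must be unique.
#'
#' @param patterns list of [point_pattern()] objects.
#' @param synapse_type free text, e.g. `"PF-PC"`.
#' @param metadata named list (animal age, antibody id, ...).
#' @param rejects optional data frame of particles that fell in no region
#'   (kept for QC, never silently dropped).
#' @return An object of class `replica_dataset`.
#' @export
replica_dataset <- function(patterns, synapse_type = "unknown",
                            metadata = list(), rejects = NULL) {
  stopifnot(is.list(patterns),
            all(vapply(patterns, inherits, TRUE, "point_pattern")))
  ids <- vapply(patterns, function(p) p$window$region_id, "")
  if (anyDuplicated(ids))
    stop("region_ids must be unique within a dataset", call. = FALSE)
  names(patterns) <- ids
  structure(list(patterns = patterns, synapse_type = synapse_type,
                 metadata = metadata, rejects = rejects),
            class = "replica_dataset")
}

#' @export
print.replica_dataset <- function(x, ...) {
  cls <- vapply(x$patterns, function(p) p$window$region_class, "")
  cat(sprintf("replica_dataset (%s): %d regions (%d AZ, %d extra-AZ), %d particles",
              x$synapse_type, length(x$patterns), sum(cls == "AZ"),
              sum(cls == "extra_AZ"),
              sum(vapply(x$patterns, npoints, 0L))))
  nrej <- if (is.null(x$rejects)) 0L else nrow(x$rejects)
  if (nrej > 0) cat(sprintf(", %d rejects", nrej))
  cat("\n")
  invisible(x)
}

#' Subset the patterns of a dataset by region class
#' @param dataset a [replica_dataset()].
#' @param region_class `"AZ"` or `"extra_AZ"`.
#' @return list of `point_pattern`s.
#' @export
patterns_by_class <- function(dataset, region_class = "AZ") {
  stopifnot(inherits(dataset, "replica_dataset"))
  Filter(function(p) p$window$region_class == region_class, dataset$patterns)
}
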