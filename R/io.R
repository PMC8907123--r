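#' Read a particle table into a replica dataset
#'
#' Reads a CSV of gold-particle coordinates (nm) and assigns each particle to
#' its region polygon. Particles whose `region_id` matches no known region,
#' or which fall outside their region's polygon, are collected into the
#' dataset's `rejects` table with their source line numbers — never silently
#' dropped. Rows with non-finite coordinates raise an error naming the line.
#'
#' The default column schema is `x_nm, y_nm, region_id, face, label`;
#' `face` and `label` are optional with defaults `"P_face"` / `"unknown"`.
#'
#' @param path CSV file path.
#' @param regions a list of [az_window()] objects, or a path accepted by
#'   [read_regions()].
#' @param schema named character vector remapping the expected column names,
#'   e.g. `c(x = "X", y = "Y", region_id = "az")`.
#' @param synapse_type,metadata stored on the returned dataset.
#' @return a [replica_dataset()]. Regions containing particles of more than
#'   one fracture face yield one pattern per face, with `/<face>` appended to
#'   the region id of the minority faces.
#' @export
read_particles <- function(path, regions,
                           schema = c(x = "x_nm", y = "y_nm",
                                      region_id = "region_id",
                                      face = "face", label = "label"),
                           synapse_type = "unknown", metadata = list()) {
  if (is.character(regions)) regions <- read_regions(regions)
  stopifnot(is.list(regions),
            all(vapply(regions, inherits, TRUE, "az_window")))
  names(regions) <- vapply(regions, function(w) w$region_id, "")
  if (anyDuplicated(names(regions)))
    stop("duplicate region_id among region polygons", call. = FALSE)

  def <- c(x = "x_nm", y = "y_nm", region_id = "region_id",
           face = "face", label = "label")
  def[names(schema)] <- schema
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- def[c("x", "y", "region_id")]
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("particle table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  x <- suppressWarnings(as.numeric(tab[[def["x"]]]))
  y <- suppressWarnings(as.numeric(tab[[def["y"]]]))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("non-finite coordinate at data line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  rid <- as.character(tab[[def["region_id"]]])
  face <- if (def["face"] %in% names(tab))
    as.character(tab[[def["face"]]]) else rep("P_face", nrow(tab))
  face[is.na(face) | face == ""] <- "P_face"
  lab <- if (def["label"] %in% names(tab))
    as.character(tab[[def["label"]]]) else rep("unknown", nrow(tab))
  lab[is.na(lab) | lab == ""] <- "unknown"

  known <- rid %in% names(regions)
  inside <- logical(nrow(tab))
  for (id in unique(rid[known])) {
    sel <- which(rid == id)
    inside[sel] <- point_in_polygon(x[sel], y[sel], regions[[id]])
  }
  ok <- known & inside
  rejects <- NULL
  if (any(!ok)) {
    rejects <- data.frame(line = which(!ok) + 1L,
                          x_nm = x[!ok], y_nm = y[!ok],
                          region_id = rid[!ok],
                          reason = ifelse(!known[!ok], "unknown region",
                                          "outside region polygon"),
                          stringsAsFactors = FALSE)
  }

  patterns <- list()
  for (id in names(regions)) {
    sel <- which(ok & rid == id)
    if (!length(sel)) {
      patterns[[id]] <- point_pattern(numeric(0), numeric(0), regions[[id]])
      next
    }
    faces <- unique(face[sel])
    main <- names(sort(table(face[sel]), decreasing = TRUE))[1]
    for (f in faces) {
      s <- sel[face[sel] == f]
      win <- regions[[id]]
      pid <- if (f == main) id else paste0(id, "/", f)
      win$region_id <- pid
      patterns[[pid]] <- point_pattern(x[s], y[s], win, face = f,
                                       label = lab[s][1])
    }
  }
  replica_dataset(patterns, synapse_type = synapse_type,
                  metadata = metadata, rejects = rejects)
}

#' Write a replica dataset's particles to CSV
#'
#' Emits the canonical `x_nm,y_nm,region_id,face,label` dialect (RFC-4180,
#' UTF-8) that [read_particles()] reads back.
#'
#' @param dataset a [replica_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(dataset, path) {
  stopifnot(inherits(dataset, "replica_dataset"))
  rows <- lapply(dataset$patterns, function(p) {
    if (npoints(p) == 0) return(NULL)
    data.frame(x_nm = p$x, y_nm = p$y, region_id = p$window$region_id,
               face = p$face, label = p$label, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      region_id = character(0), face = character(0),
                      label = character(0))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read region polygons
#'
#' Accepts either a GeoJSON FeatureCollection of Polygons with properties
#' `region_id` and `region_class`, or a CSV vertex list with columns
#' `region_id, vertex_index, x_nm, y_nm` and optional `region_class`.
#' The format is chosen by file extension (`.geojson`/`.json` vs `.csv`).
#'
#' @param path file path.
#' @return list of [az_window()] objects.
#' @export
read_regions <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
    read_regions_geojson(path)
  else
    read_regions_csv(path)
}

#' @rdname read_regions
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]  # exterior ring; holes unsupported
    xy <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    az_window(xy[, 1], xy[, 2],
              region_id = f$properties$region_id %||% "region",
              region_class = f$properties$region_class %||% "AZ")
  })
}

#' @rdname read_regions
#' @export
read_regions_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "vertex_index", "x_nm", "y_nm")
  if (!all(need %in% names(tab)))
    stop("region CSV is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  lapply(split(tab, tab$region_id), function(d) {
    d <- d[order(d$vertex_index), ]
    az_window(d$x_nm, d$y_nm, region_id = d$region_id[1],
              region_class = if ("region_class" %in% names(d))
                d$region_class[1] else "AZ")
  })
}

#' Write region polygons
#'
#' `write_regions_geojson()` emits a GeoJSON FeatureCollection (closed
#' rings); `write_regions_csv()` emits the vertex-list dialect. Both are read
#' back by [read_regions()].
#'
#' @param regions list of [az_window()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(regions, function(w) {
    ring <- lapply(c(seq_along(w$x), 1L), function(i) c(w$x[i], w$y[i]))
    list(type = "Feature",
         properties = list(region_id = w$region_id,
                           region_class = w$region_class),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
write_regions_csv <- function(regions, path) {
  tab <- do.call(rbind, lapply(regions, function(w) {
    data.frame(region_id = w$region_id,
               vertex_index = seq_along(w$x),
               x_nm = w$x, y_nm = w$y,
               region_class = w$region_class, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
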