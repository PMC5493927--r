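#' Terrain-dependent hiking-speed function
#'
#' Walking speed as an exponential function of terrain slope:
#' `speed = max_speed * exp(-slope_sensitivity * |slope + slope_offset|)`.
#' The defaults (6 km/h, 3.5, 0.05) are Tobler's classic parameters: the
#' maximum 6 km/h is attained on a gentle -5% downhill, level walking runs
#' at about 5.04 km/h, and speed decays on steeper grades in either
#' direction -- so travel time is anisotropic (uphill differs from
#' downhill). Speed is strictly positive for any finite slope, so cost
#' graphs never contain zero- or negative-speed edges.
#'
#' @param max_speed peak speed in km/h.
#' @param slope_sensitivity dimensionless decay rate.
#' @param slope_offset slope (rise/run) at which the peak is attained,
#'   negated; 0.05 puts the peak at slope -0.05.
#' @return Object of class `"hiking_function"`.
#' @export
hiking_function <- function(max_speed = 6, slope_sensitivity = 3.5,
                            slope_offset = 0.05) {
  stop_if_not_scalar_finite(max_speed, "max_speed")
  if (max_speed <= 0) stop("max_speed must be positive", call. = FALSE)
  stop_if_not_scalar_finite(slope_sensitivity, "slope_sensitivity")
  stop_if_not_scalar_finite(slope_offset, "slope_offset")
  structure(list(max_speed = max_speed,
                 slope_sensitivity = slope_sensitivity,
                 slope_offset = slope_offset),
            class = "hiking_function")
}

#' Walking speed at a given slope
#' @param slope rise/run (dimensionless), positive uphill; finite.
#' @param f a [hiking_function()].
#' @return Speed in km/h (vectorised over `slope`).
#' @export
#' @examples
#' hiking_speed(0)       # level ground, about 5.04 km/h
#' hiking_speed(-0.05)   # Tobler's optimum, 6 km/h
hiking_speed <- function(slope, f = hiking_function()) {
  if (any(!is.finite(slope)))
    stop("slope must be finite", call. = FALSE)
  f$max_speed * exp(-f$slope_sensitivity * abs(slope + f$slope_offset))
}

# Neighbour offsets (row, col) for the two supported connectivities.
# 16-connectivity adds the knight moves, reducing metric distortion.
connectivity_offsets <- function(connectivity) {
  queen <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  if (connectivity == 8) return(queen)
  if (connectivity == 16)
    return(rbind(queen,
                 cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                       dc = c(-1, 1, -2, 2, -2, 2, -1, 1))))
  stop("connectivity must be 8 or 16", call. = FALSE)
}

# Authalic sphere radius (metres) used for great-circle cell distances.
AUTHALIC_RADIUS_M <- 6371007.2

#' Build the directed travel-cost graph of an elevation raster
#'
#' Every pair of neighbouring cells (8- or 16-connectivity) contributes
#' two directed edges whose weight is the cell-centre distance divided by
#' the slope-dependent walking speed, in hours. Planar grids use
#' Euclidean distances; geographic grids use great-circle distances on
#' the authalic sphere, so east--west spacing contracts with latitude.
#' Edges touching nodata cells are omitted.
#'
#' @param dem a [dem_raster()].
#' @param f a [hiking_function()].
#' @param connectivity 8 (queen) or 16 (queen plus knight moves).
#' @return Data frame with columns `from`, `to` (linear cell indices,
#'   row-major), `dist_km` and `hours`; grid dimensions in attributes.
#' @export
build_cost_graph <- function(dem, f = hiking_function(), connectivity = 8) {
  offs <- connectivity_offsets(connectivity)
  nr <- dem$n_rows; nc <- dem$n_cols
  elev <- dem$elevation
  geographic <- dem$crs_kind == "geographic_degrees"
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    from_rc <- expand.grid(row = r0, col = c0)
    to_rc <- cbind(row = from_rc$row + dr, col = from_rc$col + dc)
    e_from <- elev[cbind(from_rc$row, from_rc$col)]
    e_to <- elev[to_rc]
    ok <- !is.na(e_from) & !is.na(e_to)
    if (!any(ok)) next
    from_rc <- from_rc[ok, , drop = FALSE]
    to_rc <- to_rc[ok, , drop = FALSE]
    e_from <- e_from[ok]; e_to <- e_to[ok]
    if (geographic) {
      p1 <- cell_xy(dem, from_rc$row, from_rc$col)
      p2 <- cell_xy(dem, to_rc[, 1], to_rc[, 2])
      dist_m <- geosphere::distCosine(p1, p2, r = AUTHALIC_RADIUS_M)
    } else {
      dist_m <- sqrt((dr * dem$cell_size)^2 + (dc * dem$cell_size)^2)
      dist_m <- rep(dist_m, nrow(from_rc))
    }
    slope <- (e_to - e_from) / dist_m
    speed <- hiking_speed(slope, f)
    edges[[k]] <- data.frame(
      from = cell_index(from_rc$row, from_rc$col, nc),
      to = cell_index(to_rc[, 1], to_rc[, 2], nc),
      dist_km = dist_m / 1000,
      hours = (dist_m / 1000) / speed
    )
  }
  out <- do.call(rbind, edges)
  attr(out, "n_rows") <- nr
  attr(out, "n_cols") <- nc
  out
}

#' Minimum travel-time surface from a source cell
#'
#' Single-source shortest-path times (Dijkstra) over the directed
#' travel-cost graph, with predecessor links for route extraction.
#'
#' @param dem a [dem_raster()].
#' @param f a [hiking_function()].
#' @param source_cell `c(row, col)` of the starting cell (1-based, row 1
#'   at the north edge); must not be nodata.
#' @param connectivity 8 or 16.
#' @return Object of class `"travel_time_surface"`: a list with `times`
#'   (matrix of hours; `Inf` = unreachable, `NA` = nodata), `predecessor`
#'   (matrix of linear cell indices; `NA` at the source and unreachable
#'   cells), `source`, `dem`, `hiking`, `connectivity`.
#' @export
#' @examples
#' dem <- synth_dem("plane", 10, 10, cell_size = 1000)
#' s <- travel_time_surface(dem, source_cell = c(5, 5))
#' s$times[5, 5]  # 0 at the source
travel_time_surface <- function(dem, f = hiking_function(),
                                source_cell, connectivity = 8) {
  nr <- dem$n_rows; nc <- dem$n_cols
  src <- cell_index(source_cell[1], source_cell[2], nc)
  if (source_cell[1] < 1 || source_cell[1] > nr ||
      source_cell[2] < 1 || source_cell[2] > nc)
    stop("source cell outside grid", call. = FALSE)
  if (is.na(dem$elevation[source_cell[1], source_cell[2]]))
    stop("source cell is nodata", call. = FALSE)
  g <- build_cost_graph(dem, f, connectivity)
  graph <- igraph::make_empty_graph(n = nr * nc, directed = TRUE)
  graph <- igraph::add_edges(graph, rbind(g$from, g$to))
  igraph::E(graph)$weight <- g$hours
  t_vec <- as.numeric(igraph::distances(graph, v = src, mode = "out",
                                        algorithm = "dijkstra"))
  # unreachable vertices (nodata islands) are expected; they surface as
  # Inf times rather than warnings
  pred <- suppressWarnings(
    igraph::shortest_paths(graph, from = src,
                           to = igraph::V(graph), mode = "out",
                           predecessors = TRUE)$predecessors)
  pred <- as.integer(pred)
  pred[src] <- NA_integer_
  pred[!is.finite(t_vec)] <- NA_integer_
  times <- matrix(t_vec, nr, nc, byrow = TRUE)
  times[is.na(dem$elevation)] <- NA
  predecessor <- matrix(pred, nr, nc, byrow = TRUE)
  structure(
    list(times = times, predecessor = predecessor, source = src,
         dem = dem, hiking = f, connectivity = connectivity,
         edges = g),
    class = "travel_time_surface"
  )
}

#' @export
print.travel_time_surface <- function(x, ...) {
  finite <- x$times[is.finite(x$times)]
  cat(sprintf("travel_time_surface: %d x %d cells from cell %d (%d-connectivity)\n",
              x$dem$n_rows, x$dem$n_cols, x$source, x$connectivity))
  cat(sprintf("  times 0..%.2f h; %d unreachable cells\n",
              max(finite), sum(is.infinite(x$times), na.rm = TRUE)))
  invisible(x)
}

# Walk predecessor links back from a target cell to the source.
extract_path <- function(surface, target_idx) {
  nc <- surface$dem$n_cols
  path <- integer(0)
  cur <- target_idx
  repeat {
    path <- c(cur, path)
    if (cur == surface$source) break
    rc <- index_rowcol(cur, nc)
    cur <- surface$predecessor[rc[1], rc[2]]
    if (is.na(cur)) stop("no path recorded to target cell", call. = FALSE)
  }
  index_rowcol(path, nc)
}

path_length_km <- function(dem, path_rc) {
  if (nrow(path_rc) < 2L) return(0)
  p <- cell_xy(dem, path_rc[, 1], path_rc[, 2])
  if (dem$crs_kind == "geographic_degrees") {
    sum(geosphere::distCosine(p[-nrow(p), , drop = FALSE],
                              p[-1, , drop = FALSE],
                              r = AUTHALIC_RADIUS_M)) / 1000
  } else {
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2))) / 1000
  }
}

#' Minimum travel time and route from a source to an elevation contour
#'
#' Finds the cell strictly below `contour_elevation` with the smallest
#' travel time from the source, and reconstructs the minimum-time route.
#' The one-way path length is the sum of per-edge cell-centre distances;
#' the round trip is twice that (out-and-back along the optimal route).
#'
#' @param dem a [dem_raster()].
#' @param f a [hiking_function()].
#' @param source_cell `c(row, col)` starting cell.
#' @param contour_elevation contour threshold in metres (default 2500,
#'   the conventional high-elevation boundary).
#' @param connectivity 8 or 16.
#' @param surface optional precomputed [travel_time_surface()] to reuse.
#' @return Object of class `"contour_route"`: list with `hours`,
#'   `target` (row, col), `path` (matrix of row/col), `length_km`,
#'   `round_trip_km`, `reached`. If no cell lies below the contour,
#'   `reached` is `FALSE` and `reason` explains why.
#' @export
time_to_contour <- function(dem, f = hiking_function(), source_cell,
                            contour_elevation = 2500, connectivity = 8,
                            surface = NULL) {
  if (is.null(surface))
    surface <- travel_time_surface(dem, f, source_cell, connectivity)
  below <- which(dem$elevation < contour_elevation, arr.ind = TRUE)
  if (!nrow(below))
    return(structure(list(reached = FALSE, reason = "no target",
                          hours = NA_real_), class = "contour_route"))
  tt <- surface$times[below]
  if (all(!is.finite(tt)))
    return(structure(list(reached = FALSE, reason = "contour unreachable",
                          hours = Inf), class = "contour_route"))
  best_rc <- below[which.min(tt), ]
  best <- cell_index(best_rc[1], best_rc[2], dem$n_cols)
  path <- extract_path(surface, best)
  len <- path_length_km(dem, path)
  structure(
    list(reached = TRUE, hours = min(tt, na.rm = TRUE),
         target = index_rowcol(best, dem$n_cols)[1, ],
         path = path, length_km = len, round_trip_km = 2 * len,
         contour_elevation = contour_elevation),
    class = "contour_route"
  )
}

#' @export
print.contour_route <- function(x, ...) {
  if (!isTRUE(x$reached)) {
    cat("contour_route: target not reached (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("contour_route: %.2f h to the %g m contour; one-way %.1f km, round trip %.1f km\n",
                x$hours, x$contour_elevation, x$length_km, x$round_trip_km))
  }
  invisible(x)
}

#' Label travel-time isochrone bands
#'
#' Each reachable cell is labelled `floor(time / interval)`, so band 0
#' covers times `[0, interval)`, band 1 `[interval, 2 interval)`, and so
#' on; the bands partition the reachable cells. Unreachable and nodata
#' cells are `NA`.
#'
#' @param surface a [travel_time_surface()].
#' @param interval band width in hours (default 10).
#' @return Integer matrix of band labels with attribute `interval`,
#'   class `"isochrone_bands"`.
#' @export
isochrones <- function(surface, interval = 10) {
  stop_if_not_scalar_finite(interval, "interval")
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  b <- floor(surface$times / interval)
  b[!is.finite(surface$times)] <- NA
  structure(b, interval = interval, class = c("isochrone_bands", "matrix"))
}

#' Write a route or isochrone bands as GeoJSON
#'
#' The route becomes a LineString of cell-centre coordinates; isochrone
#' bands become one MultiPoint feature per band. Coordinates are in the
#' raster's own system (metres for planar, lon/lat for geographic).
#'
#' @param x a [time_to_contour()] route or [isochrones()] bands.
#' @param dem the [dem_raster()] the object was computed on.
#' @param path output `.geojson` file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, dem, path) {
  feature <- function(geom, props) list(type = "Feature",
                                        properties = props, geometry = geom)
  if (inherits(x, "contour_route")) {
    if (!isTRUE(x$reached)) stop("route has no path", call. = FALSE)
    coords <- unname(cell_xy(dem, x$path[, 1], x$path[, 2]))
    fc <- list(type = "FeatureCollection", features = list(
      feature(list(type = "LineString",
                   coordinates = lapply(seq_len(nrow(coords)),
                                        function(i) coords[i, ])),
              list(hours = x$hours, length_km = x$length_km,
                   round_trip_km = x$round_trip_km))))
  } else if (inherits(x, "isochrone_bands")) {
    bands <- sort(unique(as.integer(x[!is.na(x)])))
    feats <- lapply(bands, function(b) {
      idx <- which(unclass(x) == b, arr.ind = TRUE)
      coords <- unname(cell_xy(dem, idx[, 1], idx[, 2]))
      feature(list(type = "MultiPoint",
                   coordinates = lapply(seq_len(nrow(coords)),
                                        function(i) coords[i, ])),
              list(band = b,
                   hours_lo = b * attr(x, "interval"),
                   hours_hi = (b + 1) * attr(x, "interval")))
    })
    fc <- list(type = "FeatureCollection", features = feats)
  } else stop("x must be a contour_route or isochrone_bands", call. = FALSE)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write the travel summary (minimum time, one-way and round-trip km)
#' @param route a [time_to_contour()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_travel_summary <- function(route, path) {
  utils::write.csv(
    data.frame(min_time_h = route$hours,
               one_way_km = route$length_km,
               round_trip_km = route$round_trip_km),
    path, row.names = FALSE)
  invisible(path)
}
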