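#' Distance-to-expert-range layer
#'
#' Converts an expert range polygon into the continuous predictor used by
#' the expert-informed meta-learner: 0 for every cell whose centre lies
#' inside (or on the boundary of) the polygon, otherwise the great-circle
#' distance in km to the nearest point of the polygon boundary. The boundary
#' is densified to a vertex spacing of at most \code{step_deg} degrees, which
#' bounds the discretisation error of the nearest-point search.
#'
#' @param poly a \code{range_polygon}.
#' @param env an \code{env_stack} providing the grid.
#' @param area a \code{calibration_area}; cells outside it are nodata. NULL
#'   computes the layer over all unmasked cells.
#' @param step_deg boundary densification step (degrees).
#' @return object of class \code{distance_layer}: \code{values} matrix (km),
#'   grid geometry and the source polygon label.
#' @export
distance_to_range <- function(poly, env, area = NULL, step_deg = 0.05) {
  sel <- if (is.null(area)) env$mask else {
    stopifnot_same_grid(env, area)
    area$mask & env$mask
  }
  cells <- as_cell_table(env, unmasked_only = FALSE)
  use <- as.vector(sel)
  lon <- cells$lon[use]; lat <- cells$lat[use]
  inside <- point_in_polygon(poly, lon, lat)
  if (!any(inside))
    warning("expert polygon contains no cell centre; distance layer is ",
            "positive everywhere")
  d <- numeric(length(lon))
  if (any(!inside)) {
    bnd <- densify_boundary(poly, step_deg)
    d[!inside] <- min_dist_km(cbind(lon[!inside], lat[!inside]), bnd)
  }
  vals <- matrix(NA_real_, env$nlat, env$nlon)
  vals[cbind(cells$row[use], cells$col[use])] <- d
  structure(list(values = vals, grid = grid_of(env),
                 source_label = poly$source_label),
            class = "distance_layer")
}

# distance values at point locations (km); NA outside the layer's domain
extract_distance <- function(dist, lon, lat) {
  g <- dist$grid
  col <- floor((lon - g$extent[1]) / g$res_lon) + 1L
  row <- floor((g$extent[4] - lat) / g$res_lat) + 1L
  ok <- col >= 1 & col <= g$nlon & row >= 1 & row <= g$nlat & !is.na(col)
  out <- rep(NA_real_, length(lon))
  out[ok] <- dist$values[cbind(row[ok], col[ok])]
  out
}
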