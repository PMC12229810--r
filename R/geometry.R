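#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371 km, fully vectorised.
#'
#' @param from,to two-column matrices (lon, lat) in degrees.
#' @return numeric matrix, \code{nrow(from)} x \code{nrow(to)}.
#' @export
haversine_km <- function(from, to) {
  from <- matrix(as.numeric(from), ncol = 2)
  to <- matrix(as.numeric(to), ncol = 2)
  R <- 6371
  p1 <- from * pi / 180
  p2 <- to * pi / 180
  dlat <- outer(p1[, 2], p2[, 2], `-`)
  dlon <- outer(p1[, 1], p2[, 1], `-`)
  a <- sin(dlat / 2)^2 +
    outer(cos(p1[, 2]), cos(p2[, 2])) * sin(dlon / 2)^2
  2 * R * asin(pmin(sqrt(a), 1))
}

# minimum haversine distance (km) from each point to a set of target points,
# blocked so the full distance matrix is never materialised
min_dist_km <- function(points, targets, block = 4000L) {
  points <- matrix(as.numeric(points), ncol = 2)
  targets <- matrix(as.numeric(targets), ncol = 2)
  n <- nrow(points)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d <- haversine_km(points[idx, , drop = FALSE], targets)
    out[idx] <- do.call(pmin, as.data.frame(d))
  }
  out
}

#' Range polygon
#'
#' Polygon or multipolygon in lon/lat degrees stored as a list of closed
#' rings (first vertex repeated last). Ring orientation follows the signed
#' area: counter-clockwise rings are outer boundaries, clockwise rings are
#' holes; containment is decided by even-odd crossing.
#'
#' @param rings list of two-column matrices (lon, lat); each ring is closed
#'   automatically if needed.
#' @param source_label free-text provenance label.
#' @return object of class \code{range_polygon}.
#' @export
range_polygon <- function(rings, source_label = "") {
  stopifnot(is.list(rings), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- matrix(as.numeric(r), ncol = 2)
    if (nrow(r) < 3) stop("a ring needs at least 3 vertices")
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    r
  })
  structure(list(rings = rings, source_label = source_label),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("range_polygon: %d ring(s), %d vertices, area %.0f km^2 [%s]\n",
              length(x$rings), sum(vapply(x$rings, nrow, 1L)) - length(x$rings),
              polygon_area_km2(x), x$source_label))
  invisible(x)
}

#' Spherical polygon area (km^2)
#'
#' Signed shoelace sum in the equal-area coordinates (longitude in radians,
#' sine of latitude), scaled by R^2 (R = 6371 km). Exact for boundaries made
#' of constant-longitude and constant-latitude segments (as produced by
#' \code{\link{cells_to_polygon}}); for general boundaries it treats edges as
#' straight in those coordinates.
#'
#' @param poly a \code{range_polygon}.
#' @return total area in km^2 (holes subtract).
#' @export
polygon_area_km2 <- function(poly) {
  R <- 6371
  signed <- vapply(poly$rings, function(r) {
    x <- r[, 1] * pi / 180
    y <- sin(r[, 2] * pi / 180)
    n <- nrow(r)
    sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
  }, numeric(1))
  R^2 * sum(signed)
}

#' Even-odd point-in-polygon test
#'
#' @param poly a \code{range_polygon}.
#' @param lon,lat point coordinates (degrees).
#' @return logical vector; boundary points within a small snapping tolerance
#'   count as inside.
#' @export
point_in_polygon <- function(poly, lon, lat) {
  bnd <- do.call(rbind, lapply(poly$rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  pts <- cbind(lon, lat)
  inside <- mgcv::in.out(bnd, pts)
  # in.out is open on part of the boundary; snap near-boundary points inside
  on_b <- on_boundary(poly, lon, lat, tol = 1e-9)
  inside | on_b
}

# vertex/edge membership test in lon/lat coordinates (planar, tolerance in
# degrees) -- used only to make boundary points count as inside
on_boundary <- function(poly, lon, lat, tol = 1e-9) {
  res <- rep(FALSE, length(lon))
  for (r in poly$rings) {
    n <- nrow(r)
    for (k in seq_len(n - 1)) {
      ax <- r[k, 1]; ay <- r[k, 2]; bx <- r[k + 1, 1]; by <- r[k + 1, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      if (L2 == 0) next
      t <- ((lon - ax) * vx + (lat - ay) * vy) / L2
      t <- pmin(1, pmax(0, t))
      d2 <- (lon - (ax + t * vx))^2 + (lat - (ay + t * vy))^2
      res <- res | (d2 <= tol^2)
    }
  }
  res
}

#' Densify polygon boundary for distance computation
#'
#' Resamples every ring segment at a step no larger than \code{step_deg}
#' degrees so that distance-to-boundary queries are bounded by the sampling
#' step.
#'
#' @param poly a \code{range_polygon}.
#' @param step_deg maximum vertex spacing (degrees).
#' @return two-column matrix of boundary points.
#' @export
densify_boundary <- function(poly, step_deg = 0.05) {
  pts <- lapply(poly$rings, function(r) {
    n <- nrow(r)
    seg <- lapply(seq_len(n - 1), function(k) {
      a <- r[k, ]; b <- r[k + 1, ]
      len <- max(abs(b - a))
      m <- max(1L, ceiling(len / step_deg))
      t <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    })
    do.call(rbind, seg)
  })
  do.call(rbind, pts)
}

#' Trace the outline of a set of grid cells into a polygon
#'
#' Exact rectilinear boundary of the union of the flagged cells: the returned
#' rings run along cell edges, so the polygon's spherical area equals the sum
#' of the member cells' areas and every flagged cell centre is inside. Holes
#' (enclosed unflagged cells) become clockwise rings.
#'
#' @param env an \code{env_stack} providing the grid geometry.
#' @param cells logical matrix (nlat x nlon) flagging member cells.
#' @param source_label label for the resulting polygon.
#' @return a \code{range_polygon}.
#' @export
cells_to_polygon <- function(env, cells, source_label = "cell union") {
  stopifnot(identical(dim(cells), c(env$nlat, env$nlon)))
  if (!any(cells)) stop("no cells flagged; cannot trace an empty polygon")
  nlon <- env$nlon; nlat <- env$nlat
  occ <- function(r, c) {
    ok <- r >= 1 & r <= nlat & c >= 1 & c <= nlon
    out <- rep(FALSE, length(r))
    out[ok] <- cells[cbind(r[ok], c[ok])]
    out
  }
  which_occ <- which(cells, arr.ind = TRUE)
  r <- which_occ[, 1]; c <- which_occ[, 2]
  # corner lattice: i in 0..nlon (x/lon), j in 0..nlat (y/lat, from south)
  # cell (r, c) spans i in [c-1, c], j in [nlat-r, nlat-r+1]
  jb <- nlat - r      # bottom corner row of the cell
  jt <- nlat - r + 1  # top
  il <- c - 1; ir <- c
  edges_from <- integer(0); edges_to <- integer(0)
  cid <- function(i, j) j * (nlon + 1L) + i + 1L
  add <- function(fi, fj, ti, tj) {
    edges_from <<- c(edges_from, cid(fi, fj))
    edges_to <<- c(edges_to, cid(ti, tj))
  }
  # directed so the interior lies on the left (outer rings CCW, holes CW)
  s <- !occ(r + 1, c); if (any(s)) add(il[s], jb[s], ir[s], jb[s])  # south: east
  n <- !occ(r - 1, c); if (any(n)) add(ir[n], jt[n], il[n], jt[n])  # north: west
  w <- !occ(r, c - 1); if (any(w)) add(il[w], jt[w], il[w], jb[w])  # west: south
  e <- !occ(r, c + 1); if (any(e)) add(ir[e], jb[e], ir[e], jt[e])  # east: north
  rings <- chain_edges(edges_from, edges_to, nlon)
  to_lonlat <- function(ids) {
    ids <- ids - 1L
    i <- ids %% (nlon + 1L)
    j <- ids %/% (nlon + 1L)
    cbind(env$extent[1] + i * env$res_lon, env$extent[3] + j * env$res_lat)
  }
  rings <- lapply(rings, function(ids) simplify_ring(to_lonlat(ids)))
  range_polygon(rings, source_label)
}

# chain directed lattice edges into closed rings; at corners where two
# boundary edges leave (diagonal cell contact) prefer the left turn, which
# keeps touching rings separate
chain_edges <- function(from, to, nlon) {
  m <- length(from)
  ord <- order(from)
  sorted_from <- from[ord]
  first <- match(unique(sorted_from), sorted_from)
  starts <- unique(sorted_from)
  used <- rep(FALSE, m)
  out_edges <- split(ord, from[ord])
  dir_of <- function(a, b) {
    d <- b - a
    if (d == 1L) 1L else if (d == -1L) 3L          # east / west
    else if (d == (nlon + 1L)) 2L else 4L          # north / south
  }
  rings <- list()
  for (e0 in seq_len(m)) {
    if (used[e0]) next
    ring <- from[e0]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring <- c(ring, to[cur])
      if (to[cur] == ring[1]) break
      cand <- out_edges[[as.character(to[cur])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) stop("boundary tracing failed: open chain")
      if (length(cand) > 1) {
        incoming <- dir_of(from[cur], to[cur])
        # turn preference: left, straight, right (relative to incoming)
        pref <- c((incoming %% 4L) + 1L, incoming, ((incoming + 2L) %% 4L) + 1L)
        dirs <- vapply(cand, function(k) dir_of(from[k], to[k]), 1L)
        cand <- cand[order(match(dirs, pref))]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

# drop collinear intermediate vertices from a closed rectilinear ring
simplify_ring <- function(r) {
  n <- nrow(r)
  if (n <= 4) return(r)
  open <- r[-n, , drop = FALSE]
  m <- nrow(open)
  keep <- vapply(seq_len(m), function(k) {
    p <- open[((k - 2) %% m) + 1, ]; q <- open[k, ]; s <- open[(k %% m) + 1, ]
    cross <- (q[1] - p[1]) * (s[2] - q[2]) - (q[2] - p[2]) * (s[1] - q[1])
    abs(cross) > 1e-12
  }, logical(1))
  out <- open[keep, , drop = FALSE]
  rbind(out, out[1, ])
}

#' Write a range polygon as GeoJSON
#'
#' @param poly a \code{range_polygon}.
#' @param path output file path.
#' @export
write_polygon_geojson <- function(poly, path) {
  coords <- lapply(poly$rings, function(r) {
    lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
  })
  obj <- list(
    type = "Feature",
    properties = list(source_label = poly$source_label),
    geometry = list(type = "Polygon", coordinates = coords))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a GeoJSON Polygon/MultiPolygon into a range_polygon
#'
#' Accepts a Feature, FeatureCollection (first feature used) or bare
#' geometry; all rings of all parts are collected.
#'
#' @param path GeoJSON file path.
#' @return a \code{range_polygon}.
#' @export
read_polygon_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  geom <- if (!is.null(obj$geometry)) obj$geometry
          else if (!is.null(obj$features)) obj$features[[1]]$geometry
          else obj
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  rings <- switch(geom$type,
    Polygon = lapply(geom$coordinates, ring_mat),
    MultiPolygon = do.call(c, lapply(geom$coordinates,
                                     function(part) lapply(part, ring_mat))),
    stop("unsupported GeoJSON geometry type: ", geom$type))
  label <- if (!is.null(obj$properties$source_label))
    obj$properties$source_label else basename(path)
  range_polygon(rings, label)
}
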