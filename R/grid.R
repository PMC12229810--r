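#' Gridded environmental stack
#'
#' A lightweight container for co-registered environmental layers on a regular
#' lon/lat grid (EPSG:4326 cell-centre registration). Layers are stored as
#' matrices with rows indexed by latitude (row 1 = northernmost row, matching
#' raster conventions) and columns by longitude (col 1 = westernmost).
#'
#' @param layers named list of numeric matrices, all with identical dimensions.
#' @param extent numeric vector \code{c(lon_min, lon_max, lat_min, lat_max)}
#'   in decimal degrees, outer edges of the grid.
#' @param mask logical matrix of the same dimension; \code{FALSE} marks
#'   nodata cells (land, missing coverage). Default: all cells valid.
#' @return an object of class \code{env_stack}.
#' @export
env_stack <- function(layers, extent, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- dim(layers[[1]])
  for (l in layers) stopifnot(identical(dim(l), dims))
  nlat <- dims[1]; nlon <- dims[2]
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  stopifnot(identical(dim(mask), dims))
  res_lon <- (extent[2] - extent[1]) / nlon
  res_lat <- (extent[4] - extent[3]) / nlat
  structure(list(
    layers = layers,
    extent = as.numeric(extent),
    mask = mask,
    nlon = nlon, nlat = nlat,
    res_lon = res_lon, res_lat = res_lat,
    # cell centres; lat[1] is the northernmost row centre
    lon = extent[1] + (seq_len(nlon) - 0.5) * res_lon,
    lat = extent[4] - (seq_len(nlat) - 0.5) * res_lat
  ), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on %d x %d grid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$nlat, x$nlon))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g], resolution %g x %g deg\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              x$res_lon, x$res_lat))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), x$nlat * x$nlon))
  invisible(x)
}

#' Map lon/lat coordinates to grid cell indices
#'
#' @param env an \code{env_stack}.
#' @param lon,lat coordinate vectors (degrees).
#' @return data.frame with columns \code{row}, \code{col} (NA when a point
#'   falls outside the grid extent).
#' @export
cell_index <- function(env, lon, lat) {
  col <- floor((lon - env$extent[1]) / env$res_lon) + 1L
  row <- floor((env$extent[4] - lat) / env$res_lat) + 1L
  # points exactly on the east/north edge belong to the last cell
  col[lon == env$extent[2]] <- env$nlon
  row[lat == env$extent[3]] <- env$nlat
  bad <- col < 1L | col > env$nlon | row < 1L | row > env$nlat
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at point locations
#'
#' @inheritParams cell_index
#' @param layers character vector of layer names (default: all).
#' @return data.frame of layer values, one row per point; NA outside the grid
#'   or on masked cells.
#' @export
extract_env <- function(env, lon, lat, layers = names(env$layers)) {
  idx <- cell_index(env, lon, lat)
  lin <- (idx$col - 1L) * env$nlat + idx$row
  on_grid <- !is.na(lin)
  valid <- on_grid
  valid[on_grid] <- env$mask[lin[on_grid]]
  out <- lapply(env$layers[layers], function(m) {
    v <- rep(NA_real_, length(lon))
    v[valid] <- m[lin[valid]]
    v
  })
  as.data.frame(out)
}

#' Per-cell spherical area for each grid row
#'
#' Area of one cell in each latitude row, by the spherical-strip formula
#' A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom)), R = 6371 km.
#'
#' @param env an \code{env_stack}.
#' @return numeric vector of length \code{nlat} (km^2), row 1 northernmost.
#' @export
cell_area_km2 <- function(env) {
  R <- 6371
  top <- env$lat + env$res_lat / 2
  bot <- env$lat - env$res_lat / 2
  R^2 * (env$res_lon * pi / 180) * (sin(top * pi / 180) - sin(bot * pi / 180))
}

#' Long-format data.frame of all cells
#'
#' @param env an \code{env_stack}.
#' @param unmasked_only drop masked cells.
#' @return data.frame with row, col, lon, lat and one column per layer.
#' @export
as_cell_table <- function(env, unmasked_only = TRUE) {
  grid <- expand.grid(row = seq_len(env$nlat), col = seq_len(env$nlon))
  grid$lon <- env$lon[grid$col]
  grid$lat <- env$lat[grid$row]
  for (nm in names(env$layers)) grid[[nm]] <- as.vector(env$layers[[nm]])
  if (unmasked_only) grid <- grid[as.vector(env$mask), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Suitability map on the grid of an env_stack
#'
#' @param env an \code{env_stack} providing the grid.
#' @param values numeric matrix (nlat x nlon) of per-cell suitability in
#'   [0, 1]; NA outside the prediction domain.
#' @param provenance free-text label (algorithm + hyperparameters).
#' @return object of class \code{suitability_map}.
#' @export
suitability_map <- function(env, values, provenance = "") {
  stopifnot(identical(dim(values), c(env$nlat, env$nlon)))
  finite <- values[!is.na(values)]
  if (length(finite) && (min(finite) < -1e-12 || max(finite) > 1 + 1e-12))
    stop("suitability values must lie in [0, 1]")
  structure(list(values = values, grid = grid_of(env),
                 provenance = provenance),
            class = "suitability_map")
}

# grid geometry shared by maps/layers derived from an env_stack
grid_of <- function(env) {
  env[c("extent", "nlon", "nlat", "res_lon", "res_lat", "lon", "lat")]
}

stopifnot_same_grid <- function(a, b) {
  ga <- if (inherits(a, "env_stack")) grid_of(a) else a$grid
  gb <- if (inherits(b, "env_stack")) grid_of(b) else b$grid
  if (!isTRUE(all.equal(ga$extent, gb$extent)) || ga$nlon != gb$nlon ||
      ga$nlat != gb$nlat)
    stop("grids are not co-registered")
  invisible(TRUE)
}

#' Write a grid layer as an ESRI ASCII raster (.asc)
#'
#' Plain-text single-band raster interchange format readable by standard GIS
#' software; cell-centre coordinates follow EPSG:4326.
#'
#' @param values numeric matrix (nlat x nlon, row 1 north).
#' @param env an \code{env_stack} providing grid geometry.
#' @param path output file path.
#' @param digits significant digits written.
#' @export
write_asc <- function(values, env, path, digits = 7) {
  stopifnot(identical(dim(values), c(env$nlat, env$nlon)))
  if (abs(env$res_lon - env$res_lat) > 1e-9)
    stop("ESRI ASCII grids require square cells")
  hdr <- c(
    sprintf("ncols %d", env$nlon),
    sprintf("nrows %d", env$nlat),
    sprintf("xllcorner %.10g", env$extent[1]),
    sprintf("yllcorner %.10g", env$extent[3]),
    sprintf("cellsize %.10g", env$res_lon),
    "NODATA_value -9999")
  v <- values
  v[is.na(v)] <- -9999
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster written by \code{\link{write_asc}}
#'
#' @param path .asc file path.
#' @return list with \code{values} matrix (NA for nodata) and \code{extent}.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner"); cs <- val("cellsize")
  nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  stopifnot(identical(dim(m), c(nrows, ncols)))
  m[m == nodata] <- NA_real_
  list(values = m,
       extent = c(xll, xll + ncols * cs, yll, yll + nrows * cs))
}

#' Reconstruct an env_stack from .asc layer files
#'
#' @param paths named character vector of .asc paths (names become layer
#'   names).
#' @return an \code{env_stack}; cells that are nodata in any layer are masked.
#' @export
read_env_stack <- function(paths) {
  stopifnot(!is.null(names(paths)))
  rasters <- lapply(paths, read_asc)
  ext <- rasters[[1]]$extent
  for (r in rasters) stopifnot(isTRUE(all.equal(r$extent, ext)))
  layers <- lapply(rasters, `[[`, "values")
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  env_stack(layers, ext, mask)
}
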