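#' Occurrence preparation configuration
#'
#' Defaults follow common presence-background practice for coastal marine
#' species: records thinned to one per 0.05 degree cell, predictors screened
#' at |r| > 0.7, a 1000 km calibration buffer around the presences, and
#' 10,000 background points.
#'
#' @param thin_resolution thinning grid cell size (degrees).
#' @param corr_threshold absolute Pearson correlation cutoff in (0, 1).
#' @param buffer_km calibration-area buffer radius (km, great-circle).
#' @param n_background number of background points.
#' @param keep_list predictor names protected from collinearity removal
#'   (stands in for expert knowledge about which member of a correlated
#'   pair to keep).
#' @param seed integer seed for background sampling.
#' @return a \code{prep_config} list.
#' @export
prep_config <- function(thin_resolution = 0.05, corr_threshold = 0.7,
                        buffer_km = 1000, n_background = 10000,
                        keep_list = character(0), seed = 1) {
  stopifnot(thin_resolution > 0, corr_threshold > 0, corr_threshold < 1,
            buffer_km > 0, n_background >= 1)
  structure(list(thin_resolution = thin_resolution,
                 corr_threshold = corr_threshold,
                 buffer_km = buffer_km, n_background = n_background,
                 keep_list = keep_list, seed = as.integer(seed)),
            class = "prep_config")
}

#' Clean and spatially thin occurrence records
#'
#' Removes records with no environmental coverage (off-grid or on masked
#' cells) and keeps at most one record per \code{thin_resolution} cell. The
#' first record per cell in input order is retained, so thinning is
#' deterministic and idempotent.
#'
#' @param occ data.frame with \code{lon}, \code{lat} columns.
#' @param env an \code{env_stack} defining coverage.
#' @param cfg a \code{\link{prep_config}}.
#' @return the thinned subset of \code{occ} (original columns preserved).
#' @export
clean_and_thin <- function(occ, env, cfg = prep_config()) {
  stopifnot(nrow(occ) > 0, all(c("lon", "lat") %in% names(occ)))
  vals <- extract_env(env, occ$lon, occ$lat, layers = names(env$layers)[1])
  covered <- !is.na(vals[[1]])
  occ <- occ[covered, , drop = FALSE]
  if (nrow(occ) == 0) stop("no records with environmental coverage survive")
  ci <- floor((occ$lon - env$extent[1]) / cfg$thin_resolution)
  ri <- floor((occ$lat - env$extent[3]) / cfg$thin_resolution)
  key <- paste(ri, ci)
  out <- occ[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delineate the calibration area around the presences
#'
#' The calibration area is the set of unmasked cells whose centre lies
#' within \code{buffer_km} great-circle distance of any presence record.
#'
#' @param presences cleaned presence data.frame (lon, lat).
#' @param env an \code{env_stack}.
#' @param cfg a \code{\link{prep_config}}.
#' @return object of class \code{calibration_area}: logical matrix
#'   \code{mask} (nlat x nlon) plus grid geometry.
#' @export
build_calibration_area <- function(presences, env, cfg = prep_config()) {
  stopifnot(nrow(presences) >= 1)
  cells <- as_cell_table(env, unmasked_only = TRUE)
  d <- min_dist_km(cbind(cells$lon, cells$lat),
                   cbind(presences$lon, presences$lat))
  mask <- matrix(FALSE, env$nlat, env$nlon)
  keep <- d <= cfg$buffer_km
  mask[cbind(cells$row, cells$col)[keep, , drop = FALSE]] <- TRUE
  # presences sit at zero distance from themselves; their cells must be in
  pres_idx <- cell_index(env, presences$lon, presences$lat)
  stopifnot(all(mask[cbind(pres_idx$row, pres_idx$col)]))
  structure(list(mask = mask, grid = grid_of(env)),
            class = "calibration_area")
}

#' Sample background points within the calibration area
#'
#' Cells are drawn uniformly over the calibration area (without replacement
#' when the area has at least \code{n_background} cells, with replacement
#' otherwise) and each point is jittered uniformly within its cell. This is
#' the MaxEnt-style background definition: background may coincide with
#' presence cells.
#'
#' @param area a \code{calibration_area}.
#' @param cfg a \code{\link{prep_config}}.
#' @return data.frame with \code{lon}, \code{lat}, \code{label}
#'   (all \code{"background"}).
#' @export
sample_background <- function(area, cfg = prep_config()) {
  idx <- which(area$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty calibration area")
  g <- area$grid
  set.seed(cfg$seed)
  pick <- sample.int(nrow(idx), cfg$n_background,
                     replace = nrow(idx) < cfg$n_background)
  lon <- g$lon[idx[pick, 2]] +
    stats::runif(cfg$n_background, -0.5, 0.5) * g$res_lon
  lat <- g$lat[idx[pick, 1]] +
    stats::runif(cfg$n_background, -0.5, 0.5) * g$res_lat
  data.frame(lon = lon, lat = lat, label = "background",
             stringsAsFactors = FALSE)
}

#' Screen predictors for collinearity
#'
#' Computes pairwise Pearson correlations over calibration-area cells. While
#' any pair exceeds the threshold, the predictor with the highest mean
#' absolute correlation among the offending (non-protected) predictors is
#' dropped — a reproducible stand-in for breaking correlated pairs by expert
#' knowledge, with \code{keep_list} carrying the expert choices.
#'
#' @param env an \code{env_stack}.
#' @param area a \code{calibration_area} (or NULL to use all unmasked cells).
#' @param cfg a \code{\link{prep_config}}.
#' @return character vector of retained predictor names, in input order.
#' @export
screen_predictors <- function(env, area = NULL, cfg = prep_config()) {
  nms <- names(env$layers)
  stopifnot(length(nms) >= 2)
  sel <- if (is.null(area)) env$mask else area$mask & env$mask
  X <- vapply(env$layers, function(m) m[sel], numeric(sum(sel)))
  retained <- nms
  repeat {
    C <- abs(stats::cor(X[, retained, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= cfg$corr_threshold) break
    viol <- which(C > cfg$corr_threshold, arr.ind = TRUE)
    offenders <- unique(retained[viol[, 1]])
    droppable <- setdiff(offenders, cfg$keep_list)
    if (length(droppable) == 0)
      stop("protected predictors are mutually correlated above the ",
           "threshold: ", paste(offenders, collapse = ", "))
    mean_abs <- colMeans(C)[droppable]
    drop <- droppable[which.max(mean_abs)]
    retained <- setdiff(retained, drop)
  }
  # contract: no surviving pair above the threshold
  Cfin <- abs(stats::cor(X[, retained, drop = FALSE]))
  diag(Cfin) <- 0
  stopifnot(max(Cfin) <= cfg$corr_threshold)
  nms[nms %in% retained]
}
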