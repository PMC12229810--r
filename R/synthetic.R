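#' Virtual species configuration
#'
#' Settings for the simulated seascape and species used to validate the
#' expert-informed stacking workflow offline. The default emulates a coastal
#' north-west Pacific setting: a 120 x 120 grid over 118-130 E, 28-40 N at
#' 0.1 degree, with a hard dispersal barrier at 31.5 N (the latitude of the
#' Yangtze estuary's freshwater plume) south of which the species is absent
#' even where the environment is suitable.
#'
#' @param extent lon/lat bounding box c(lon_min, lon_max, lat_min, lat_max).
#' @param resolution cell size in degrees.
#' @param n_env number of environmental layers.
#' @param b0 intercept of the true logistic suitability surface.
#' @param beta linear coefficients (length n_env, recycled).
#' @param gamma quadratic coefficients (length n_env, recycled).
#' @param barrier_lat latitude south of which occupancy is forced to zero.
#' @param n_presence presence sample size.
#' @param sampling_bias_strength exponent >= 0: sampling weight is
#'   suitability^strength times the spatial bias kernel.
#' @param bias_kernel \code{"coastal"} (sampling effort decays eastward from
#'   the western, mainland coast) or \code{"uniform"}.
#' @param expert_buffer_km commission-error buffer: the expert polygon is the
#'   occupied area dilated by this many km.
#' @param noise_sd_cells Gaussian smoothing bandwidth (in cells) applied to
#'   the white-noise component of each layer.
#' @param noise_weight relative weight of the smoothed noise against the
#'   deterministic gradient.
#' @param seed integer RNG seed; the whole simulation is a pure function of
#'   this configuration.
#' @return a \code{virtual_species_config} list.
#' @export
virtual_species_config <- function(extent = c(118, 130, 28, 40),
                                   resolution = 0.1,
                                   n_env = 4,
                                   b0 = 0.5,
                                   beta = c(1.6, -1.2, 0.8, 0),
                                   gamma = c(-1.0, -0.6, 0, 0),
                                   barrier_lat = 31.5,
                                   n_presence = 300,
                                   sampling_bias_strength = 1,
                                   bias_kernel = c("coastal", "uniform"),
                                   expert_buffer_km = 50,
                                   noise_sd_cells = 5,
                                   noise_weight = 0.6,
                                   seed = 1) {
  stopifnot(resolution > 0, n_env >= 1, n_presence >= 1,
            expert_buffer_km >= 0, sampling_bias_strength >= 0,
            barrier_lat > extent[3], barrier_lat < extent[4])
  cfg <- list(extent = extent, resolution = resolution, n_env = n_env,
              b0 = b0,
              beta = rep_len(beta, n_env), gamma = rep_len(gamma, n_env),
              barrier_lat = barrier_lat, n_presence = n_presence,
              sampling_bias_strength = sampling_bias_strength,
              bias_kernel = match.arg(bias_kernel),
              expert_buffer_km = expert_buffer_km,
              noise_sd_cells = noise_sd_cells, noise_weight = noise_weight,
              seed = as.integer(seed))
  class(cfg) <- "virtual_species_config"
  cfg
}

# separable Gaussian smoothing with edge renormalisation
smooth_gaussian <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    padded <- c(rep(0, half), x, rep(0, half))
    ones <- c(rep(0, half), rep(1, n), rep(0, half))
    num <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
    den <- stats::filter(ones, k, sides = 2)[(half + 1):(half + n)]
    as.numeric(num / den)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Generate the virtual environmental stack
#'
#' Each layer is a deterministic large-scale gradient (a rotating mix of the
#' latitudinal and longitudinal trends, so layers are not collinear) plus
#' spatially autocorrelated noise (white noise smoothed with a Gaussian
#' kernel), standardised to mean 0 and sd 1 over unmasked cells.
#'
#' @param config a \code{\link{virtual_species_config}}.
#' @return an \code{env_stack} with layers \code{env1..envK}.
#' @export
generate_env <- function(config) {
  nlon <- round((config$extent[2] - config$extent[1]) / config$resolution)
  nlat <- round((config$extent[4] - config$extent[3]) / config$resolution)
  if (nlon < 4 || nlat < 4)
    stop("degenerate grid: need at least 4 x 4 cells")
  empty <- matrix(0, nlat, nlon)
  env0 <- env_stack(list(tmp = empty), config$extent)
  latn <- matrix(rep(scale01(env0$lat), nlon), nlat, nlon)
  lonn <- matrix(rep(scale01(env0$lon), each = nlat), nlat, nlon)
  set.seed(config$seed)
  layers <- lapply(seq_len(config$n_env), function(j) {
    theta <- (j - 1) * pi / config$n_env
    grad <- cos(theta) * latn + sin(theta) * lonn
    noise <- smooth_gaussian(matrix(stats::rnorm(nlat * nlon), nlat, nlon),
                             config$noise_sd_cells)
    raw <- grad + config$noise_weight * noise / stats::sd(noise)
    (raw - mean(raw)) / stats::sd(raw)
  })
  names(layers) <- paste0("env", seq_len(config$n_env))
  env_stack(layers, config$extent)
}

scale01 <- function(x) (x - min(x)) / (max(x) - min(x)) * 2 - 1

#' Build the species truth: suitability, occupancy, expert polygon
#'
#' True suitability is logistic in the layers with linear and quadratic
#' terms. Occupancy is Bernoulli(suitability) north of the barrier latitude
#' and zero south of it, so environmentally suitable but unoccupied habitat
#' exists beyond the barrier. The expert range polygon is the exact outline
#' of the occupied cells dilated by the commission-error buffer.
#'
#' @param env an \code{env_stack} from \code{\link{generate_env}}.
#' @param config the matching \code{\link{virtual_species_config}}.
#' @return list of class \code{truth_bundle}: \code{true_suitability}
#'   (suitability_map), \code{occupancy} (0/1 matrix), \code{expert_polygon}
#'   (range_polygon), \code{barrier_lat}, and \code{config}.
#' @export
make_truth <- function(env, config) {
  stopifnot(length(env$layers) == config$n_env)
  eta <- matrix(config$b0, env$nlat, env$nlon)
  for (j in seq_len(config$n_env)) {
    x <- env$layers[[j]]
    eta <- eta + config$beta[j] * x + config$gamma[j] * x^2
  }
  suit <- stats::plogis(eta)
  suit[!env$mask] <- NA
  set.seed(config$seed + 1L)
  occ <- matrix(0L, env$nlat, env$nlon)
  draw <- matrix(stats::runif(env$nlat * env$nlon), env$nlat, env$nlon)
  occ[env$mask & draw < suit] <- 1L
  south <- env$lat < config$barrier_lat
  occ[south, ] <- 0L
  if (sum(occ) == 0)
    stop("simulation failure: occupancy is zero everywhere ",
         "(true suitability too low)")
  # the headline experiment needs suitable-but-unoccupied southern habitat
  south_suit <- suit[south, , drop = FALSE]
  if (!any(south_suit > 0.5, na.rm = TRUE))
    warning("no suitable habitat south of the barrier; ",
            "a barrier-exclusion contrast on this species would be vacuous")
  expert_cells <- dilate_cells(env, occ == 1L, config$expert_buffer_km)
  poly <- cells_to_polygon(env, expert_cells,
                           source_label = "synthetic expert range")
  structure(list(true_suitability = suitability_map(env, suit, "truth"),
                 occupancy = occ,
                 expert_polygon = poly,
                 barrier_lat = config$barrier_lat,
                 config = config),
            class = "truth_bundle")
}

# cells within buffer_km (great-circle) of any member cell centre.
# Exact morphological dilation: for every latitude-row offset the maximum
# admissible column offset is solved from the haversine formula, then the
# per-row membership is OR-ed over a sliding column window of that width.
dilate_cells <- function(env, cells, buffer_km) {
  if (buffer_km <= 0) return(cells)
  R <- 6371
  rad <- pi / 180
  lat <- env$lat
  km_per_row <- 2 * R * asin(sin(env$res_lat * rad / 2))
  w_lat <- ceiling(buffer_km / km_per_row)
  out <- matrix(FALSE, env$nlat, env$nlon)
  sin2_buf <- sin(buffer_km / (2 * R))^2
  for (dr in -w_lat:w_lat) {
    rows <- seq_len(env$nlat)
    src_rows <- rows + dr
    ok <- src_rows >= 1 & src_rows <= env$nlat
    rows <- rows[ok]; src_rows <- src_rows[ok]
    dlat <- abs(lat[rows] - lat[src_rows]) * rad
    rhs <- (sin2_buf - sin(dlat / 2)^2) /
      (cos(lat[rows] * rad) * cos(lat[src_rows] * rad))
    feasible <- rhs >= 0
    dlon_max <- rep(-1, length(rows))
    dlon_max[feasible] <- 2 * asin(pmin(sqrt(rhs[feasible]), 1)) / rad
    dc_max <- floor(dlon_max / env$res_lon + 1e-12)
    for (k in seq_along(rows)) {
      if (dc_max[k] < 0) next
      src <- cells[src_rows[k], ]
      hit <- if (dc_max[k] == 0) src else {
        win <- 2 * dc_max[k] + 1
        padded <- c(rep(FALSE, dc_max[k]), src, rep(FALSE, dc_max[k]))
        S <- c(0, cumsum(padded))
        (S[seq_len(env$nlon) + win] - S[seq_len(env$nlon)]) > 0
      }
      out[rows[k], ] <- out[rows[k], ] | hit
    }
  }
  out | cells
}

#' Sample biased presence records from the occupied cells
#'
#' Draws \code{n_presence} occupied cells without replacement with weight
#' proportional to suitability^bias_strength times the spatial bias kernel,
#' then jitters each point uniformly within its cell — mimicking
#' opportunistic, spatially biased occurrence data.
#'
#' @param truth a \code{truth_bundle} from \code{\link{make_truth}}.
#' @param config the matching \code{\link{virtual_species_config}}.
#' @return data.frame with columns \code{lon}, \code{lat},
#'   \code{label} (all \code{"presence"}).
#' @export
sample_presences <- function(truth, config) {
  env_grid <- truth$true_suitability$grid
  occ_idx <- which(truth$occupancy == 1L, arr.ind = TRUE)
  if (nrow(occ_idx) < config$n_presence)
    stop("insufficient occupied cells (", nrow(occ_idx), ") for n_presence = ",
         config$n_presence)
  suit <- truth$true_suitability$values[occ_idx]
  lon <- env_grid$lon[occ_idx[, 2]]
  lat <- env_grid$lat[occ_idx[, 1]]
  kern <- if (config$bias_kernel == "coastal") {
    scale <- (env_grid$extent[2] - env_grid$extent[1]) / 3
    exp(-(lon - env_grid$extent[1]) / scale)
  } else rep(1, nrow(occ_idx))
  w <- suit^config$sampling_bias_strength * kern
  set.seed(config$seed + 2L)
  pick <- sample.int(nrow(occ_idx), config$n_presence, prob = w,
                     replace = FALSE)
  jit_lon <- stats::runif(config$n_presence, -0.5, 0.5) * env_grid$res_lon
  jit_lat <- stats::runif(config$n_presence, -0.5, 0.5) * env_grid$res_lat
  data.frame(lon = lon[pick] + jit_lon, lat = lat[pick] + jit_lat,
             label = "presence", stringsAsFactors = FALSE)
}

#' Run the full virtual-species simulation
#'
#' Convenience wrapper: environment, truth and presence sample from one
#' configuration. Deterministic given the configuration.
#'
#' @param config a \code{\link{virtual_species_config}}.
#' @return list with \code{env}, \code{truth} and \code{presences}.
#' @export
simulate_virtual_species <- function(config = virtual_species_config()) {
  env <- generate_env(config)
  truth <- make_truth(env, config)
  presences <- sample_presences(truth, config)
  list(env = env, truth = truth, presences = presences, config = config)
}

#' Write simulation fixtures to a directory
#'
#' Environmental layers as ESRI ASCII grids, presences as CSV (lon, lat) and
#' the expert polygon as GeoJSON.
#'
#' @param sim output of \code{\link{simulate_virtual_species}}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$env$layers))
    write_asc(sim$env$layers[[nm]], sim$env, file.path(dir, paste0(nm, ".asc")))
  utils::write.csv(sim$presences[, c("lon", "lat")],
                   file.path(dir, "presences.csv"), row.names = FALSE)
  write_polygon_geojson(sim$truth$expert_polygon,
                        file.path(dir, "expert_range.geojson"))
  write_asc(sim$truth$true_suitability$values, sim$env,
            file.path(dir, "true_suitability.asc"))
  invisible(dir)
}
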