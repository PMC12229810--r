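#' Run the full expert-informed stacking workflow
#'
#' End-to-end driver: thin occurrences, delineate the calibration area,
#' sample background, screen predictors, tune and fit the four base
#' learners, build the distance layer, fit both meta-learner variants
#' (occurrence-only and expert-informed), project all maps, and binarize
#' each ensemble at its 10 percent omission threshold.
#'
#' @param env an \code{env_stack}.
#' @param occurrences presence data.frame (lon, lat).
#' @param expert_poly a \code{range_polygon}.
#' @param prep a \code{\link{prep_config}}.
#' @param k cross-validation folds.
#' @param maxent_grid,rf_grid candidate lists (NULL = package defaults from
#'   \code{\link{tune_candidate_grid}}).
#' @param stack_mode stacking mode for the meta tables.
#' @param omission_rate binarization omission rate.
#' @param seed master seed (folds; background sampling uses
#'   \code{prep$seed}).
#' @param validate_single cross-validate the single-candidate learners
#'   (GLM/GAM) for reporting; disable to save the fold loop when only the
#'   final maps are needed.
#' @return list of class \code{sdm_pipeline_result} with the fitted models,
#'   maps, meta fits, thresholds, binary maps and bookkeeping (retained
#'   predictors, seeds, modes).
#' @export
run_sdm_pipeline <- function(env, occurrences, expert_poly,
                             prep = prep_config(),
                             k = 10,
                             maxent_grid = NULL, rf_grid = NULL,
                             stack_mode = "out_of_fold",
                             omission_rate = 0.10,
                             seed = 1,
                             validate_single = TRUE) {
  presences <- clean_and_thin(occurrences, env, prep)
  area <- build_calibration_area(presences, env, prep)
  background <- sample_background(area, prep)
  predictors <- screen_predictors(env, area, prep)
  train <- make_training_table(presences, background, env, predictors,
                               k = k, seed = seed)
  base <- list(
    GLM = tune_algorithm(train, predictors, "GLM",
                         validate_single = validate_single),
    GAM = tune_algorithm(train, predictors, "GAM",
                         validate_single = validate_single),
    MAXENT = tune_algorithm(train, predictors, "MAXENT", grid = maxent_grid),
    RF = tune_algorithm(train, predictors, "RF", grid = rf_grid))
  dist <- distance_to_range(expert_poly, env, area,
                            step_deg = min(0.05, env$res_lon / 2))
  base_pred <- stack_base_predictions(base, train, mode = stack_mode)
  meta_occ <- fit_meta(build_meta_table(base, train, dist = NULL,
                                        mode = stack_mode,
                                        base_pred = base_pred))
  meta_exp <- fit_meta(build_meta_table(base, train, dist = dist,
                                        mode = stack_mode,
                                        base_pred = base_pred))
  base_maps <- lapply(base, predict_map, env = env, area = area)
  map_occ <- predict_ensemble(meta_occ, base_maps)
  map_exp <- predict_ensemble(meta_exp, base_maps, dist = dist)
  pres_rows <- train[train$label == 1L, , drop = FALSE]
  ens_train_pred <- function(map) {
    v <- extract_distance(list(values = map$values, grid = map$grid),
                          pres_rows$lon, pres_rows$lat)
    stopifnot(!anyNA(v))
    v
  }
  thr_occ <- omission_threshold(ens_train_pred(map_occ), rate = omission_rate)
  thr_exp <- omission_threshold(ens_train_pred(map_exp), rate = omission_rate)
  structure(list(
    presences = presences, background = background, area = area,
    predictors = predictors, train = train,
    base_models = base, base_maps = base_maps,
    dist = dist,
    meta_occ = meta_occ, meta_exp = meta_exp,
    map_occ = map_occ, map_exp = map_exp,
    thr_occ = thr_occ, thr_exp = thr_exp,
    bin_occ = binarize(map_occ, thr_occ),
    bin_exp = binarize(map_exp, thr_exp),
    coefficient_table = meta_coefficient_table(meta_occ, meta_exp),
    settings = list(k = k, stack_mode = stack_mode,
                    omission_rate = omission_rate, seed = seed,
                    prep = prep)),
    class = "sdm_pipeline_result")
}

#' Reduced tuning grids used by the barrier experiment
#'
#' Compact candidate sets (MaxEnt: LQ/LQH x rm 1/2; RF: 500 trees, m_try 2,
#' node size 1 or 10) sized for replicated simulation experiments; the full
#' defaults remain \code{\link{tune_candidate_grid}}.
#'
#' @param p number of predictors.
#' @return list with \code{maxent} and \code{rf} candidate lists.
#' @export
experiment_grids <- function(p) {
  maxent <- list(list(fc = "LQ", rm = 1), list(fc = "LQH", rm = 1),
                 list(fc = "LQ", rm = 2), list(fc = "LQH", rm = 2))
  m <- min(p, 2)
  rf <- list(list(n_trees = 500, m_try = m, min_node_size = 1),
             list(n_trees = 500, m_try = m, min_node_size = 10))
  list(maxent = maxent, rf = rf)
}

#' Barrier-exclusion experiment on the virtual species
#'
#' The headline validation: simulate a species whose southern range limit
#' is set by a dispersal barrier (suitable but unoccupied habitat south of
#' it), run the full pipeline, and compare the two ensembles' binary maps
#' south of the barrier. Expert-map integration should (i) shrink the
#' suitable area predicted south of the barrier, (ii) move the southernmost
#' suitable latitude north, and (iii) raise the fraction of suitable area
#' inside the expert polygon, with a negative meta-coefficient on distance.
#'
#' @param seed simulation seed (drives the virtual species, the background
#'   draw and the fold assignment).
#' @param config virtual species configuration.
#' @param prep prep configuration; default thins at the grid resolution and
#'   uses the standard 1000-km buffer and 10,000 background points.
#' @return one-row data.frame with the south-of-barrier areas, southernmost
#'   suitable latitudes, percent-within-expert values, the distance
#'   coefficient and its p-value, plus the pipeline result as attribute
#'   \code{"result"}.
#' @export
run_barrier_experiment <- function(seed = 1,
                                   config = virtual_species_config(seed = seed),
                                   prep = NULL) {
  sim <- simulate_virtual_species(config)
  if (is.null(prep))
    prep <- prep_config(thin_resolution = config$resolution,
                        seed = seed + 1000L)
  grids <- experiment_grids(p = config$n_env)
  res <- run_sdm_pipeline(sim$env, sim$presences, sim$truth$expert_polygon,
                          prep = prep,
                          maxent_grid = grids$maxent, rf_grid = grids$rf,
                          stack_mode = "out_of_fold", seed = seed,
                          validate_single = FALSE)
  s_occ <- summarize_range(res$bin_occ, sim$truth$expert_polygon)
  s_exp <- summarize_range(res$bin_exp, sim$truth$expert_polygon)
  dist_coef <- res$meta_exp$coefficients[["distance_km"]]
  dist_p <- res$meta_exp$p_values_lrt[["distance_km"]]
  out <- data.frame(
    seed = seed,
    area_south_occ = area_south_of(res$bin_occ, config$barrier_lat),
    area_south_exp = area_south_of(res$bin_exp, config$barrier_lat),
    southern_lat_occ = s_occ$southernmost_lat,
    southern_lat_exp = s_exp$southernmost_lat,
    pct_within_occ = s_occ$pct_within_expert,
    pct_within_exp = s_exp$pct_within_expert,
    area_occ = s_occ$area_km2,
    area_exp = s_exp$area_km2,
    dist_coef = dist_coef,
    dist_p = dist_p)
  attr(out, "result") <- res
  attr(out, "sim") <- sim
  out
}

#' Replicate the barrier experiment over seeds
#'
#' @param seeds integer vector of simulation seeds.
#' @param ... passed to \code{\link{run_barrier_experiment}}.
#' @return data.frame with one row per seed and logical columns for the
#'   three exclusion inequalities and the distance-coefficient sign test.
#' @export
replicate_barrier_experiment <- function(seeds, ...) {
  rows <- lapply(seeds, function(s) {
    r <- run_barrier_experiment(seed = s, ...)
    attr(r, "result") <- NULL; attr(r, "sim") <- NULL
    r
  })
  out <- do.call(rbind, rows)
  out$smaller_south_area <- out$area_south_exp < out$area_south_occ
  out$limit_farther_north <- out$southern_lat_exp > out$southern_lat_occ
  out$higher_pct_within <- out$pct_within_exp > out$pct_within_occ
  out$dist_coef_negative_sig <- out$dist_coef < 0 & out$dist_p < 0.05
  out
}
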