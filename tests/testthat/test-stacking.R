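# a compact fitted-pipeline fixture shared by the stacking tests
stack_fixture <- function() {
  if (!is.null(.fixture_cache$stack)) return(.fixture_cache$stack)
  sim <- small_sim()
  prep <- prep_config(thin_resolution = sim$config$resolution,
                      n_background = 1000, buffer_km = 400, seed = 7)
  pres <- clean_and_thin(sim$presences, sim$env, prep)
  area <- build_calibration_area(pres, sim$env, prep)
  bg <- sample_background(area, prep)
  predictors <- screen_predictors(sim$env, area, prep)
  train <- make_training_table(pres, bg, sim$env, predictors, k = 5, seed = 7)
  base <- list(
    GLM = fit_sdm_glm(train, predictors),
    GAM = fit_sdm_gam(train, predictors),
    MAXENT = fit_sdm_maxent(train, predictors, fc = "LQ", rm = 1),
    RF = fit_sdm_rf(train, predictors, n_trees = 300, m_try = 2,
                    min_node_size = 10))
  dist <- distance_to_range(sim$truth$expert_polygon, sim$env, area)
  .fixture_cache$stack <- list(sim = sim, area = area, train = train,
                               base = base, dist = dist,
                               predictors = predictors)
  .fixture_cache$stack
}

test_that("the meta table has the right columns and bounded predictions", {
  fx <- stack_fixture()
  tab <- build_meta_table(fx$base, fx$train, dist = NULL, mode = "in_sample")
  expect_named(tab, c("GLM", "GAM", "MAXENT", "RF", "label"))
  for (nm in c("GLM", "GAM", "MAXENT", "RF"))
    expect_true(all(tab[[nm]] >= 0 & tab[[nm]] <= 1))
  tab_d <- build_meta_table(fx$base, fx$train, dist = fx$dist,
                            mode = "in_sample")
  expect_named(tab_d, c("GLM", "GAM", "MAXENT", "RF", "distance_km", "label"))
  expect_true(all(tab_d$distance_km >= 0))
})

test_that("out-of-fold stacking refits once per fold per algorithm", {
  fx <- stack_fixture()
  pred <- stack_base_predictions(fx$base, fx$train, mode = "out_of_fold")
  refits <- attr(pred, "refits")
  expect_equal(unname(unlist(refits)),
               rep(length(unique(fx$train$fold_id)), 4))
  # out-of-fold predictions differ from in-sample ones (no leakage)
  ins <- stack_base_predictions(fx$base, fx$train, mode = "in_sample")
  expect_false(isTRUE(all.equal(pred$RF, ins$RF)))
  # a table built from a cached prediction matrix matches a direct build
  tab1 <- build_meta_table(fx$base, fx$train, dist = fx$dist,
                           mode = "out_of_fold", base_pred = pred)
  expect_equal(tab1$GLM, pred$GLM)
  expect_error(build_meta_table(fx$base, fx$train, mode = "in_sample",
                                base_pred = pred), "mode")
})

test_that("an in-sample constant base model yields a constant column", {
  fx <- stack_fixture()
  fit0 <- glm(label ~ 1, family = binomial(), data = fx$train)
  base0 <- c(fx$base[c("GLM", "GAM", "MAXENT")],
             list(RF = sdmstack:::new_sdm_model("GLM", list(terms = "1"),
                                                fit0, fx$predictors)))
  tab <- build_meta_table(base0, fx$train, mode = "in_sample")
  expect_equal(diff(range(tab$RF)), 0, tolerance = 1e-12)
  # and fit_meta refuses the constant column
  expect_error(fit_meta(tab), "constant")
})

test_that("the meta-learner finds the informative column", {
  set.seed(31)
  n <- 5000
  z <- runif(n)
  informative <- plogis(3 * qlogis(pmin(pmax(z, 1e-6), 1 - 1e-6)))
  tab <- data.frame(
    GLM = informative,
    GAM = runif(n), MAXENT = runif(n), RF = runif(n),
    label = rbinom(n, 1, plogis(3 * qlogis(pmin(pmax(z, 1e-6), 1 - 1e-6)))))
  fit <- fit_meta(tab)
  expect_lt(fit$p_values[["GLM"]], 0.01)
  for (nm in c("GAM", "MAXENT", "RF"))
    expect_gt(fit$p_values[[nm]], 0.01)
  expect_gt(fit$coefficients[["GLM"]], 0)
})

test_that("duplicating a column flags collinearity but keeps predictions", {
  set.seed(32)
  n <- 2000
  p1 <- runif(n); p2 <- runif(n); p3 <- runif(n)
  lab <- rbinom(n, 1, plogis(2 * p1 - 1))
  tab <- data.frame(GLM = p1, GAM = p2, MAXENT = p3, label = lab)
  fit <- fit_meta(tab)
  tab_dup <- data.frame(GLM = p1, GAM = p2, MAXENT = p3,
                        RF = p1 + rnorm(n, sd = 1e-8), label = lab)
  expect_warning(fit_dup <- fit_meta(tab_dup), "collinear")
  newd <- data.frame(GLM = runif(50), GAM = runif(50), MAXENT = runif(50))
  newd$RF <- newd$GLM
  pr1 <- predict(fit$fit, newd, type = "response")
  pr2 <- predict(fit_dup$fit, newd, type = "response")
  expect_equal(unname(pr1), unname(pr2), tolerance = 1e-4)
})

test_that("ensemble projection is the inverse-logit of the meta predictor", {
  fx <- stack_fixture()
  base_maps <- lapply(fx$base, predict_map, env = fx$sim$env, area = fx$area)
  # hand-built meta fit: all coefficients zero except the intercept
  mk_fit <- function(coefs, variant, inputs) {
    structure(list(variant = variant, coefficients = coefs,
                   inputs = inputs), class = "meta_learner_fit")
  }
  b0 <- 0.7
  fit0 <- mk_fit(c("(Intercept)" = b0, GLM = 0, GAM = 0, MAXENT = 0, RF = 0),
                 "occurrence_only", c("GLM", "GAM", "MAXENT", "RF"))
  map0 <- predict_ensemble(fit0, base_maps)
  vals <- map0$values[!is.na(map0$values)]
  expect_equal(vals, rep(plogis(b0), length(vals)), tolerance = 1e-12)
  # a negative distance coefficient strictly lowers far cells
  fitd <- mk_fit(c("(Intercept)" = 0, GLM = 1, GAM = 0, MAXENT = 0, RF = 0,
                   distance_km = -0.01),
                 "expert_informed",
                 c("GLM", "GAM", "MAXENT", "RF", "distance_km"))
  mapd <- predict_ensemble(fitd, base_maps, dist = fx$dist)
  fit_nod <- mk_fit(c("(Intercept)" = 0, GLM = 1, GAM = 0, MAXENT = 0,
                      RF = 0),
                    "occurrence_only", c("GLM", "GAM", "MAXENT", "RF"))
  map_nod <- predict_ensemble(fit_nod, base_maps)
  outside <- !is.na(fx$dist$values) & fx$dist$values > 0
  expect_true(all((mapd$values < map_nod$values)[outside]))
  inside <- !is.na(fx$dist$values) & fx$dist$values == 0
  expect_equal(mapd$values[inside], map_nod$values[inside])
  # a zero distance coefficient reduces to the occurrence-only map
  fitd0 <- fitd; fitd0$coefficients[["distance_km"]] <- 0
  mapd0 <- predict_ensemble(fitd0, base_maps, dist = fx$dist)
  expect_equal(mapd0$values, map_nod$values)
  # variant/distance mismatches are errors
  expect_error(predict_ensemble(fitd, base_maps), "distance")
  expect_error(predict_ensemble(fit_nod, base_maps, dist = fx$dist),
               "no distance")
})

test_that("inside the polygon the two variants agree in rank more than outside", {
  fx <- stack_fixture()
  base_maps <- lapply(fx$base, predict_map, env = fx$sim$env, area = fx$area)
  base_pred <- stack_base_predictions(fx$base, fx$train, "out_of_fold")
  meta_occ <- fit_meta(build_meta_table(fx$base, fx$train, NULL,
                                        "out_of_fold", base_pred))
  meta_exp <- fit_meta(build_meta_table(fx$base, fx$train, fx$dist,
                                        "out_of_fold", base_pred))
  m_occ <- predict_ensemble(meta_occ, base_maps)
  m_exp <- predict_ensemble(meta_exp, base_maps, dist = fx$dist)
  ok <- !is.na(fx$dist$values)
  inside <- ok & fx$dist$values == 0
  outside <- ok & fx$dist$values > 0
  r_in <- cor(m_occ$values[inside], m_exp$values[inside],
              method = "spearman")
  r_out <- cor(m_occ$values[outside], m_exp$values[outside],
               method = "spearman")
  expect_gt(r_in, r_out)
  # inside the polygon the expert-informed map is a monotone transform of
  # the same linear predictor, so ranks agree near-perfectly
  expect_gt(r_in, 0.95)
})
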