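test_that("GLM selection returns a near-null model when labels are noise", {
  set.seed(12)
  n <- 2000
  train <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                      label = rbinom(n, 1, 0.3),
                      fold_id = rep(1:5, length.out = n),
                      lon = 0, lat = 0)
  m <- fit_sdm_glm(train, c("x1", "x2"))
  null_fit <- glm(label ~ 1, family = binomial(), data = train)
  expect_lte(m$aic, AIC(null_fit) + 2)
  # and AIC agrees with the independent -2 loglik + 2k computation
  fit <- m$fit_state
  p_hat <- fitted(fit)
  loglik <- sum(train$label * log(p_hat) + (1 - train$label) * log(1 - p_hat))
  expect_equal(m$aic, -2 * loglik + 2 * length(coef(fit)), tolerance = 1e-6)
})

test_that("GLM recovers an informative predictor with the right sign", {
  train <- logistic_train(n = 2000, b1 = 2)
  m <- fit_sdm_glm(train, c("x1", "x2", "x3"))
  expect_true("x1" %in% names(coef(m$fit_state)))
  expect_gt(coef(m$fit_state)[["x1"]], 0)
})

test_that("intercept-only GLM predicts the presence fraction everywhere", {
  set.seed(13)
  n <- 600
  train <- data.frame(x1 = rnorm(n), label = rbinom(n, 1, 0.4),
                      fold_id = rep(1:5, length.out = n), lon = 0, lat = 0)
  fit <- glm(label ~ 1, family = binomial(), data = train)
  m <- sdmstack:::new_sdm_model("GLM", list(terms = "1"), fit, "x1")
  pred <- predict_sdm(m, data.frame(x1 = c(-5, 0, 5)))
  expect_equal(pred, rep(mean(train$label), 3), tolerance = 1e-12)
})

test_that("GAM partial effect is monotone when the truth is logistic-linear", {
  train <- logistic_train(n = 3000, b1 = 2, p_extra = 1)
  m <- fit_sdm_gam(train, c("x1", "x2"))
  grid <- data.frame(x1 = seq(quantile(train$x1, 0.05),
                              quantile(train$x1, 0.95), length.out = 50),
                     x2 = 0)
  pred <- predict_sdm(m, grid)
  expect_true(all(diff(pred) > -1e-9))
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("a constant predictor contributes nothing to the GAM", {
  train <- logistic_train(n = 1500, b1 = 1.5, p_extra = 0)
  train$flat <- 1
  m <- fit_sdm_gam(train, c("x1", "flat"))
  pred_a <- predict_sdm(m, data.frame(x1 = 0.5, flat = 1))
  pred_b <- predict_sdm(m, data.frame(x1 = 0.5, flat = 99))
  expect_equal(pred_a, pred_b, tolerance = 1e-8)
})

test_that("heavy MaxEnt regularization shrinks to a constant map", {
  train <- logistic_train(n = 1200, b0 = -2.2, b1 = 2, p_extra = 1)
  m <- fit_sdm_maxent(train, c("x1", "x2"), fc = "LQH", rm = 100)
  beta <- m$fit_state$beta
  expect_true(all(abs(beta[-1]) < 1e-10))
  pred <- predict_sdm(m, data.frame(x1 = c(-2, 0, 2), x2 = c(1, 0, -1)))
  expect_equal(diff(range(pred)), 0, tolerance = 1e-12)
})

test_that("MaxEnt linear features recover the sign of the truth", {
  train <- logistic_train(n = 2000, b1 = 2, p_extra = 1)
  m <- fit_sdm_maxent(train, c("x1", "x2"), fc = "L", rm = 1)
  expect_gt(m$fit_state$beta[["x1"]], 0)
  expect_gt(abs(m$fit_state$beta[["x1"]]), abs(m$fit_state$beta[["x2"]]))
})

test_that("MaxEnt predictions are invariant to affine predictor rescaling", {
  train <- logistic_train(n = 1500, b1 = 1.5, p_extra = 1)
  newd <- data.frame(x1 = seq(-2, 2, length.out = 40),
                     x2 = seq(1, -1, length.out = 40))
  m1 <- fit_sdm_maxent(train, c("x1", "x2"), fc = "LQ", rm = 1)
  p1 <- predict_sdm(m1, newd)
  train2 <- train; train2$x1 <- 100 + 7 * train$x1
  newd2 <- newd; newd2$x1 <- 100 + 7 * newd$x1
  m2 <- fit_sdm_maxent(train2, c("x1", "x2"), fc = "LQ", rm = 1)
  p2 <- predict_sdm(m2, newd2)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("a degenerate down-sampled tree predicts 0.5 from its balanced root", {
  train <- logistic_train(n = 800, b1 = 2, p_extra = 0)
  m <- fit_sdm_rf(train, "x1", n_trees = 1, m_try = 1,
                  min_node_size = nrow(train) * 2)
  pred <- predict_sdm(m, data.frame(x1 = c(-3, 0, 3)))
  expect_equal(pred, rep(0.5, 3))
})

test_that("the forest separates a thresholded truth almost perfectly", {
  set.seed(21)
  n <- 3000
  x1 <- rnorm(n)
  train <- data.frame(x1 = x1, x2 = rnorm(n),
                      label = as.integer(x1 > 0),
                      fold_id = rep(1:5, length.out = n), lon = 0, lat = 0)
  hold <- data.frame(x1 = rnorm(800), x2 = rnorm(800))
  hold$label <- as.integer(hold$x1 > 0)
  m <- fit_sdm_rf(train, c("x1", "x2"), n_trees = 500, m_try = 1,
                  min_node_size = 1)
  pred <- predict_sdm(m, hold)
  expect_gt(auc_mw(pred[hold$label == 1], pred[hold$label == 0]), 0.95)
})

test_that("m_try beyond the predictor count is rejected", {
  train <- logistic_train(n = 300, p_extra = 1)
  expect_error(fit_sdm_rf(train, c("x1", "x2"), m_try = 5), "m_try")
})

test_that("selection keeps the lowest-omission decile then maximises AUC", {
  # hand-constructed candidate table, K = 20: the two lowest OR10 members
  # are c05 (or10 .01, auc .80) and c11 (or10 .02, auc .91) -> c11 wins
  set.seed(3)
  or10 <- c(0.30, 0.25, 0.28, 0.40, 0.01, 0.35, 0.22, 0.33, 0.27, 0.31,
            0.02, 0.26, 0.38, 0.29, 0.24, 0.36, 0.23, 0.32, 0.34, 0.21)
  auc <- c(0.85, 0.70, 0.72, 0.99, 0.80, 0.71, 0.74, 0.73, 0.75, 0.76,
           0.91, 0.77, 0.78, 0.79, 0.81, 0.69, 0.68, 0.67, 0.66, 0.65)
  cands <- lapply(1:20, function(i)
    list(id = i, validation_or10 = or10[i], validation_auc = auc[i]))
  expect_equal(tune_and_select(cands)$id, 11)
  # singleton list: returned as-is
  expect_equal(tune_and_select(cands[4])$id, 4)
  # all omission rates equal: global max AUC
  flat <- lapply(cands, function(c_) { c_$validation_or10 <- 0.1; c_ })
  expect_equal(tune_and_select(flat)$id, 4)
  expect_error(tune_and_select(list()), "empty")
})

test_that("cross-validated metrics are computed on shared folds", {
  train <- logistic_train(n = 1200, b1 = 2, p_extra = 1, k = 5)
  met <- cv_candidate_metrics(train, c("x1", "x2"), "MAXENT",
                              list(fc = "L", rm = 1))
  expect_gte(met$validation_or10, 0)
  expect_lte(met$validation_or10, 1)
  expect_gt(met$validation_auc, 0.6)  # informative truth
})

test_that("map prediction is consistent with point prediction", {
  sim <- small_sim()
  prep <- prep_config(thin_resolution = sim$config$resolution,
                      n_background = 800, buffer_km = 300, seed = 2)
  pres <- clean_and_thin(sim$presences, sim$env, prep)
  area <- build_calibration_area(pres, sim$env, prep)
  bg <- sample_background(area, prep)
  preds <- screen_predictors(sim$env, area, prep)
  train <- make_training_table(pres, bg, sim$env, preds, k = 5, seed = 3)
  m <- fit_sdm_maxent(train, preds, fc = "LQ", rm = 1)
  map <- predict_map(m, sim$env, area)
  vals <- map$values[!is.na(map$values)]
  expect_true(all(vals >= 0 & vals <= 1))
  # the prediction at a training point's cell equals the row prediction
  idx <- cell_index(sim$env, train$lon[1], train$lat[1])
  cell_df <- as_cell_table(sim$env, unmasked_only = FALSE)
  cell_row <- cell_df[cell_df$row == idx$row & cell_df$col == idx$col, ]
  expect_equal(map$values[idx$row, idx$col],
               unname(predict_sdm(m, cell_row)), tolerance = 1e-9)
  # an intercept-only model projects a constant map
  fit0 <- glm(label ~ 1, family = binomial(), data = train)
  m0 <- sdmstack:::new_sdm_model("GLM", list(terms = "1"), fit0, preds)
  map0 <- predict_map(m0, sim$env, area)
  expect_equal(diff(range(map0$values, na.rm = TRUE)), 0, tolerance = 1e-12)
})

test_that("all four algorithms fit monotone response curves to a 1-D truth", {
  # one informative predictor plus a nuisance: central-80%-range monotonicity
  train <- logistic_train(n = 2500, b1 = 2.5, p_extra = 1, seed = 99)
  algos <- list(
    GLM = fit_sdm_glm(train, c("x1", "x2")),
    GAM = fit_sdm_gam(train, c("x1", "x2")),
    MAXENT = fit_sdm_maxent(train, c("x1", "x2"), fc = "LQ", rm = 1),
    RF = fit_sdm_rf(train, c("x1", "x2"), n_trees = 500, m_try = 1,
                    min_node_size = 10))
  qs <- quantile(train$x1, c(0.1, 0.9))
  x1_grid <- seq(qs[1], qs[2], length.out = 30)
  set.seed(1)
  x2_sample <- sample(train$x2, 150)  # partial-dependence averaging
  for (nm in names(algos)) {
    resp <- vapply(x1_grid, function(v)
      mean(predict_sdm(algos[[nm]], data.frame(x1 = v, x2 = x2_sample))), 0)
    expect_gt(cor(resp, x1_grid, method = "spearman"), 0.95)
    expect_gt(resp[30], resp[1])
  }
})
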