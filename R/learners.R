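#' Assemble the presence-background training table
#'
#' One row per presence or background point with the retained predictor
#' values, a 0/1 label and a shared k-fold assignment. All four base
#' learners consume this identical table and fold split, which is what makes
#' the downstream paired model comparisons valid.
#'
#' @param presences,background data.frames with \code{lon}, \code{lat}.
#' @param env an \code{env_stack}.
#' @param predictors character vector of retained layer names.
#' @param k number of cross-validation folds.
#' @param seed seed for the random fold assignment (stratified by label).
#' @return data.frame with predictor columns, \code{label}, \code{fold_id},
#'   \code{lon}, \code{lat}.
#' @export
make_training_table <- function(presences, background, env, predictors,
                                k = 10, seed = 1) {
  pts <- rbind(
    data.frame(lon = presences$lon, lat = presences$lat, label = 1L),
    data.frame(lon = background$lon, lat = background$lat, label = 0L))
  vals <- extract_env(env, pts$lon, pts$lat, layers = predictors)
  tab <- cbind(vals, pts)
  if (anyNA(tab[predictors]))
    stop("training points with missing predictor values; clean first")
  set.seed(seed)
  assign_folds <- function(n) sample(rep_len(seq_len(k), n))
  tab$fold_id <- NA_integer_
  tab$fold_id[tab$label == 1L] <- assign_folds(sum(tab$label == 1L))
  tab$fold_id[tab$label == 0L] <- assign_folds(sum(tab$label == 0L))
  if (any(table(factor(tab$fold_id[tab$label == 1L], levels = seq_len(k))) == 0))
    stop("a fold has zero presences; use fewer folds")
  rownames(tab) <- NULL
  tab
}

new_sdm_model <- function(algorithm, hyperparams, fit_state,
                          predictors, extra = list()) {
  structure(c(list(algorithm = algorithm, hyperparams = hyperparams,
                   fit_state = fit_state, predictors = predictors,
                   validation_auc = NA_real_, validation_or10 = NA_real_),
              extra),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams),
              sep = "=", collapse = ", ")
  cat(sprintf("sdm_model [%s] (%s)  val AUC %.3f, val OR10 %.3f\n",
              x$algorithm, hp, x$validation_auc, x$validation_or10))
  invisible(x)
}

# ---------------------------------------------------------------------------
# GLM: second-order polynomial terms, backward elimination by AIC

glm_full_formula <- function(predictors) {
  terms <- c(predictors, paste0("I(", predictors, "^2)"))
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

#' Fit the polynomial logistic GLM base learner
#'
#' Binomial GLM with linear and quadratic terms for every predictor;
#' backward elimination from the full model selects the AIC-minimal term
#' set. Perfect separation triggers a warning and a ridge-stabilised refit
#' of the selected terms.
#'
#' @param train training table (see \code{\link{make_training_table}}).
#' @param predictors predictor column names.
#' @return an \code{sdm_model} with the selected \code{stats::glm} fit.
#' @export
fit_sdm_glm <- function(train, predictors) {
  stopifnot(length(predictors) >= 1)
  fit <- suppressWarnings(
    stats::step(stats::glm(glm_full_formula(predictors), data = train,
                           family = stats::binomial()),
                direction = "backward", trace = 0))
  separated <- !fit$converged || fit$boundary ||
    max(abs(stats::coef(fit))) > 1e3
  if (separated) {
    warning("perfect separation detected in GLM; using ridge-penalized ",
            "coefficients for the selected terms")
    mm <- stats::model.matrix(fit$formula, train)
    rfit <- glmnet::glmnet(mm[, -1, drop = FALSE], train$label,
                           family = "binomial", alpha = 0, lambda = 1e-4)
    fit$coefficients[] <- as.numeric(stats::coef(rfit,
                                                 s = 1e-4))[seq_along(fit$coefficients)]
  }
  new_sdm_model("GLM", list(terms = deparse1(stats::formula(fit)[[3]])),
                fit, predictors, extra = list(aic = stats::AIC(fit)))
}

# ---------------------------------------------------------------------------
# GAM: thin-plate smooths with basis dimension 3, GCV-selected penalties

#' Fit the GAM base learner
#'
#' Additive binomial model with one thin-plate regression spline (basis
#' dimension 3) per predictor; smoothing penalties chosen by generalized
#' cross-validation.
#'
#' @inheritParams fit_sdm_glm
#' @param k_basis spline basis dimension per smooth.
#' @return an \code{sdm_model} with the \code{mgcv::gam} fit.
#' @export
fit_sdm_gam <- function(train, predictors, k_basis = 3) {
  # constant columns carry no information; their smooth is identically 0,
  # so they are excluded from the basis construction
  varying <- predictors[vapply(train[predictors], function(x)
    stats::sd(x) > 0, logical(1))]
  rhs <- if (length(varying) == 0) "1"
         else paste(sprintf("s(%s, k = %d, bs = 'tp')", varying, k_basis),
                    collapse = " + ")
  f <- stats::as.formula(paste("label ~", rhs))
  fit <- mgcv::gam(f, data = train, family = stats::binomial(),
                   method = "GCV.Cp")
  if (!fit$converged)
    stop("GAM did not converge for smooth block: ",
         paste(predictors, collapse = ", "))
  new_sdm_model("GAM", list(k_basis = k_basis), fit, predictors)
}

# ---------------------------------------------------------------------------
# MaxEnt-style penalized feature regression

# per-feature default regularization weights, interpolated on the presence
# sample size (the defaults used by mainstream MaxEnt tuning workflows)
maxent_default_reg <- function(class, n_presence) {
  tab <- switch(class,
    L = list(m = c(0, 10, 30, 100), v = c(1, 1, 0.2, 0.05)),
    Q = list(m = c(0, 10, 17, 30, 100), v = c(1.3, 0.8, 0.5, 0.25, 0.05)),
    H = list(m = c(0, 1), v = c(0.5, 0.5)),
    P = list(m = c(0, 10, 17, 30, 100), v = c(2.6, 1.6, 0.9, 0.55, 0.25)))
  stats::approx(tab$m, tab$v, xout = min(n_presence, max(tab$m)),
                rule = 2)$y
}

# feature recipe frozen from the training data so train/predict agree
maxent_recipe <- function(train, predictors, fc, n_hinge = 10) {
  fc <- strsplit(toupper(fc), "")[[1]]
  stopifnot(length(fc) >= 1, all(fc %in% c("L", "Q", "H", "P")))
  center <- vapply(train[predictors], mean, 0)
  scale <- vapply(train[predictors], stats::sd, 0)
  scale[scale == 0] <- 1
  hinges <- if ("H" %in% fc) {
    lapply(train[predictors], function(x)
      list(knots = unique(stats::quantile(x, seq(0.05, 0.95,
                                                 length.out = n_hinge))),
           min = min(x), max = max(x)))
  } else NULL
  list(predictors = predictors, fc = fc, center = center, scale = scale,
       hinges = hinges)
}

maxent_features <- function(recipe, data) {
  Z <- as.matrix(data[recipe$predictors])
  Z <- sweep(sweep(Z, 2, recipe$center), 2, recipe$scale, "/")
  colnames(Z) <- recipe$predictors
  feats <- list(); classes <- character(0)
  if ("L" %in% recipe$fc) {
    feats$L <- Z
    classes <- c(classes, rep("L", ncol(Z)))
  }
  if ("Q" %in% recipe$fc) {
    Q <- Z^2
    colnames(Q) <- paste0(recipe$predictors, "_sq")
    feats$Q <- Q
    classes <- c(classes, rep("Q", ncol(Q)))
  }
  if ("H" %in% recipe$fc) {
    H <- do.call(cbind, lapply(recipe$predictors, function(p) {
      x <- data[[p]]
      h <- recipe$hinges[[p]]
      fwd <- vapply(h$knots, function(t)
        pmax(0, x - t) / max(h$max - t, 1e-12), numeric(length(x)))
      rev <- vapply(h$knots, function(t)
        pmax(0, t - x) / max(t - h$min, 1e-12), numeric(length(x)))
      m <- cbind(fwd, rev)
      colnames(m) <- c(paste0(p, "_hf", seq_along(h$knots)),
                       paste0(p, "_hr", seq_along(h$knots)))
      m
    }))
    feats$H <- H
    classes <- c(classes, rep("H", ncol(H)))
  }
  if ("P" %in% recipe$fc && length(recipe$predictors) >= 2) {
    pairs <- utils::combn(recipe$predictors, 2)
    P <- apply(pairs, 2, function(pr) Z[, pr[1]] * Z[, pr[2]])
    colnames(P) <- apply(pairs, 2, paste, collapse = "_x_")
    feats$P <- P
    classes <- c(classes, rep("P", ncol(P)))
  }
  X <- do.call(cbind, feats)
  list(X = X, classes = classes)
}

#' Fit the MaxEnt-style penalized regression base learner
#'
#' L1-penalized binomial regression on a MaxEnt feature expansion of the
#' predictors: standardized linear (L), quadratic (Q), hinge (H, forward and
#' reverse hinges at 10 sample quantiles per predictor) and pairwise product
#' (P) features. Per-feature penalties follow the MaxEnt class defaults
#' (scaled by the presence sample size) times the regularization multiplier
#' \code{rm}. Suitability is the inverse complementary log-log of the fitted
#' linear predictor, giving values in (0, 1).
#'
#' @inheritParams fit_sdm_glm
#' @param fc feature classes as a string, e.g. \code{"LQH"}.
#' @param rm regularization multiplier (> 0).
#' @return an \code{sdm_model} holding the penalized coefficients and the
#'   feature recipe.
#' @export
fit_sdm_maxent <- function(train, predictors, fc = "LQH", rm = 1) {
  if (rm <= 0) stop("regularization multiplier must be positive")
  recipe <- maxent_recipe(train, predictors, fc)
  fx <- maxent_features(recipe, train)
  np <- sum(train$label == 1L)
  reg <- vapply(fx$classes, maxent_default_reg, 0, n_presence = np)
  # overall penalty level: rm times the mean class default, shrinking with
  # the presence sample size; per-feature weights keep the class ratios
  lambda <- rm * mean(reg) / sqrt(np)
  fit <- glmnet::glmnet(fx$X, train$label, family = "binomial",
                        penalty.factor = reg / mean(reg), standardize = FALSE,
                        lambda = lambda * c(64, 16, 4, 1))
  beta <- as.numeric(stats::coef(fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(fx$X))
  new_sdm_model("MAXENT", list(fc = fc, rm = rm),
                list(beta = beta, recipe = recipe), predictors)
}

# ---------------------------------------------------------------------------
# Down-sampled random forest

#' Fit the down-sampled random forest base learner
#'
#' Probability forest in which every tree is grown on a bootstrap sample of
#' the presences plus an equal-sized random subsample of the background, so
#' each tree sees a balanced class mix (the down-sampling treatment for the
#' heavy presence/background imbalance). Predictions average the terminal
#' node presence fractions across trees.
#'
#' @inheritParams fit_sdm_glm
#' @param n_trees number of trees.
#' @param m_try predictors tried per split (must not exceed the predictor
#'   count).
#' @param min_node_size minimum terminal node size.
#' @param seed forest RNG seed.
#' @param check_downsampling verify the per-tree class balance from the
#'   in-bag counts (adds bookkeeping cost; on by default).
#' @return an \code{sdm_model} with the \code{ranger} fit.
#' @export
fit_sdm_rf <- function(train, predictors, n_trees = 500, m_try = NULL,
                       min_node_size = 1, seed = 1,
                       check_downsampling = TRUE) {
  p <- length(predictors)
  if (is.null(m_try)) m_try <- max(1, floor(sqrt(p)))
  if (m_try > p) stop("m_try (", m_try, ") exceeds predictor count (", p, ")")
  y <- factor(train$label, levels = c(0L, 1L))
  np <- sum(y == "1"); n <- length(y)
  fit <- ranger::ranger(x = train[predictors], y = y,
                        num.trees = n_trees, mtry = m_try,
                        min.node.size = min_node_size,
                        probability = TRUE, replace = TRUE,
                        sample.fraction = c(np / n, np / n),
                        keep.inbag = check_downsampling, seed = seed,
                        num.threads = 1)
  if (check_downsampling) {
    # down-sampling contract: every tree sees equal class counts
    inbag <- simplify2array(fit$inbag.counts)
    stopifnot(all(colSums(inbag[y == "1", , drop = FALSE]) == np),
              all(colSums(inbag[y == "0", , drop = FALSE]) == np))
    fit$inbag.counts <- NULL  # drop the bulky bookkeeping after the check
  }
  new_sdm_model("RF", list(n_trees = n_trees, m_try = m_try,
                           min_node_size = min_node_size), fit, predictors)
}

# ---------------------------------------------------------------------------
# Prediction

#' Predict suitability for new data from any base learner
#'
#' @param model an \code{sdm_model}.
#' @param newdata data.frame containing the model's predictor columns.
#' @return numeric vector of suitabilities in [0, 1].
#' @export
predict_sdm <- function(model, newdata) {
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing))
    stop("newdata lacks predictor column(s): ", paste(missing, collapse = ", "))
  switch(model$algorithm,
    GLM = as.numeric(stats::predict(model$fit_state, newdata,
                                    type = "response")),
    GAM = as.numeric(mgcv::predict.gam(model$fit_state, newdata,
                                       type = "response")),
    MAXENT = {
      fx <- maxent_features(model$fit_state$recipe, newdata)
      beta <- model$fit_state$beta
      eta <- as.numeric(fx$X %*% beta[-1]) + beta[1]
      1 - exp(-exp(eta))
    },
    RF = {
      pr <- stats::predict(model$fit_state, data = newdata,
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    stop("unknown algorithm: ", model$algorithm))
}

#' Project a fitted base learner over the grid
#'
#' @param model an \code{sdm_model}.
#' @param env an \code{env_stack} with the model's predictors.
#' @param area a \code{calibration_area}; cells outside it are nodata.
#' @return a \code{suitability_map}.
#' @export
predict_map <- function(model, env, area) {
  stopifnot_same_grid(env, area)
  missing <- setdiff(model$predictors, names(env$layers))
  if (length(missing))
    stop("env stack lacks layer(s): ", paste(missing, collapse = ", "))
  cells <- as_cell_table(env, unmasked_only = FALSE)
  sel <- as.vector(area$mask & env$mask)
  vals <- matrix(NA_real_, env$nlat, env$nlon)
  pred <- predict_sdm(model, cells[sel, , drop = FALSE])
  vals[cbind(cells$row[sel], cells$col[sel])] <- pmin(1, pmax(0, pred))
  suitability_map(env, vals,
                  provenance = paste0(model$algorithm, " ",
                                      paste(names(model$hyperparams),
                                            unlist(model$hyperparams),
                                            sep = "=", collapse = ",")))
}

# ---------------------------------------------------------------------------
# Tuning: cross-validated OR10 + AUC per candidate, best-decile selection

fit_candidate <- function(train, predictors, algorithm, hp, seed = 1) {
  switch(algorithm,
    GLM = fit_sdm_glm(train, predictors),
    GAM = fit_sdm_gam(train, predictors),
    MAXENT = fit_sdm_maxent(train, predictors, fc = hp$fc, rm = hp$rm),
    RF = fit_sdm_rf(train, predictors, n_trees = hp$n_trees,
                    m_try = hp$m_try, min_node_size = hp$min_node_size,
                    seed = seed, check_downsampling = FALSE),
    stop("unknown algorithm: ", algorithm))
}

#' Cross-validated validation metrics for one hyperparameter setting
#'
#' For each fold: fit on the other folds, take the 10th percentile of the
#' training-presence predictions as the omission threshold, and score the
#' held-out fold (omission rate of held-out presences below the threshold,
#' and presence-vs-background AUC). Returns fold means.
#'
#' @param train training table with \code{fold_id}.
#' @param predictors predictor names.
#' @param algorithm one of GLM, GAM, MAXENT, RF.
#' @param hp hyperparameter list for the algorithm.
#' @return list with \code{validation_or10} and \code{validation_auc}.
#' @export
cv_candidate_metrics <- function(train, predictors, algorithm, hp = list()) {
  folds <- sort(unique(train$fold_id))
  or10 <- auc_v <- numeric(length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    tr <- train[train$fold_id != f, , drop = FALSE]
    te <- train[train$fold_id == f, , drop = FALSE]
    m <- fit_candidate(tr, predictors, algorithm, hp, seed = f)
    thr <- omission_threshold(predict_sdm(m, tr[tr$label == 1L, , drop = FALSE]))
    pred_te <- predict_sdm(m, te)
    or10[i] <- mean(pred_te[te$label == 1L] < thr)
    auc_v[i] <- auc_mw(pred_te[te$label == 1L], pred_te[te$label == 0L])
  }
  list(validation_or10 = mean(or10), validation_auc = mean(auc_v))
}

#' Default hyperparameter grids for the tuned algorithms
#'
#' MaxEnt: feature classes L, LQ, H, LQH, LQHP crossed with regularization
#' multipliers 0.5, 1, 2, 3, 4 (the conventional tuning grid). RF: all
#' combinations of 500/1000 trees, m_try in {2, floor(sqrt(p)), p-1} and
#' minimum node sizes 1, 5, 10. Candidates are ordered simplest-first (lower
#' rm / smaller model), which is the tie-breaking order used in selection.
#'
#' @param algorithm \code{"MAXENT"} or \code{"RF"}.
#' @param p number of predictors (needed for the RF m_try values).
#' @return list of hyperparameter lists.
#' @export
tune_candidate_grid <- function(algorithm, p = NULL) {
  if (algorithm == "MAXENT") {
    grid <- expand.grid(rm = c(0.5, 1, 2, 3, 4),
                        fc = c("L", "LQ", "H", "LQH", "LQHP"),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$rm, nchar(grid$fc)), ]
    lapply(seq_len(nrow(grid)),
           function(i) list(fc = grid$fc[i], rm = grid$rm[i]))
  } else if (algorithm == "RF") {
    stopifnot(!is.null(p))
    mtries <- sort(unique(pmin(p, pmax(1, c(2, floor(sqrt(p)), p - 1)))))
    grid <- expand.grid(n_trees = c(500, 1000), m_try = mtries,
                        min_node_size = c(1, 5, 10))
    grid <- grid[order(grid$n_trees, grid$m_try, -grid$min_node_size), ]
    lapply(seq_len(nrow(grid)), function(i)
      list(n_trees = grid$n_trees[i], m_try = grid$m_try[i],
           min_node_size = grid$min_node_size[i]))
  } else stop("no tuning grid for algorithm ", algorithm)
}

#' Select the optimal candidate: best omission decile, then max AUC
#'
#' Keeps the candidates whose mean validation omission rate is within the
#' lowest ceiling(10%) of omission values (ties at the cutoff are kept, so
#' a flat omission profile keeps everyone) and returns the one with the
#' highest mean validation AUC among them; remaining ties go to the
#' earliest candidate, and grids list simpler models first.
#'
#' @param candidates list of \code{sdm_model}s (or plain lists) carrying
#'   \code{validation_or10} and \code{validation_auc}.
#' @return the selected element of \code{candidates}.
#' @export
tune_and_select <- function(candidates) {
  if (length(candidates) == 0) stop("empty candidate list")
  or10 <- vapply(candidates, function(x) x$validation_or10, 0)
  auc <- vapply(candidates, function(x) x$validation_auc, 0)
  stopifnot(!anyNA(or10), !anyNA(auc))
  n_keep <- ceiling(0.1 * length(candidates))
  cutoff <- sort(or10)[n_keep]
  keep <- which(or10 <= cutoff)
  best <- keep[order(-auc[keep], keep)][1]
  candidates[[best]]
}

#' Tune an algorithm over its candidate grid and fit the final model
#'
#' Runs \code{\link{cv_candidate_metrics}} for every grid point, applies the
#' best-decile-by-omission / max-AUC rule, and refits the winner on the full
#' table. GLM and GAM have a single candidate each (their complexity is set
#' by AIC backward elimination and GCV respectively) but still receive
#' cross-validated metrics on the shared folds.
#'
#' @param train training table with \code{fold_id}.
#' @param predictors predictor names.
#' @param algorithm GLM, GAM, MAXENT or RF.
#' @param grid candidate list (default \code{\link{tune_candidate_grid}} for
#'   MAXENT/RF).
#' @param validate_single also cross-validate when there is only one
#'   candidate (GLM/GAM, whose complexity is set internally); set FALSE to
#'   skip the fold loop and leave the validation metrics NA.
#' @return the final fitted \code{sdm_model} with validation metrics and a
#'   \code{candidate_table} attribute (one row per candidate).
#' @export
tune_algorithm <- function(train, predictors, algorithm, grid = NULL,
                           validate_single = TRUE) {
  if (algorithm %in% c("GLM", "GAM")) grid <- list(list())
  if (is.null(grid))
    grid <- tune_candidate_grid(algorithm, p = length(predictors))
  if (length(grid) == 1 && !validate_single) {
    final <- fit_candidate(train, predictors, algorithm, grid[[1]])
    return(final)
  }
  scored <- lapply(grid, function(hp) {
    met <- cv_candidate_metrics(train, predictors, algorithm, hp)
    c(list(hyperparams = hp), met)
  })
  sel <- tune_and_select(scored)
  final <- fit_candidate(train, predictors, algorithm, sel$hyperparams)
  final$validation_or10 <- sel$validation_or10
  final$validation_auc <- sel$validation_auc
  attr(final, "candidate_table") <- do.call(rbind, lapply(scored, function(s)
    data.frame(algorithm = algorithm,
               hyperparams = paste(names(s$hyperparams),
                                   unlist(s$hyperparams),
                                   sep = "=", collapse = ","),
               validation_or10 = s$validation_or10,
               validation_auc = s$validation_auc)))
  final
}
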