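#' Build the meta-learner training table
#'
#' Stacked generalization: each presence/background row gets the suitability
#' predicted by each of the four base algorithms, optionally plus the
#' distance (km) to the expert range polygon, and the 0/1 label. In
#' \code{out_of_fold} mode (Wolpert's scheme, the leakage-safe default) each
#' row is predicted by a model refitted without that row's fold, so ten
#' distinct refits per algorithm feed the meta-learner; \code{in_sample}
#' mode uses the full-data fits.
#'
#' @param base_models named list of fitted \code{sdm_model}s
#'   (GLM, GAM, MAXENT, RF) fitted on \code{train}.
#' @param train the shared training table with \code{fold_id}.
#' @param dist a \code{distance_layer} or NULL (occurrence-only variant).
#' @param mode \code{"out_of_fold"} or \code{"in_sample"}.
#' @param base_pred optional precomputed base-prediction table from
#'   \code{\link{stack_base_predictions}} with a matching mode — lets the
#'   two ensemble variants share one set of out-of-fold refits.
#' @return data.frame with one column per base algorithm, optional
#'   \code{distance_km}, and \code{label}; attributes record the stacking
#'   mode and, in out-of-fold mode, the per-fold refit bookkeeping.
#' @export
build_meta_table <- function(base_models, train, dist = NULL,
                             mode = c("out_of_fold", "in_sample"),
                             base_pred = NULL) {
  mode <- match.arg(mode)
  if (is.null(base_pred)) {
    base_pred <- stack_base_predictions(base_models, train, mode)
  } else if (!identical(attr(base_pred, "mode"), mode)) {
    stop("precomputed base predictions were built in mode '",
         attr(base_pred, "mode"), "', not '", mode, "'")
  }
  out <- as.data.frame(base_pred)
  if (!is.null(dist)) {
    dkm <- extract_distance(dist, train$lon, train$lat)
    if (anyNA(dkm)) stop("training points outside the distance layer domain")
    out$distance_km <- dkm
  }
  out$label <- train$label
  attr(out, "mode") <- mode
  attr(out, "refits") <- attr(base_pred, "refits")
  out
}

#' Base-model prediction columns for stacking
#'
#' In \code{out_of_fold} mode each algorithm is refitted once per fold at
#' its selected hyperparameters, and every row is predicted by the refit
#' that did not see that row's fold; \code{in_sample} mode predicts from the
#' full-data fits.
#'
#' @inheritParams build_meta_table
#' @return data.frame of per-row base predictions with attributes
#'   \code{mode} and (out-of-fold) \code{refits}, the per-algorithm refit
#'   count.
#' @export
stack_base_predictions <- function(base_models, train,
                                   mode = c("out_of_fold", "in_sample")) {
  mode <- match.arg(mode)
  stopifnot(length(base_models) >= 1, !is.null(names(base_models)))
  out <- data.frame(row.names = seq_len(nrow(train)))
  refits <- list()
  for (nm in names(base_models)) {
    model <- base_models[[nm]]
    if (mode == "in_sample") {
      out[[nm]] <- predict_sdm(model, train)
    } else {
      folds <- sort(unique(train$fold_id))
      pred <- rep(NA_real_, nrow(train))
      for (f in folds) {
        tr <- train[train$fold_id != f, , drop = FALSE]
        m_f <- refit_at_hyperparams(model, tr)
        pred[train$fold_id == f] <-
          predict_sdm(m_f, train[train$fold_id == f, , drop = FALSE])
      }
      stopifnot(!anyNA(pred))
      refits[[nm]] <- length(folds)
      out[[nm]] <- pred
    }
  }
  attr(out, "mode") <- mode
  if (mode == "out_of_fold") attr(out, "refits") <- refits
  out
}

# refit a selected model on a data subset, keeping its hyperparameters
# (stacking refits do not redo model selection)
refit_at_hyperparams <- function(model, train) {
  switch(model$algorithm,
    GLM = {
      fit <- stats::glm(stats::formula(model$fit_state), data = train,
                        family = stats::binomial())
      new_sdm_model("GLM", model$hyperparams, fit, model$predictors)
    },
    GAM = fit_sdm_gam(train, model$predictors,
                      k_basis = model$hyperparams$k_basis),
    MAXENT = fit_sdm_maxent(train, model$predictors,
                            fc = model$hyperparams$fc,
                            rm = model$hyperparams$rm),
    RF = fit_sdm_rf(train, model$predictors,
                    n_trees = model$hyperparams$n_trees,
                    m_try = model$hyperparams$m_try,
                    min_node_size = model$hyperparams$min_node_size,
                    check_downsampling = FALSE),
    stop("unknown algorithm: ", model$algorithm))
}

#' Fit the logistic-regression meta-learner
#'
#' Maximum-likelihood binomial GLM of the label on the base-model
#' predictions (and, in the expert-informed variant, the distance to the
#' expert range). Reports coefficients with Wald p-values. Near-collinear
#' inputs are flagged via the design-matrix condition number; separation
#' triggers a warning and a ridge-stabilised refit of the coefficients.
#'
#' @param table a meta-training table from \code{\link{build_meta_table}}.
#' @return object of class \code{meta_learner_fit}: \code{variant},
#'   \code{coefficients}, \code{p_values}, \code{fit}, \code{fold_provenance},
#'   \code{condition_number}.
#' @export
fit_meta <- function(table) {
  stopifnot("label" %in% names(table))
  inputs <- setdiff(names(table), "label")
  if (length(unique(table$label)) < 2)
    stop("meta table needs both presence and background labels")
  const <- inputs[vapply(table[inputs], function(x) stats::sd(x) == 0,
                         logical(1))]
  if (length(const)) {
    if ("distance_km" %in% const)
      stop("distance_km is constant (all points inside or equidistant from ",
           "the expert polygon); fit the occurrence-only variant instead")
    stop("constant meta predictor column(s): ", paste(const, collapse = ", "))
  }
  f <- stats::as.formula(paste("label ~", paste(inputs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = table,
                                     family = stats::binomial()))
  # extreme fitted probabilities alone are benign; treat the fit as
  # separated only when the MLE actually diverged
  separated <- !fit$converged || fit$boundary ||
    max(abs(stats::coef(fit))) > 1e3
  if (separated) {
    warning("separation in meta-learner; ridge-stabilised coefficients used")
    mm <- stats::model.matrix(f, table)
    rfit <- glmnet::glmnet(mm[, -1, drop = FALSE], table$label,
                           family = "binomial", alpha = 0, lambda = 1e-4)
    fit$coefficients[] <- as.numeric(stats::coef(rfit, s = 1e-4))
  }
  mm <- stats::model.matrix(f, table)
  kappa_val <- kappa(mm, exact = FALSE)
  if (kappa_val > 1e8)
    warning(sprintf("meta design matrix is near-collinear (condition number %.3g)",
                    kappa_val))
  sm <- summary(fit)$coefficients
  # Wald p-values break down under (quasi-)separation (Hauck-Donner: the
  # standard error inflates faster than the estimate), which arises
  # naturally when an accurate expert polygon makes distance > 0 almost
  # perfectly predict absence; the likelihood-ratio test stays valid, so
  # both are reported
  lrt <- stats::drop1(fit, test = "Chisq")
  p_lrt <- stats::setNames(lrt[["Pr(>Chi)"]][-1], rownames(lrt)[-1])
  variant <- if ("distance_km" %in% inputs) "expert_informed"
             else "occurrence_only"
  structure(list(variant = variant,
                 coefficients = stats::coef(fit),
                 p_values = sm[, "Pr(>|z|)"],
                 p_values_lrt = p_lrt,
                 fit = fit,
                 inputs = inputs,
                 fold_provenance = attr(table, "mode"),
                 condition_number = kappa_val),
            class = "meta_learner_fit")
}

#' @export
print.meta_learner_fit <- function(x, ...) {
  cat(sprintf("meta_learner_fit [%s] (%s stacking)\n", x$variant,
              x$fold_provenance))
  print(data.frame(coefficient = x$coefficients,
                   p_value = signif(x$p_values, 3)))
  invisible(x)
}

#' Coefficient table of the two ensemble variants
#'
#' Side-by-side coefficients and p-values in the conventional layout
#' (GLM, GAM, MaxEnt, RF, distance to expert range).
#'
#' @param occ_fit occurrence-only \code{meta_learner_fit}.
#' @param exp_fit expert-informed \code{meta_learner_fit} (or NULL).
#' @return data.frame.
#' @export
meta_coefficient_table <- function(occ_fit, exp_fit = NULL) {
  rows <- union(occ_fit$inputs, if (!is.null(exp_fit)) exp_fit$inputs)
  get <- function(fit, what, nm) {
    if (is.null(fit) || !(nm %in% names(fit$coefficients))) NA_real_
    else fit[[what]][[nm]]
  }
  data.frame(
    predictor = rows,
    occurrence_only_coef = vapply(rows, get, 0, fit = occ_fit,
                                  what = "coefficients"),
    occurrence_only_p = vapply(rows, get, 0, fit = occ_fit,
                               what = "p_values"),
    expert_informed_coef = vapply(rows, get, 0, fit = exp_fit,
                                  what = "coefficients"),
    expert_informed_p = vapply(rows, get, 0, fit = exp_fit,
                               what = "p_values"),
    row.names = NULL)
}

#' Project an ensemble over the grid
#'
#' Per-cell inverse-logit of the meta linear predictor applied to the base
#' suitability maps (and the distance layer for the expert-informed
#' variant).
#'
#' @param fit a \code{meta_learner_fit}.
#' @param base_maps named list of \code{suitability_map}s matching the base
#'   columns the meta-learner was trained on.
#' @param dist a \code{distance_layer} (required iff the fit is
#'   expert-informed).
#' @return a \code{suitability_map}.
#' @export
predict_ensemble <- function(fit, base_maps, dist = NULL) {
  needs_dist <- fit$variant == "expert_informed"
  if (needs_dist && is.null(dist))
    stop("expert-informed ensemble requires the distance layer")
  if (!needs_dist && !is.null(dist))
    stop("occurrence-only ensemble takes no distance layer")
  base_inputs <- setdiff(fit$inputs, "distance_km")
  missing <- setdiff(base_inputs, names(base_maps))
  if (length(missing))
    stop("missing base map(s): ", paste(missing, collapse = ", "))
  ref <- base_maps[[base_inputs[1]]]
  eta <- matrix(fit$coefficients[["(Intercept)"]],
                nrow(ref$values), ncol(ref$values))
  for (nm in base_inputs) {
    stopifnot_same_grid(ref, base_maps[[nm]])
    eta <- eta + fit$coefficients[[nm]] * base_maps[[nm]]$values
  }
  if (needs_dist) {
    stopifnot_same_grid(ref, dist)
    eta <- eta + fit$coefficients[["distance_km"]] * dist$values
  }
  vals <- stats::plogis(eta)
  structure(list(values = vals, grid = ref$grid,
                 provenance = paste0("ensemble:", fit$variant)),
            class = "suitability_map")
}
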