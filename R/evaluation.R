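#' Continuous Boyce index
#'
#' Predicted-to-expected ratio evaluation for presence-background models:
#' moving windows of width \code{window_fraction} of the suitability range
#' are centred on evenly spaced midpoints; in each window the fraction of
#' presence values (P) is divided by the fraction of background values (E),
#' windows without background mass are dropped, and the index is the
#' Spearman rank correlation between P/E and the window midpoint. 1 means
#' predictions rank habitat use perfectly, 0 is random, negative is
#' inverse.
#'
#' @param pres_suit suitability at presence points.
#' @param background_suit suitability at background points.
#' @param n_windows number of window midpoints.
#' @param window_fraction window width as a fraction of the suitability
#'   range.
#' @param rm_duplicate collapse runs of tied P/E ratios to a single window
#'   before the rank correlation (the convention of the standard continuous
#'   Boyce implementations; without it the long runs of zero-presence
#'   windows produced by a sharply ranked model drag the correlation down).
#' @return Boyce index in [-1, 1]; NA with a warning when the P/E profile
#'   is constant (undefined rank correlation).
#' @export
boyce_index <- function(pres_suit, background_suit, n_windows = 101,
                        window_fraction = 0.1, rm_duplicate = TRUE) {
  stopifnot(length(pres_suit) > 0, length(background_suit) > 0,
            n_windows >= 3, window_fraction > 0, window_fraction < 1)
  if (stats::sd(background_suit) == 0) {
    warning("background suitability has zero variance; Boyce undefined")
    return(NA_real_)
  }
  lo <- min(pres_suit, background_suit)
  hi <- max(pres_suit, background_suit)
  # window membership is decided on the midpoint-index scale, where the
  # alignment of the sample extremes with window edges is exact
  tp <- (pres_suit - lo) / (hi - lo) * (n_windows - 1)
  tb <- (background_suit - lo) / (hi - lo) * (n_windows - 1)
  half <- window_fraction * (n_windows - 1) / 2
  mids <- seq(lo, hi, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    k <- i - 1
    P[i] <- mean(tp >= k - half & tp <= k + half)
    E[i] <- mean(tb >= k - half & tb <= k + half)
  }
  keep <- E > 0
  if (!any(keep)) {
    warning("no window contains background values; Boyce undefined")
    return(NA_real_)
  }
  F_ratio <- P[keep] / E[keep]
  mids_kept <- mids[keep]
  if (rm_duplicate) {
    first <- !duplicated(F_ratio)
    F_ratio <- F_ratio[first]
    mids_kept <- mids_kept[first]
  }
  if (length(F_ratio) < 2 || stats::sd(F_ratio) == 0) {
    warning("constant P/E profile; Boyce undefined")
    return(NA_real_)
  }
  stats::cor(F_ratio, mids_kept, method = "spearman")
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence outranks a random background point,
#' ties counted one half.
#'
#' @inheritParams boyce_index
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(pres_suit, background_suit) {
  np <- length(pres_suit); nb <- length(background_suit)
  stopifnot(np > 0, nb > 0)
  r <- rank(c(pres_suit, background_suit))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximised true skill statistic
#'
#' TSS = sensitivity + specificity - 1, maximised over candidate thresholds
#' placed at midpoints between consecutive sorted unique suitability
#' values (plus the extremes).
#'
#' @inheritParams boyce_index
#' @return TSS in [-1, 1].
#' @export
tss_max <- function(pres_suit, background_suit) {
  stopifnot(length(pres_suit) > 0, length(background_suit) > 0)
  u <- sort(unique(c(pres_suit, background_suit)))
  thr <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  thr <- c(min(u), thr)  # threshold at the minimum classifies all suitable
  best <- -1
  for (t in thr) {
    sens <- mean(pres_suit >= t)
    spec <- mean(background_suit < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Exact two-sided paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired per-fold metric differences. Zero differences
#' are dropped; ranks of tied absolute differences are midranks; the exact
#' null distribution of the positive-rank sum V is computed by dynamic
#' programming over the rank generating polynomial (exact also under ties),
#' used for n up to 25 with a normal approximation beyond.
#'
#' @param a,b paired metric vectors (e.g. per-fold Boyce of two models);
#'   the test statistic V is the positive-rank sum of \code{b - a}.
#' @param labels length-2 character vector naming the pair.
#' @return list with \code{statistic} (V), \code{p_value}, \code{n_nonzero},
#'   \code{pair}.
#' @export
wilcoxon_signed_exact <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero; signed-rank test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25) {
    # DP over doubled ranks so midranks (x.5) stay integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    probs <- numeric(total + 1)  # probs[v+1] = P(2V = v)
    probs[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(total + 1 - ri)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(probs[(v2 + 1):(total + 1)])
    p_le <- sum(probs[seq_len(v2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum((table(r)^3 - table(r)) / 48)
    z <- (V - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p_value = p, n_nonzero = n, pair = labels)
}

#' Omission-rate threshold
#'
#' The suitability cutoff below which at most \code{rate} of the training
#' presences fall: the ceiling(rate * n)-th smallest training-presence
#' suitability, so at least (1 - rate) of training presences are at or
#' above the threshold.
#'
#' @param train_pres_suit suitability at training presences.
#' @param rate omission rate in (0, 1); default 10 percent.
#' @return the threshold value.
#' @export
omission_threshold <- function(train_pres_suit, rate = 0.10) {
  stopifnot(length(train_pres_suit) > 0, rate > 0, rate < 1)
  sort(train_pres_suit)[ceiling(rate * length(train_pres_suit))]
}

#' Binarize a suitability map at a threshold
#'
#' @param map a \code{suitability_map}.
#' @param threshold suitability cutoff; cells with value >= threshold are
#'   suitable.
#' @return object of class \code{binary_map} with logical \code{values}
#'   (NA preserved) and the applied \code{threshold}.
#' @export
binarize <- function(map, threshold) {
  stopifnot(is.finite(threshold))
  structure(list(values = map$values >= threshold, threshold = threshold,
                 grid = map$grid, provenance = map$provenance),
            class = "binary_map")
}

#' Summarise a binary range map
#'
#' Suitable area by the spherical-strip cell formula (R = 6371 km),
#' southernmost suitable cell-centre latitude, and the percentage of
#' suitable area whose cell centres fall inside the expert polygon.
#'
#' @param bin a \code{binary_map}.
#' @param poly a \code{range_polygon} (or NULL to skip the overlap
#'   percentage).
#' @param min_lat optional: restrict the summary to cells south of this
#'   latitude excluded — i.e. only count suitable cells with centre latitude
#'   >= \code{min_lat} when given.
#' @return list with \code{area_km2}, \code{southernmost_lat},
#'   \code{pct_within_expert}, \code{n_suitable_cells}.
#' @export
summarize_range <- function(bin, poly = NULL, min_lat = NULL) {
  g <- bin$grid
  suit <- which(!is.na(bin$values) & bin$values, arr.ind = TRUE)
  if (nrow(suit) == 0)
    return(list(area_km2 = 0, southernmost_lat = NA_real_,
                pct_within_expert = NA_real_, n_suitable_cells = 0L))
  lat <- g$lat[suit[, 1]]
  lon <- g$lon[suit[, 2]]
  if (!is.null(min_lat)) {
    keep <- lat >= min_lat
    suit <- suit[keep, , drop = FALSE]
    lat <- lat[keep]; lon <- lon[keep]
    if (nrow(suit) == 0)
      return(list(area_km2 = 0, southernmost_lat = NA_real_,
                  pct_within_expert = NA_real_, n_suitable_cells = 0L))
  }
  R <- 6371
  top <- lat + g$res_lat / 2
  bot <- lat - g$res_lat / 2
  areas <- R^2 * (g$res_lon * pi / 180) *
    (sin(top * pi / 180) - sin(bot * pi / 180))
  total <- sum(areas)
  pct <- NA_real_
  if (!is.null(poly)) {
    inside <- point_in_polygon(poly, lon, lat)
    pct <- 100 * sum(areas[inside]) / total
  }
  list(area_km2 = total, southernmost_lat = min(lat),
       pct_within_expert = pct, n_suitable_cells = nrow(suit))
}

#' Suitable area south of a latitude line
#'
#' @param bin a \code{binary_map}.
#' @param barrier_lat latitude (degrees).
#' @return area in km^2 of suitable cells with centre latitude strictly
#'   south of \code{barrier_lat}.
#' @export
area_south_of <- function(bin, barrier_lat) {
  g <- bin$grid
  suit <- which(!is.na(bin$values) & bin$values, arr.ind = TRUE)
  if (nrow(suit) == 0) return(0)
  lat <- g$lat[suit[, 1]]
  keep <- lat < barrier_lat
  if (!any(keep)) return(0)
  R <- 6371
  lat <- lat[keep]
  top <- lat + g$res_lat / 2
  bot <- lat - g$res_lat / 2
  sum(R^2 * (g$res_lon * pi / 180) *
        (sin(top * pi / 180) - sin(bot * pi / 180)))
}

#' 10-fold cross-validation of the four base learners and two ensembles
#'
#' Presences and background are partitioned into the table's shared folds;
#' for each fold all six models are trained on the other folds and scored
#' on the held-out rows with the continuous Boyce index (held-out
#' background as the expectation sample), AUC and TSS. The fold assignment
#' is identical across models, so per-fold metrics are paired.
#'
#' @param train training table with \code{fold_id} (from
#'   \code{\link{make_training_table}}).
#' @param predictors predictor names.
#' @param dist a \code{distance_layer} for the expert-informed ensemble.
#' @param hyper list with elements \code{maxent} (fc, rm) and \code{rf}
#'   (n_trees, m_try, min_node_size): the selected hyperparameters.
#' @param stack_mode stacking mode used inside each training split.
#' @return data.frame: fold x model x (boyce, auc, tss), class
#'   \code{cv_result}.
#' @export
crossvalidate <- function(train, predictors, dist, hyper,
                          stack_mode = c("out_of_fold", "in_sample")) {
  stack_mode <- match.arg(stack_mode)
  folds <- sort(unique(train$fold_id))
  res <- list()
  for (f in folds) {
    tr <- train[train$fold_id != f, , drop = FALSE]
    te <- train[train$fold_id == f, , drop = FALSE]
    if (!any(te$label == 1L)) stop("fold ", f, " has no presences")
    base <- list(
      GLM = fit_sdm_glm(tr, predictors),
      GAM = fit_sdm_gam(tr, predictors),
      MAXENT = fit_sdm_maxent(tr, predictors, fc = hyper$maxent$fc,
                              rm = hyper$maxent$rm),
      RF = fit_sdm_rf(tr, predictors, n_trees = hyper$rf$n_trees,
                      m_try = hyper$rf$m_try,
                      min_node_size = hyper$rf$min_node_size, seed = f))
    meta_occ <- fit_meta(build_meta_table(base, tr, dist = NULL,
                                          mode = stack_mode))
    meta_exp <- fit_meta(build_meta_table(base, tr, dist = dist,
                                          mode = stack_mode))
    preds <- lapply(base, predict_sdm, newdata = te)
    meta_te <- as.data.frame(preds)
    meta_te$distance_km <- extract_distance(dist, te$lon, te$lat)
    preds$ENS_OCC <- as.numeric(
      stats::predict(meta_occ$fit, meta_te, type = "response"))
    preds$ENS_EXP <- as.numeric(
      stats::predict(meta_exp$fit, meta_te, type = "response"))
    for (m in names(preds)) {
      p <- preds[[m]][te$label == 1L]
      b <- preds[[m]][te$label == 0L]
      res[[length(res) + 1L]] <- data.frame(
        fold = f, model = m,
        boyce = boyce_index(p, b), auc = auc_mw(p, b), tss = tss_max(p, b))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Mean +/- sd summary of cross-validation metrics
#'
#' @param cv a \code{cv_result}.
#' @param metric metric column name.
#' @return data.frame with model, mean, sd and a formatted
#'   \code{"0.781 +/- 0.177"}-style string.
#' @export
summarize_cv <- function(cv, metric = "boyce") {
  agg <- do.call(rbind, lapply(split(cv, cv$model), function(d)
    data.frame(model = d$model[1],
               mean = mean(d[[metric]], na.rm = TRUE),
               sd = stats::sd(d[[metric]], na.rm = TRUE))))
  agg$formatted <- sprintf("%.3f ± %.3f", agg$mean, agg$sd)
  rownames(agg) <- NULL
  agg
}

#' Paired comparison of two models from a cross-validation result
#'
#' @param cv a \code{cv_result}.
#' @param a,b model names in \code{cv$model}.
#' @param metric metric column to compare.
#' @return see \code{\link{wilcoxon_signed_exact}}.
#' @export
compare_models <- function(cv, a, b, metric = "boyce") {
  da <- cv[cv$model == a, ]
  db <- cv[cv$model == b, ]
  da <- da[order(da$fold), ]; db <- db[order(db$fold), ]
  stopifnot(nrow(da) == nrow(db), all(da$fold == db$fold))
  wilcoxon_signed_exact(da[[metric]], db[[metric]], labels = c(a, b))
}
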