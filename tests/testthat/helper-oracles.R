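# Independent brute-force oracles for the evaluation metrics. These are
# deliberately written as plain loops / enumeration, on a different code
# path from the package implementations they check.

oracle_auc <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

oracle_tss <- function(pres, bg) {
  u <- sort(unique(c(pres, bg)))
  cand <- c(u[1], if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  best <- -1
  for (t in cand) {
    tp <- sum(pres >= t); fn <- sum(pres < t)
    tn <- sum(bg < t); fp <- sum(bg >= t)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    if (sens + spec - 1 > best) best <- sens + spec - 1
  }
  best
}

oracle_boyce <- function(pres, bg, n_windows = 101, window_fraction = 0.1,
                         rm_duplicate = TRUE) {
  lo <- min(c(pres, bg)); hi <- max(c(pres, bg))
  # same index-scale membership convention as the implementation (edge
  # alignment of the sample extremes is exact there); aggregation and the
  # rank correlation are computed independently
  half <- window_fraction * (n_windows - 1) / 2
  F_ratio <- mid_kept <- c()
  for (k in 0:(n_windows - 1)) {
    inP <- 0
    for (x in pres) {
      t <- (x - lo) / (hi - lo) * (n_windows - 1)
      if (t >= k - half && t <= k + half) inP <- inP + 1
    }
    inE <- 0
    for (x in bg) {
      t <- (x - lo) / (hi - lo) * (n_windows - 1)
      if (t >= k - half && t <= k + half) inE <- inE + 1
    }
    if (inE > 0) {
      F_ratio <- c(F_ratio, (inP / length(pres)) / (inE / length(bg)))
      mid_kept <- c(mid_kept, k)
    }
  }
  if (rm_duplicate) {
    seen <- c(); pick <- logical(length(F_ratio))
    for (i in seq_along(F_ratio)) {
      if (!any(abs(seen - F_ratio[i]) == 0)) {
        pick[i] <- TRUE; seen <- c(seen, F_ratio[i])
      }
    }
    F_ratio <- F_ratio[pick]; mid_kept <- mid_kept[pick]
  }
  if (length(F_ratio) < 2 || stats::sd(F_ratio) == 0) return(NA_real_)
  # Spearman as Pearson on ranks (different route from cor(method="spearman"))
  stats::cor(rank(F_ratio), rank(mid_kept))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(a, b) {
  d <- (b - a)[b - a != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    v <- 0
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L))) v <- v + r[i]
    vs[mask + 1] <- v
  }
  p_ge <- mean(vs >= V); p_le <- mean(vs <= V)
  min(1, 2 * min(p_ge, p_le))
}

# spherical cell-strip area, written from the integral R^2 * dlon * d(sin lat)
oracle_cell_area <- function(lat_centre, res_deg) {
  R <- 6371
  phi1 <- (lat_centre - res_deg / 2) * pi / 180
  phi2 <- (lat_centre + res_deg / 2) * pi / 180
  R^2 * (res_deg * pi / 180) * (sin(phi2) - sin(phi1))
}
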