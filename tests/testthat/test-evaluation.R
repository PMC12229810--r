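test_that("AUC matches hand-enumerated examples", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc_mw(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # two pairs: one win, one loss
  expect_equal(auc_mw(c(0.7, 0.3), c(0.5)), 0.5)
})

test_that("TSS matches hand-constructed contingencies", {
  expect_equal(tss_max(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  # 10 presences (8 above threshold), 10 background (7 below):
  # sensitivity 0.8, specificity 0.7 at the optimum -> TSS 0.5
  pres <- c(rep(0.9, 8), rep(0.1, 2))
  bg <- c(rep(0.1, 7), rep(0.9, 3))
  expect_equal(tss_max(pres, bg), 0.5)
})

test_that("metrics match brute-force oracles on random small instances", {
  set.seed(101)
  for (i in 1:200) {
    np <- sample(2:50, 1); nb <- sample(2:50, 1)
    # mix of continuous and heavily tied values to exercise tie handling
    gen <- function(n) if (runif(1) < 0.3) sample(seq(0, 1, 0.1), n, TRUE)
                       else runif(n)
    pres <- gen(np); bg <- gen(nb)
    expect_equal(auc_mw(pres, bg), oracle_auc(pres, bg), tolerance = 1e-9)
    expect_equal(tss_max(pres, bg), oracle_tss(pres, bg), tolerance = 1e-9)
    for (dd in c(TRUE, FALSE)) {
      b1 <- suppressWarnings(boyce_index(pres, bg, rm_duplicate = dd))
      b2 <- oracle_boyce(pres, bg, rm_duplicate = dd)
      if (is.na(b1) || is.na(b2)) expect_equal(is.na(b1), is.na(b2))
      else expect_equal(b1, b2, tolerance = 1e-9)
    }
  }
})

test_that("Boyce rewards models that rank presences above background", {
  set.seed(33)
  bg <- runif(1000)
  pres <- runif(1000, 0.9, 1.0)  # presences in the top decile
  expect_gt(boyce_index(pres, bg), 0.9)
  # same distribution: no skill. The 101 heavily-overlapping windows make
  # the null index noisy (P/E profiles are strongly autocorrelated), so the
  # assertion separates no-skill from the sharply ranked model above rather
  # than pinning the null near zero.
  pres0 <- runif(1000)
  expect_lt(abs(boyce_index(pres0, bg)), 0.7)
})

test_that("Boyce negates exactly under negation of the suitability axis", {
  # exact antisymmetry holds for the raw (no duplicate-collapsing) profile:
  # negation mirrors the window sequence and the P/E values with it
  set.seed(34)
  bg <- runif(500); pres <- rbeta(400, 4, 2)
  expect_equal(boyce_index(-pres, -bg, rm_duplicate = FALSE),
               -boyce_index(pres, bg, rm_duplicate = FALSE),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(35)
  pres <- rbeta(300, 3, 2); bg <- runif(400)
  cube <- function(x) x^3
  expect_equal(auc_mw(cube(pres), cube(bg)), auc_mw(pres, bg),
               tolerance = 1e-12)
})

test_that("degenerate Boyce inputs are signalled", {
  expect_warning(out <- boyce_index(runif(10), rep(0.5, 10)), "variance")
  expect_true(is.na(out))
})

test_that("exact signed-rank p matches full enumeration for n <= 12", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    a <- round(runif(n), 2)
    b <- round(a + rnorm(n, sd = 0.3), 2)
    if (all(b == a)) next
    res <- wilcoxon_signed_exact(a, b)
    expect_equal(res$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-9)
  }
})

test_that("signed-rank statistic follows the textbook identities", {
  a <- 1:10; b <- a + 1           # all positive differences
  res <- wilcoxon_signed_exact(a, b)
  expect_equal(res$statistic, 55)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)
  # swapping the pair reflects V and keeps p
  res_sw <- wilcoxon_signed_exact(b, a)
  expect_equal(res_sw$statistic, 0)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
  # identical vectors: undefined
  expect_error(wilcoxon_signed_exact(a, a), "zero")
})

test_that("exact signed-rank p agrees with wilcox.test when tie-free", {
  set.seed(66)
  a <- runif(10); b <- a + rnorm(10, sd = 0.5)
  res <- wilcoxon_signed_exact(a, b)
  ref <- wilcox.test(b, a, paired = TRUE, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("omission threshold follows the sorted-index convention", {
  vals <- seq(0.1, 1.0, by = 0.1)
  thr <- omission_threshold(vals, rate = 0.10)
  expect_equal(thr, 0.1)
  expect_equal(mean(vals < thr), 0)  # nothing strictly below
  expect_equal(omission_threshold(rep(0.4, 7)), 0.4)
  set.seed(77)
  u <- runif(1000)
  thr_u <- omission_threshold(u, rate = 0.10)
  expect_gte(mean(u < thr_u), 0.09)
  expect_lte(mean(u < thr_u), 0.10)
  expect_error(omission_threshold(u, rate = 1.5))
})

test_that("binarization respects the threshold and preserves nodata", {
  sim <- small_sim()
  map <- sim$truth$true_suitability
  map$values[2, 2] <- NA
  bin <- binarize(map, 0.5)
  expect_true(is.na(bin$values[2, 2]))
  expect_equal(bin$values[10, 10], map$values[10, 10] >= 0.5)
  all_in <- binarize(map, 0)
  expect_true(all(all_in$values[!is.na(all_in$values)]))
  none <- binarize(map, max(map$values, na.rm = TRUE) + 0.1)
  expect_false(any(none$values[!is.na(none$values)]))
  # idempotence: re-binarizing at the stored threshold reproduces the map
  rebin <- binarize(list(values = bin$values + 0, grid = bin$grid,
                         provenance = ""), 1)
  expect_equal(rebin$values, bin$values > 0)
})

test_that("range summaries match the spherical-strip oracle", {
  env <- env_stack(list(a = matrix(0, 4, 4)), extent = c(0, 4, -2, 2))
  vals <- matrix(FALSE, 4, 4)
  vals[2, 1] <- TRUE   # lat centre 0.5
  vals[3, 2] <- TRUE   # lat centre -0.5
  bin <- structure(list(values = vals, threshold = 0.5,
                        grid = sdmstack:::grid_of(env)),
                   class = "binary_map")
  s <- summarize_range(bin, square_poly(0, 1, 0, 2))
  expect_equal(s$area_km2, oracle_cell_area(0.5, 1) + oracle_cell_area(-0.5, 1),
               tolerance = 1e-9)
  expect_equal(s$southernmost_lat, -0.5)
  # only the (2,1) cell centre (0.5, 0.5) is inside the polygon
  expect_equal(s$pct_within_expert,
               100 * oracle_cell_area(0.5, 1) /
                 (oracle_cell_area(0.5, 1) + oracle_cell_area(-0.5, 1)),
               tolerance = 1e-9)
  # a polygon covering everything gives 100%
  s_all <- summarize_range(bin, square_poly(-1, 5, -3, 3))
  expect_equal(s_all$pct_within_expert, 100)
  # empty map
  s0 <- summarize_range(binarize(suitability_map(env, matrix(0.2, 4, 4)), 0.9),
                        NULL)
  expect_equal(s0$area_km2, 0)
  expect_true(is.na(s0$southernmost_lat))
})

test_that("suitable area is stable under grid refinement", {
  # a smooth suitability field binarized at 0.5, computed at two resolutions
  f <- function(lon, lat) plogis(2 * sin(lon / 2) + lat / 3)
  make_bin <- function(n) {
    env <- env_stack(list(a = matrix(0, n, n)), extent = c(0, 10, 20, 30))
    vals <- outer(seq_len(n), seq_len(n),
                  function(i, j) f(env$lon[j], env$lat[i]))
    binarize(suitability_map(env, vals), 0.5)
  }
  a1 <- summarize_range(make_bin(50))$area_km2
  a2 <- summarize_range(make_bin(100))$area_km2
  expect_lt(abs(a1 - a2) / a2, 0.01)
})
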