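# Shared small fixtures, built in code and cached per test run.

# compact virtual species on a 40 x 40 grid; fast enough to regenerate but
# cached because several test files use it
small_config <- function(seed = 11, ...) {
  args <- list(extent = c(118, 122, 28, 32), resolution = 0.1,
               n_env = 3, n_presence = 80, barrier_lat = 29.5,
               expert_buffer_km = 30, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(virtual_species_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_virtual_species(small_config())
  .fixture_cache$sim
}

# a small presence-background training table with a known logistic truth:
# P(presence | x) = plogis(b0 + b1 * x1); other predictors are noise
logistic_train <- function(n = 1500, b0 = -1, b1 = 2, p_extra = 2,
                           k = 5, seed = 42) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * (1 + p_extra)), n))
  names(X) <- paste0("x", seq_len(1 + p_extra))
  lab <- rbinom(n, 1, plogis(b0 + b1 * X$x1))
  X$label <- lab
  X$fold_id <- NA_integer_
  X$fold_id[lab == 1] <- sample(rep_len(seq_len(k), sum(lab == 1)))
  X$fold_id[lab == 0] <- sample(rep_len(seq_len(k), sum(lab == 0)))
  X$lon <- runif(n, 0, 1); X$lat <- runif(n, 0, 1)
  X
}

# square range polygon
square_poly <- function(lon0 = 0, lon1 = 1, lat0 = 0, lat1 = 1) {
  range_polygon(list(rbind(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1),
                           c(lon0, lat1))), "square")
}
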