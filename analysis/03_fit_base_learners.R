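#!/usr/bin/env Rscript
# Stage 3: fit and tune the four base learners on the shared training table
# and project their suitability maps. MaxEnt and RF are tuned by 10-fold
# cross-validation (best omission decile, then validation AUC); GLM
# complexity is set by AIC backward elimination and GAM smoothness by GCV.

source(file.path("analysis", "00_common.R"))

fx <- CFG$paths$fixtures
layer_files <- list.files(fx, pattern = "^env\\d+\\.asc$", full.names = TRUE)
names(layer_files) <- sub("\\.asc$", "", basename(layer_files))
env <- read_env_stack(layer_files)

out <- results_dir()
presences <- read.csv(file.path(out, "presences_thinned.csv"))
background <- read.csv(file.path(out, "background.csv"))
predictors <- readLines(file.path(out, "retained_predictors.txt"))

prep <- prep_from_config()
area <- build_calibration_area(presences, env, prep)
train <- make_training_table(presences, background, env, predictors,
                             k = CFG$evaluation$k_folds,
                             seed = CFG$virtual_species$seed)

grids <- experiment_grids(p = length(predictors))
base <- list(
  GLM = tune_algorithm(train, predictors, "GLM"),
  GAM = tune_algorithm(train, predictors, "GAM"),
  MAXENT = tune_algorithm(train, predictors, "MAXENT", grid = grids$maxent),
  RF = tune_algorithm(train, predictors, "RF", grid = grids$rf))

cand <- do.call(rbind, lapply(base, attr, "candidate_table"))
write.csv(cand, file.path(out, "candidate_models.csv"), row.names = FALSE)

for (nm in names(base)) {
  cat(sprintf("%-7s val AUC %.3f  val OR10 %.3f  (%s)\n", nm,
              base[[nm]]$validation_auc, base[[nm]]$validation_or10,
              paste(names(base[[nm]]$hyperparams),
                    unlist(base[[nm]]$hyperparams),
                    sep = "=", collapse = ", ")))
  map <- predict_map(base[[nm]], env, area)
  write_asc(map$values, env,
            file.path(out, paste0("suitability_", tolower(nm), ".asc")))
}
cat("Base-model maps and the candidate table written to", out, "\n")
write_manifest("fit", list(selected = lapply(base, `[[`, "hyperparams")))
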