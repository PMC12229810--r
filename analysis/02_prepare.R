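#!/usr/bin/env Rscript
# Stage 2: read the fixtures back from disk (exercising the plain-text I/O
# path), thin the occurrences, delineate the 1000-km calibration area,
# draw the background sample and screen predictors for collinearity.

source(file.path("analysis", "00_common.R"))

fx <- CFG$paths$fixtures
layer_files <- list.files(fx, pattern = "^env\\d+\\.asc$", full.names = TRUE)
names(layer_files) <- sub("\\.asc$", "", basename(layer_files))
env <- read_env_stack(layer_files)
occ <- read.csv(file.path(fx, "presences.csv"))

prep <- prep_from_config()
presences <- clean_and_thin(occ, env, prep)
area <- build_calibration_area(presences, env, prep)
background <- sample_background(area, prep)
predictors <- screen_predictors(env, area, prep)

cat("Occurrences:", nrow(occ), "->", nrow(presences), "after thinning at",
    prep$thin_resolution, "deg\n")
cat("Calibration area:", sum(area$mask), "cells within", prep$buffer_km,
    "km of a presence\n")
cat("Background points:", nrow(background), "\n")
cat("Retained predictors:", paste(predictors, collapse = ", "), "\n")

out <- results_dir()
write.csv(presences, file.path(out, "presences_thinned.csv"),
          row.names = FALSE)
write.csv(background, file.path(out, "background.csv"), row.names = FALSE)
write_asc(ifelse(area$mask, 1, NA), env, file.path(out, "calibration_area.asc"))
writeLines(predictors, file.path(out, "retained_predictors.txt"))
write_manifest("prepare",
               list(n_thinned = nrow(presences),
                    n_background = nrow(background),
                    retained_predictors = predictors))
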