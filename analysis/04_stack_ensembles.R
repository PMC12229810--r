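#!/usr/bin/env Rscript
# Stage 4: stacked generalization. Out-of-fold predictions of the four base
# learners (plus the distance-to-expert-range layer for the expert-informed
# variant) train the two logistic meta-learners; both ensemble maps are
# binarized at their 10% omission thresholds and summarised.

source(file.path("analysis", "00_common.R"))

cfg <- vs_config()
sim <- simulate_virtual_species(cfg)   # deterministic: same seed as stage 1
prep <- prep_from_config()
grids <- experiment_grids(p = cfg$n_env)

res <- run_sdm_pipeline(sim$env, sim$presences, sim$truth$expert_polygon,
                        prep = prep, k = CFG$evaluation$k_folds,
                        maxent_grid = grids$maxent, rf_grid = grids$rf,
                        stack_mode = CFG$stacking$mode,
                        omission_rate = CFG$evaluation$omission_rate,
                        seed = cfg$seed, validate_single = FALSE)

out <- results_dir()
coef_tab <- res$coefficient_table
write.csv(coef_tab, file.path(out, "meta_coefficients.csv"),
          row.names = FALSE)
cat("Meta-learner coefficients (occurrence-only vs expert-informed):\n")
print(coef_tab, row.names = FALSE, digits = 3)

write_asc(res$map_occ$values, sim$env,
          file.path(out, "ensemble_occurrence_only.asc"))
write_asc(res$map_exp$values, sim$env,
          file.path(out, "ensemble_expert_informed.asc"))
write_asc(ifelse(res$bin_occ$values, 1, 0), sim$env,
          file.path(out, "binary_occurrence_only.asc"))
write_asc(ifelse(res$bin_exp$values, 1, 0), sim$env,
          file.path(out, "binary_expert_informed.asc"))

s_occ <- summarize_range(res$bin_occ, sim$truth$expert_polygon)
s_exp <- summarize_range(res$bin_exp, sim$truth$expert_polygon)
summ <- data.frame(
  ensemble = c("occurrence_only", "expert_informed"),
  threshold = c(res$thr_occ, res$thr_exp),
  area_km2 = c(s_occ$area_km2, s_exp$area_km2),
  southernmost_lat = c(s_occ$southernmost_lat, s_exp$southernmost_lat),
  pct_within_expert = c(s_occ$pct_within_expert, s_exp$pct_within_expert),
  area_south_of_barrier_km2 = c(area_south_of(res$bin_occ, cfg$barrier_lat),
                                area_south_of(res$bin_exp, cfg$barrier_lat)))
write.csv(summ, file.path(out, "range_summaries.csv"), row.names = FALSE)
cat("\nRange summaries:\n")
print(summ, row.names = FALSE, digits = 4)
write_manifest("stack", list(stack_mode = CFG$stacking$mode))
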