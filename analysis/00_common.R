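# Shared setup for the analysis scripts: read the config, rebuild the
# virtual species and (deterministically) the prepared modelling inputs.
# Sourced by the numbered drivers; everything heavy lives in the package.

library(sdmstack)

cfg_file <- file.path("analysis", "config.yaml")
CFG <- yaml::read_yaml(cfg_file)

vs_config <- function() {
  v <- CFG$virtual_species
  virtual_species_config(extent = unlist(v$extent), resolution = v$resolution,
                         n_env = v$n_env, barrier_lat = v$barrier_lat,
                         n_presence = v$n_presence,
                         expert_buffer_km = v$expert_buffer_km,
                         seed = v$seed)
}

prep_from_config <- function(seed_offset = 0) {
  p <- CFG$prep
  prep_config(thin_resolution = p$thin_resolution,
              corr_threshold = p$corr_threshold,
              buffer_km = p$buffer_km, n_background = p$n_background,
              seed = CFG$virtual_species$seed + seed_offset)
}

results_dir <- function() {
  dir.create(CFG$paths$results, recursive = TRUE, showWarnings = FALSE)
  CFG$paths$results
}

write_manifest <- function(stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     seed = CFG$virtual_species$seed,
                     config = CFG,
                     r_version = R.version.string,
                     stacking_mode = CFG$stacking$mode,
                     notes = paste("thinning at the grid resolution;",
                                   "OR10 from training presences;",
                                   "LRT p-values reported beside Wald")),
                extra)
  jsonlite::write_json(manifest,
                       file.path(results_dir(),
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}
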