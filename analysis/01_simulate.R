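#!/usr/bin/env Rscript
# Stage 1: simulate the virtual seascape and species, and write the fixture
# files (environmental .asc layers, presence CSV, expert-range GeoJSON).
# The species' occupancy is truncated at the dispersal barrier, so suitable
# but unoccupied habitat exists south of it — the situation the
# expert-informed ensemble is meant to handle.

source(file.path("analysis", "00_common.R"))

cfg <- vs_config()
sim <- simulate_virtual_species(cfg)

fx_dir <- CFG$paths$fixtures
write_fixtures(sim, fx_dir)

south <- sim$env$lat < cfg$barrier_lat
suitable_south <- sum(sim$truth$true_suitability$values[south, ] > 0.5,
                      na.rm = TRUE)
occ_total <- sum(sim$truth$occupancy)

cat("Simulated", cfg$n_presence, "presences on a",
    sim$env$nlat, "x", sim$env$nlon, "grid\n")
cat("Occupied cells:", occ_total,
    "| suitable-but-unoccupied cells south of the barrier:",
    suitable_south, "\n")
cat("Expert polygon area:",
    round(polygon_area_km2(sim$truth$expert_polygon)), "km^2\n")
cat("Fixtures written to", fx_dir, "\n")

write_manifest("simulate",
               list(occupied_cells = occ_total,
                    suitable_unoccupied_south = suitable_south))
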