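#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Generates a synthetic seabed survey shaped like the monitoring data the
# pipeline is designed for: 56 complete stations clustered along a shelf-
# sized lon/lat box, ten candidate physical predictors, and an overdispersed
# microplastic count response (negative binomial around a five-predictor
# signal). Also lays down a 20 x 20 prediction grid with smooth predictor
# surfaces and three synthetic source/receptor polygon layers.

suppressPackageStartupMessages(library(seabedmp))

MASTER_SEED <- 42
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- generate_station_dataset(n = 56, seed = derive_seed(MASTER_SEED, 1L))
stations <- sim$stations
write_station_csv(stations, file.path(out_dir, "stations.csv"))

grid <- generate_prediction_grid(nx = 20, ny = 20,
                                 seed = derive_seed(MASTER_SEED, 2L))
write_grid_csv(grid, file.path(out_dir, "grid.csv"))

layers <- generate_risk_layers(
  c(MPA = "receptor", disposal_sites = "source", wind_farms = "source"),
  polygons_per_kind = 8, seed = derive_seed(MASTER_SEED, 3L))
write_layers_geojson(layers, file.path(out_dir, "layers.geojson"))

cat("Simulated survey:", nrow(stations), "stations;",
    "response range", paste(round(range(stations$mp_count)), collapse = "-"),
    "particles/kg; mean", round(mean(stations$mp_count)), "\n")
cat("Prediction grid:", nrow(grid), "cells;",
    length(layers), "risk layers written to", out_dir, "\n")
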