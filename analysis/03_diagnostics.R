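#!/usr/bin/env Rscript
# Stage 3: interrogate the selected model.
#
# Refits the chosen subset, runs a leave-one-out pass for honest per-station
# errors, and checks the residuals for spatial autocorrelation with an
# empirical semivariogram plus a 199-permutation envelope: a curve that
# stays inside the envelope is consistent with spatially unstructured
# residuals. Partial-dependence curves show each selected predictor's
# marginal effect.

suppressPackageStartupMessages(library(seabedmp))

MASTER_SEED <- 42
stations <- read_station_csv("results/data/stations.csv")
sel <- jsonlite::read_json("results/selection/selection.json",
                           simplifyVector = TRUE)
best <- sel$selected
out_dir <- "results/diagnostics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- boost_params(ntrees = 400, depth = 1, minobs = 10,
                       seed = derive_seed(MASTER_SEED, 5L))
model <- fit_boosted_model(stations, "mp_count", best, params)
write_model_json(model, file.path(out_dir, "model.json"))

loo <- loo_predictions(stations, best, params)
cat("LOOMAE of the selected model:", round(loo$loomae, 1), "particles/kg\n")
utils::write.csv(data.frame(station_id = stations$station_id,
                            observed = stations$mp_count,
                            loo_prediction = loo$per_case_prediction,
                            abs_error = loo$abs_error),
                 file.path(out_dir, "loo.csv"), row.names = FALSE)

resid <- model_residuals(model, stations)
sv <- semivariogram_envelope(stations[, c("lon", "lat")], resid,
                             n_bins = 8, n_perm = 199,
                             seed = derive_seed(MASTER_SEED, 6L))
utils::write.csv(as.data.frame(sv), file.path(out_dir, "semivariogram.csv"),
                 row.names = FALSE)
occ <- sv$pair_count > 0
inside <- sv$semivariance[occ] >= sv$envelope_lower[occ] &
  sv$semivariance[occ] <= sv$envelope_upper[occ]
cat("Semivariogram bins inside the permutation envelope:",
    sum(inside), "of", sum(occ), "\n")

pd <- do.call(rbind, lapply(best, function(f) {
  d <- partial_dependence(model, stations, f)
  d$feature <- f
  d
}))
utils::write.csv(pd, file.path(out_dir, "partial_dependence.csv"),
                 row.names = FALSE)
cat("Diagnostics written to", out_dir, "\n")
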