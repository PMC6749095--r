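#!/usr/bin/env Rscript
# Stage 1: generate the ground-truth trajectory ensembles.
#
# Four ensembles mirror the experimental groups: freely diffusing small
# aggregates and directed-moving inclusion bodies, each imaged fast
# (32 fps, GFP-like) and slow (10 fps, photoconverted-channel-like).
# Tracks go to results/ as CSV; the generator settings to a YAML sidecar.

suppressMessages({library(incluflux); library(yaml)})
dir.create("results", showWarnings = FALSE)
seed <- 20260923

n_frames <- 300
small_model <- motion_model("brownian", diffusion_coefficient = 0.059)
ib_model <- motion_model("directed", diffusion_coefficient = 0.005,
                         drift_speed = 0.2, drift_persistence = 1)

groups <- list(
  small_32fps = list(model = small_model, n = 23, fps = 32),
  ib_32fps    = list(model = ib_model,    n = 23, fps = 32),
  small_10fps = list(model = small_model, n = 8,  fps = 10),
  ib_10fps    = list(model = ib_model,    n = 8,  fps = 10))

for (name in names(groups)) {
  g <- groups[[name]]
  tracks <- simulate_ensemble(g$model, g$n, n_frames, 1 / g$fps,
                              seed = seed + match(name, names(groups)) * 100)
  write_tracks(tracks, file.path("results", paste0("tracks_", name, ".csv")),
               pixel_size = 0.1, frame_interval = 1 / g$fps)
  cat(sprintf("%-12s %2d tracks x %d frames at %d fps\n",
              name, g$n, n_frames, g$fps))
}

write_yaml(list(
  seed = seed, n_frames = n_frames,
  small_particles = list(kind = "brownian", D_um2_s = 0.059),
  inclusion_bodies = list(kind = "directed", D_um2_s = 0.005,
                          drift_speed_um_s = 0.2, drift_persistence_s = 1),
  frame_rates_fps = c(32, 10)),
  "results/simulation_parameters.yaml")
cat("wrote results/tracks_*.csv and results/simulation_parameters.yaml\n")
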