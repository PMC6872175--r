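#!/usr/bin/env Rscript

# Build the synthetic trajectory cohorts used throughout the workflow:
# free Brownian walkers at a membrane-protein diffusivity, tracks confined
# to a 200 nm domain, immobilized emitters, and a drifting cohort — all
# with 25 nm localization noise and mild blinking, at 10 Hz. Writes the
# track tables and their ground-truth labels under results/.

suppressMessages(library(sptdiff))
dir.create("results", showWarnings = FALSE)

seed <- 20260925L
dt <- 0.1          # 10 Hz acquisition
sigma <- 0.025     # 25 nm localization accuracy

cohorts <- list(
  brownian = sim_config(n_tracks = 150, n_steps = 300, dt = dt, D = 0.027,
                        mode = "brownian", seed = seed + 1L),
  confined = sim_config(n_tracks = 150, n_steps = 300, dt = 1 / 33,
                        D = 0.027, mode = "confined_square", L = 0.2,
                        seed = seed + 2L),
  immobile = sim_config(n_tracks = 30, n_steps = 120, dt = dt, D = 0,
                        mode = "immobile", seed = seed + 3L),
  directed = sim_config(n_tracks = 50, n_steps = 300, dt = dt, D = 0.02,
                        mode = "directed", v = c(0.15, 0), seed = seed + 4L))

for (name in names(cohorts)) {
  ts <- simulate_tracks(cohorts[[name]])
  ts <- add_localization_noise(ts, sigma, seed = seed + 10L)
  ts <- add_blinking(ts, blink_p = 0.03, seed = seed + 11L)
  write_tracks(ts, file.path("results", paste0("tracks_", name, ".csv")))
  message(sprintf("%-9s %3d tracks, dt = %.3f s, D = %.3f um^2/s",
                  name, length(ts), cohorts[[name]]$dt, cohorts[[name]]$D))
}

# one long state-switching trajectory for the segmentation analysis
P <- matrix(c(0.97, 0.02, 0.01,
              0.02, 0.96, 0.02,
              0.01, 0.02, 0.97), 3, byrow = TRUE)
sw <- simulate_switching(sim_config(n_tracks = 1, n_steps = 3001, dt = dt,
                                    mode = "switching", seed = seed + 5L),
                         D_states = c(0.004, 0.04, 0.25), trans_matrix = P)
write_tracks(sw$tracks, "results/tracks_switching.csv")
write_ground_truth(sw$ground_truth, "results/ground_truth_switching.csv")
message("switching: 1 track of 3001 frames, D states 0.004/0.04/0.25 um^2/s")
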