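#!/usr/bin/env Rscript
# Stage 1: synthesise the two study-shaped recordings with known ground
# truth and write them under results/data/.
#
#  * comparison: 3 proximal shell electrodes + 4 distal planar electrodes,
#    five stimulation rounds, an increasing amplitude gain on the shell
#    group only (the glutamate-sensitivity contrast).
#  * glutamate: a single 3-electrode shell recorded for a baseline round
#    and a stimulated round with a +60% amplitude gain.

suppressPackageStartupMessages(library(shellmea))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- comparison recording (3D shell vs 2D planar, 5 rounds) --")
cfg_cmp <- sim_config(duration_s = 30, n_rounds = 5, spike_rate_hz = 2,
                      round_gain = seq(1, 1.4, by = 0.1),
                      planar_round_gain = rep(1, 5),
                      base_amplitude_uv = 60, noise_sigma_uv = 5,
                      channel_distances_um = c(10, 20, 30, 100, 120, 140, 160),
                      seed = seed)
sim <- generate_recording(cfg_cmp)
print(sim$recording)
message(sprintf("injected %d source events across %d rounds",
                length(sim$ground_truth$event_times_s), cfg_cmp$n_rounds))
write_recording(sim$recording, file.path(out, "comparison.dat"))
write_ground_truth(sim$ground_truth, file.path(out, "comparison_truth.csv"))
write_sim_config(cfg_cmp, file.path(out, "comparison_config.yaml"))

message("-- glutamate recording (one shell group, before/after) --")
cfg_glu <- sim_config(duration_s = 40, n_rounds = 2, spike_rate_hz = 2,
                      round_gain = c(1, 1.6),
                      n_shell_channels = 3, n_planar_channels = 0,
                      channel_distances_um = c(10, 20, 30),
                      base_amplitude_uv = 60, noise_sigma_uv = 5,
                      seed = seed + 1L)
sim2 <- generate_recording(cfg_glu)
print(sim2$recording)
message(sprintf("injected %d source events (round gain %s)",
                length(sim2$ground_truth$event_times_s),
                paste(cfg_glu$round_gain, collapse = " -> ")))
write_recording(sim2$recording, file.path(out, "glutamate.dat"))
write_ground_truth(sim2$ground_truth, file.path(out, "glutamate_truth.csv"))
write_sim_config(cfg_glu, file.path(out, "glutamate_config.yaml"))

message("done: recordings and ground truth under ", out)
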