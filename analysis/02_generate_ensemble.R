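#!/usr/bin/env Rscript
# Step 2 -- ground-truth LN ensemble over a simulated session.
#
# Simulates one long single-prey session, samples a 60-neuron ground-truth
# ensemble with known tuned variable sets (world-centric position,
# direction, speed; avatar-centric prey distance and angle), and writes the
# session states, spike table, and per-neuron ground truth to
# results/ensemble/ for the downstream fitting and decoding steps.

suppressMessages(library(pursuitglm))
dir.create("results/ensemble", recursive = TRUE, showWarnings = FALSE)

cfg <- world_config()
dt <- cfg$frame_dt
set.seed(7)

sess <- run_session(cfg, subject_policy("predictive"), 120, seed = 7,
                    two_prey = FALSE, predator = FALSE)
states <- session_states(sess, cfg)
message(sprintf("session: %d trials, %d frames (%.1f task-minutes)",
                length(sess$trials), nrow(states), nrow(states) * dt / 60))

specs <- default_variable_specs(cfg)
use_vars <- c("self_pos", "self_dir", "self_speed", "prey_dist", "prey_angle")
blocks <- session_design(states, specs, use_vars)

subsets <- list("self_pos", "self_dir", "self_speed", "prey_dist",
                "prey_angle", c("self_pos", "self_dir"),
                c("self_pos", "prey_angle"), character(0))
neurons <- lapply(1:60, function(i)
  sample_ground_truth(specs, subsets[[((i - 1) %% length(subsets)) + 1]],
                      smoothness = 2, strength = 0.8,
                      baseline_range = c(2, 10)))
counts <- simulate_ensemble(neurons, blocks, dt)

write.csv(states, "results/ensemble/states.csv", row.names = FALSE)
write_spikes(counts, "results/ensemble/spikes.csv")
for (i in seq_along(neurons))
  write_neuron_json(neurons[[i]],
                    sprintf("results/ensemble/neuron_%03d.json", i))
truth <- data.frame(neuron = seq_along(neurons),
                    tuned = vapply(neurons, function(n)
                      paste(names(n$filters), collapse = "+"), character(1)))
write.csv(truth, "results/ensemble/ground_truth_sets.csv", row.names = FALSE)

message(sprintf("wrote %d neurons (mean rate %.1f spikes/s) to results/ensemble/",
                length(neurons), mean(counts) / dt))
print(table(truth$tuned))
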