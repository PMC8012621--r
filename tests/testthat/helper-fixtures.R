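# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A moderate single-prey session (no predator) reused across GLM, tuning,
# mixed-selectivity, and decoding unit tests: ~11 minutes of task time.
test_session <- function() {
  if (is.null(.fixtures$sess)) {
    cfg <- world_config()
    s <- run_session(cfg, subject_policy("predictive"), 40, seed = 4242,
                     two_prey = FALSE, predator = FALSE)
    states <- session_states(s, cfg)
    specs <- default_variable_specs(cfg)
    blocks <- session_design(states, specs,
                             c("self_pos", "self_dir", "self_speed",
                               "prey_dist", "prey_angle"))
    .fixtures$sess <- list(cfg = cfg, trials = s$trials, states = states,
                           specs = specs, blocks = blocks,
                           dt = cfg$frame_dt)
  }
  .fixtures$sess
}

# Independent prey/predator step oracle: exhaustive candidate evaluation
# written against the stated rules, not the package internals.
oracle_prey_step <- function(prey_pos, subject_pos, max_step, pol, cfg) {
  ang <- 2 * pi * (0:(pol$n_candidates - 1)) / pol$n_candidates
  cx <- prey_pos[1] + max_step * cos(ang)
  cy <- prey_pos[2] + max_step * sin(ang)
  centre <- 0.5 * (((cx - cfg$field_width / 2) / (cfg$field_width / 2))^2 +
                   ((cy - cfg$field_height / 2) / (cfg$field_height / 2))^2)
  d <- sqrt((cx - subject_pos[1])^2 + (cy - subject_pos[2])^2)
  sig <- pol$distance_cost_scale /
    (1 + exp(pol$distance_cost_slope * (d - pol$distance_cost_midpoint)))
  sig[d >= pol$distance_cost_cutoff] <- 0
  cost <- pol$center_bias_weight * centre + sig
  ok <- cx >= 0 & cx <= cfg$field_width & cy >= 0 & cy <= cfg$field_height
  cost[!ok] <- Inf
  best <- which(cost <= min(cost) + 1e-9)[1]  # contract: lowest index on ties
  c(cx[best], cy[best])
}
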