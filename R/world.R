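#' World configuration for the pursuit/evasion task
#'
#' Bundles the physical constants of the virtual pen: field size, frame
#' duration, agent speed caps and sizes, trial timeout, the minimum initial
#' subject--prey separation, trial-type probabilities, and the reward/penalty
#' menus. Defaults reproduce the task as run in the original experiment:
#' a 1920 x 1080 px field, 16.67 ms frames, a 23 px/frame subject speed cap,
#' a 15 px diameter avatar, 30 px prey squares, a 20 s timeout, a 400 px
#' minimum initial distance, predators on 25% of trials and two prey on 50%.
#'
#' Prey maximum speeds were staircased online in the experiment and are not
#' published; the defaults increase with reward value (the task's deliberate
#' value-speed confound), topping out just below the subject's cap.
#'
#' @param field_width,field_height Field size in pixels.
#' @param frame_dt Frame duration in seconds.
#' @param subject_max_speed Subject speed cap, px/frame.
#' @param prey_speeds Named numeric vector of prey max speeds (px/frame),
#'   names are reward values in mL.
#' @param predator_max_speed Predator speed cap, px/frame. Default 0.8 x
#'   subject cap so predator trials are survivable.
#' @param avatar_radius Avatar circle radius, px.
#' @param prey_half_side,predator_half_side Half side length of the prey
#'   square / predator bounding square, px.
#' @param trial_timeout Trial timeout, seconds.
#' @param min_initial_distance Minimum initial distance between subject and
#'   any other agent, px.
#' @param predator_probability Fraction of trials with a predator.
#' @param two_prey_probability Fraction of trials with two prey.
#' @param reward_menu Reward values (mL) a prey can carry.
#' @param penalty_menu Timeout penalties (s) a predator can impose.
#' @param inertia Maximum per-frame change of the subject's velocity, as a
#'   fraction of `subject_max_speed`. Prevents instantaneous reversals.
#' @return A list of class `world_config`.
#' @export
world_config <- function(field_width = 1920, field_height = 1080,
                         frame_dt = 0.01667,
                         subject_max_speed = 23,
                         prey_speeds = c(`0.3` = 14, `0.4` = 16, `0.5` = 18,
                                         `0.6` = 20, `0.7` = 22),
                         predator_max_speed = 0.8 * subject_max_speed,
                         avatar_radius = 7.5,
                         prey_half_side = 15,
                         predator_half_side = 15,
                         trial_timeout = 20,
                         min_initial_distance = 400,
                         predator_probability = 0.25,
                         two_prey_probability = 0.5,
                         reward_menu = c(0.3, 0.4, 0.5, 0.6, 0.7),
                         penalty_menu = c(2, 4, 6, 8, 10),
                         inertia = 0.3) {
  stopifnot(field_width > 0, field_height > 0, frame_dt > 0,
            subject_max_speed > 0, all(prey_speeds > 0),
            predator_max_speed > 0, trial_timeout > 0,
            predator_probability >= 0, predator_probability <= 1,
            two_prey_probability >= 0, two_prey_probability <= 1,
            min_initial_distance < sqrt(field_width^2 + field_height^2),
            inertia > 0)
  if (is.null(names(prey_speeds)))
    names(prey_speeds) <- as.character(reward_menu)
  cfg <- list(field_width = field_width, field_height = field_height,
              frame_dt = frame_dt, subject_max_speed = subject_max_speed,
              prey_speeds = prey_speeds,
              predator_max_speed = predator_max_speed,
              avatar_radius = avatar_radius, prey_half_side = prey_half_side,
              predator_half_side = predator_half_side,
              trial_timeout = trial_timeout,
              min_initial_distance = min_initial_distance,
              predator_probability = predator_probability,
              two_prey_probability = two_prey_probability,
              reward_menu = reward_menu, penalty_menu = penalty_menu,
              inertia = inertia)
  class(cfg) <- "world_config"
  cfg
}

#' Prey movement policy
#'
#' The prey evaluates `n_candidates` future positions spaced equally on a
#' circle of radius equal to its per-frame speed cap and moves to the
#' cheapest in-bounds one. Cost is the sum of a center-bias surface (a
#' quadratic bowl over the field, normalized to \[0, 1\], favoring the
#' center) and a sigmoidal cost of distance to the subject's avatar that
#' grows as the subject approaches and is exactly zero beyond
#' `distance_cost_cutoff`.
#'
#' @param n_candidates Number of candidate positions per frame.
#' @param center_bias_weight Weight of the center-bias cost term.
#' @param distance_cost_scale Height of the subject-distance cost term.
#' @param distance_cost_midpoint Sigmoid midpoint, px.
#' @param distance_cost_slope Sigmoid slope, 1/px.
#' @param distance_cost_cutoff Distance beyond which the subject exerts no
#'   cost, px. Matched by default to the 400 px minimum initial distance.
#' @return A list of class `prey_policy`.
#' @export
prey_policy <- function(n_candidates = 15, center_bias_weight = 1,
                        distance_cost_scale = 2,
                        distance_cost_midpoint = 200,
                        distance_cost_slope = 0.02,
                        distance_cost_cutoff = 400) {
  stopifnot(n_candidates >= 2, distance_cost_cutoff > 0,
            is.finite(center_bias_weight))
  pol <- list(n_candidates = n_candidates,
              center_bias_weight = center_bias_weight,
              distance_cost_scale = distance_cost_scale,
              distance_cost_midpoint = distance_cost_midpoint,
              distance_cost_slope = distance_cost_slope,
              distance_cost_cutoff = distance_cost_cutoff)
  class(pol) <- "prey_policy"
  pol
}

#' Subject (player) policy
#'
#' The artificial-agent family used to characterize behavioral strategies.
#' `predictive`/`reactive` agents aim at the prey's position extrapolated
#' `tau` frames forward under Newtonian physics (positive tau = predictive,
#' negative = reactive, 0 = pure homing) and add an avoidance vector away
#' from the predator weighted by a sigmoid of predator distance whose range
#' is `narrow` (short range) or `broad` (long range). `random_walk` agents
#' take a seeded random heading with bounded turning per frame and never
#' look at the prey.
#'
#' @param kind One of `"predictive"`, `"reactive"`, `"random_walk"`.
#' @param tau Frames of Newtonian extrapolation. Defaults to +30 for
#'   predictive and -30 for reactive, the fixed values used for the agent
#'   family.
#' @param predator_influence `"narrow"` or `"broad"` distance-dependent
#'   influence of the predator.
#' @param influence_midpoint Sigmoid midpoint of the avoidance weight, px;
#'   default 150 (narrow) or 500 (broad).
#' @param influence_slope Sigmoid slope of the avoidance weight, 1/px.
#' @param target_rule How a target prey is chosen on two-prey trials:
#'   `"highest_value"`, `"nearest"`, or `"first"`.
#' @param max_turn Random-walk maximum heading change per frame, radians.
#' @return A list of class `subject_policy`.
#' @export
subject_policy <- function(kind = c("predictive", "reactive", "random_walk"),
                           tau = NULL,
                           predator_influence = c("narrow", "broad"),
                           influence_midpoint = NULL,
                           influence_slope = 0.02,
                           target_rule = c("highest_value", "nearest", "first"),
                           max_turn = pi / 6) {
  kind <- match.arg(kind)
  predator_influence <- match.arg(predator_influence)
  target_rule <- match.arg(target_rule)
  if (is.null(tau))
    tau <- switch(kind, predictive = 30, reactive = -30, random_walk = 0)
  stopifnot(is.finite(tau))
  if (is.null(influence_midpoint))
    influence_midpoint <- switch(predator_influence, narrow = 150, broad = 500)
  pol <- list(kind = kind, tau = tau,
              predator_influence = predator_influence,
              influence_midpoint = influence_midpoint,
              influence_slope = influence_slope,
              target_rule = target_rule, max_turn = max_turn)
  class(pol) <- "subject_policy"
  pol
}

#' Candidate future positions on a circle
#'
#' The `n` positions an agent can move to in one frame, spaced equally on
#' the circumference of a circle of radius `max_step` centered on `pos`,
#' in deterministic angular order starting at angle 0 (positive x axis).
#'
#' @param pos Numeric length-2, current (x, y) in px.
#' @param max_step Circle radius: the maximum distance travelable in one
#'   frame, px.
#' @param n Number of candidates (>= 2).
#' @return An `n` x 2 matrix of (x, y) candidates.
#' @export
candidate_positions <- function(pos, max_step, n = 15) {
  stopifnot(length(pos) == 2, max_step >= 0, n >= 2)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(pos[1] + max_step * cos(ang), pos[2] + max_step * sin(ang))
}

# Center-bias cost surface: quadratic bowl over the field, 0 at center,
# 1 at the corners.
center_bias <- function(x, y, cfg) {
  0.5 * (((x - cfg$field_width / 2) / (cfg$field_width / 2))^2 +
         ((y - cfg$field_height / 2) / (cfg$field_height / 2))^2)
}

# Sigmoidal cost of subject proximity; exactly zero beyond the cutoff.
subject_distance_cost <- function(d, policy) {
  cost <- policy$distance_cost_scale /
    (1 + exp(policy$distance_cost_slope * (d - policy$distance_cost_midpoint)))
  cost[d >= policy$distance_cost_cutoff] <- 0
  cost
}

in_field <- function(xy, cfg) {
  xy[, 1] >= 0 & xy[, 1] <= cfg$field_width &
    xy[, 2] >= 0 & xy[, 2] <= cfg$field_height
}

#' One evasion step of the prey
#'
#' Evaluates the candidate positions and returns the in-bounds candidate
#' with the lowest total cost (center bias + sigmoidal subject-distance
#' cost). If the cheapest candidate is out of bounds the next-cheapest
#' in-bounds one is taken; ties break to the lowest candidate index.
#'
#' @param prey_pos,subject_pos Numeric length-2 positions, px.
#' @param max_step Prey speed cap, px/frame.
#' @param policy A [prey_policy()].
#' @param cfg A [world_config()].
#' @return Numeric length-2: the chosen next position.
#' @export
prey_step <- function(prey_pos, subject_pos, max_step, policy, cfg) {
  cand <- candidate_positions(prey_pos, max_step, policy$n_candidates)
  d <- sqrt((cand[, 1] - subject_pos[1])^2 + (cand[, 2] - subject_pos[2])^2)
  cost <- policy$center_bias_weight * center_bias(cand[, 1], cand[, 2], cfg) +
    subject_distance_cost(d, policy)
  ok <- in_field(cand, cfg)
  if (!any(ok)) stop("all prey candidate positions are out of bounds; check speeds vs field size")
  cost[!ok] <- Inf
  # lowest index wins on ties (up to floating-point noise)
  cand[which(cost <= min(cost) + 1e-9)[1], ]
}

#' One pursuit step of the predator
#'
#' The predator's single rule: move to the in-bounds candidate position that
#' minimizes Euclidean distance to the subject; ties break to the lowest
#' candidate index.
#'
#' @inheritParams prey_step
#' @param pred_pos Predator position, px.
#' @param n_candidates Candidate count (same construction as the prey).
#' @return Numeric length-2: the chosen next position.
#' @export
predator_step <- function(pred_pos, subject_pos, max_step, cfg,
                          n_candidates = 15) {
  cand <- candidate_positions(pred_pos, max_step, n_candidates)
  d2 <- (cand[, 1] - subject_pos[1])^2 + (cand[, 2] - subject_pos[2])^2
  ok <- in_field(cand, cfg)
  if (!any(ok)) stop("all predator candidate positions are out of bounds")
  d2[!ok] <- Inf
  cand[which(d2 <= min(d2) * (1 + 1e-12) + 1e-9)[1], ]
}
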