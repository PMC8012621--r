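# Trial and session loops for the pursuit/evasion world.

# Evaluate f with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, f) {
  if (is.null(seed)) return(f())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

# Circle (avatar) vs axis-aligned square overlap: TRUE on any overlap.
circle_square_overlap <- function(center, radius, square_center, half_side) {
  dx <- max(abs(center[1] - square_center[1]) - half_side, 0)
  dy <- max(abs(center[2] - square_center[2]) - half_side, 0)
  dx * dx + dy * dy <= radius * radius
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' One step of the subject's movement policy
#'
#' For `predictive`/`reactive` policies: aim at the target prey's position
#' extrapolated `tau` frames forward (clipped to the field), head toward it
#' at the speed cap, and add an avoidance vector pointing away from the
#' predator weighted by a sigmoid of predator distance; the sum is
#' renormalized to respect the cap. For `random_walk`: rotate the current
#' heading by a uniform draw in `[-max_turn, max_turn]` and move at the cap
#' (consumes the caller's RNG stream, so identical seeds give identical
#' walks).
#'
#' @param self_pos Subject position (x, y), px.
#' @param heading Current heading, radians (used by random walk).
#' @param preys List of prey states, each `list(pos=, vel=, value=)`.
#' @param pred_pos Predator position or `NULL`.
#' @param policy A [subject_policy()].
#' @param cfg A [world_config()].
#' @return `list(vel = c(vx, vy), heading = <rad>)`: the commanded velocity
#'   (px/frame) before inertia, and the updated heading.
#' @export
subject_step <- function(self_pos, heading, preys, pred_pos, policy, cfg) {
  vmax <- cfg$subject_max_speed
  if (policy$kind == "random_walk") {
    heading <- heading + stats::runif(1, -policy$max_turn, policy$max_turn)
    return(list(vel = vmax * c(cos(heading), sin(heading)), heading = heading))
  }
  if (length(preys) == 0) stop("subject policy requires at least one prey")
  target <- switch(policy$target_rule,
    highest_value = which.max(vapply(preys, `[[`, numeric(1), "value")),
    nearest = which.min(vapply(preys, function(p)
      sum((p$pos - self_pos)^2), numeric(1))),
    first = 1L)
  p <- preys[[target]]
  aim <- p$pos + policy$tau * p$vel
  aim <- c(clamp(aim[1], 0, cfg$field_width), clamp(aim[2], 0, cfg$field_height))
  dirv <- aim - self_pos
  nd <- sqrt(sum(dirv^2))
  v <- if (nd > 0) vmax * dirv / nd else c(0, 0)
  if (!is.null(pred_pos)) {
    away <- self_pos - pred_pos
    d <- sqrt(sum(away^2))
    w <- 1 / (1 + exp(policy$influence_slope * (d - policy$influence_midpoint)))
    if (d > 0) v <- v + vmax * w * away / d
    nv <- sqrt(sum(v^2))
    if (nv > vmax) v <- v * vmax / nv
  }
  list(vel = v, heading = if (sqrt(sum(v^2)) > 1e-9) atan2(v[2], v[1]) else heading)
}

draw_position <- function(cfg, margin = 20) {
  margin <- min(margin, cfg$field_width / 4, cfg$field_height / 4)
  c(stats::runif(1, margin, cfg$field_width - margin),
    stats::runif(1, margin, cfg$field_height - margin))
}

#' Run one pursuit/evasion trial
#'
#' Frame loop applying the subject, prey, and predator policies under the
#' speed caps and inertia. Capture is any overlap between the avatar circle
#' and a prey square, tested every frame; capture by the predator is tested
#' the same way. The trial ends at the first capture/caught event or at the
#' timeout (default 20 s = 1200 frames), whichever comes first.
#'
#' @param cfg A [world_config()].
#' @param policy A [subject_policy()].
#' @param trial_spec `list(prey_values=, predator=, penalty_s=)`: reward
#'   values (mL) of the 1-2 prey on screen, whether a predator is present,
#'   and its penalty. Built by [run_session()] or by hand.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param prey_pol A [prey_policy()].
#' @return A `trial_result`: `outcome` (`"capture"`, `"caught_by_predator"`,
#'   `"timeout"`), `capture_time` (s, `NA` unless capture), `captured_prey`,
#'   `reward_mL`, `prey_values`, `predator_present`, and `trajectory`, a tidy
#'   data frame (frame, time_s, agent_role, agent_id, x, y, vx, vy) with
#'   velocities in px/frame.
#' @export
run_trial <- function(cfg, policy, trial_spec, seed = NULL,
                      prey_pol = prey_policy()) {
  with_seed(seed, function() {
    n_prey <- length(trial_spec$prey_values)
    if (n_prey < 1) stop("trial_spec must contain at least one prey")
    has_pred <- isTRUE(trial_spec$predator)
    n_max <- round(cfg$trial_timeout / cfg$frame_dt)

    self_pos <- draw_position(cfg)
    far_from_self <- function() {
      repeat {
        p <- draw_position(cfg)
        if (sqrt(sum((p - self_pos)^2)) >= cfg$min_initial_distance) return(p)
      }
    }
    prey_pos <- lapply(seq_len(n_prey), function(i)
      if (!is.null(trial_spec$prey_pos)) trial_spec$prey_pos[[i]] else far_from_self())
    pred_pos <- if (has_pred) far_from_self() else NULL

    prey_speed <- cfg$prey_speeds[as.character(trial_spec$prey_values)]
    prey_speed[is.na(prey_speed)] <- mean(cfg$prey_speeds)

    n_agents <- 1L + n_prey + has_pred
    X <- matrix(NA_real_, n_max + 1L, n_agents)  # columns: self, prey..., pred
    Y <- X
    self_vel <- c(0, 0)
    prey_vel <- rep(list(c(0, 0)), n_prey)
    pred_vel <- c(0, 0)
    heading <- stats::runif(1, 0, 2 * pi)
    alive <- rep(TRUE, n_prey)
    outcome <- "timeout"
    captured <- NA_integer_
    end_frame <- n_max

    record <- function(f) {
      X[f + 1L, 1L] <<- self_pos[1]; Y[f + 1L, 1L] <<- self_pos[2]
      for (i in seq_len(n_prey)) {
        X[f + 1L, 1L + i] <<- prey_pos[[i]][1]; Y[f + 1L, 1L + i] <<- prey_pos[[i]][2]
      }
      if (has_pred) { X[f + 1L, n_agents] <<- pred_pos[1]; Y[f + 1L, n_agents] <<- pred_pos[2] }
    }

    for (f in 0:n_max) {
      record(f)
      # terminal checks at the current state
      hit <- which(alive & vapply(seq_len(n_prey), function(i)
        circle_square_overlap(self_pos, cfg$avatar_radius, prey_pos[[i]],
                              cfg$prey_half_side), logical(1)))
      if (length(hit) > 0) {
        outcome <- "capture"; captured <- hit[1]; end_frame <- f; break
      }
      if (has_pred && circle_square_overlap(self_pos, cfg$avatar_radius,
                                            pred_pos, cfg$predator_half_side)) {
        outcome <- "caught_by_predator"; end_frame <- f; break
      }
      if (f == n_max) { end_frame <- f; break }

      # policy steps
      preys <- lapply(which(alive), function(i)
        list(pos = prey_pos[[i]], vel = prey_vel[[i]],
             value = trial_spec$prey_values[i]))
      cmd <- subject_step(self_pos, heading, preys, pred_pos, policy, cfg)
      heading <- cmd$heading
      dv <- cmd$vel - self_vel
      dvn <- sqrt(sum(dv^2))
      dv_max <- cfg$inertia * cfg$subject_max_speed
      if (dvn > dv_max) dv <- dv * dv_max / dvn
      self_vel <- self_vel + dv
      sv <- sqrt(sum(self_vel^2))
      if (sv > cfg$subject_max_speed)
        self_vel <- self_vel * cfg$subject_max_speed / sv
      new_self <- c(clamp(self_pos[1] + self_vel[1], 0, cfg$field_width),
                    clamp(self_pos[2] + self_vel[2], 0, cfg$field_height))
      self_vel <- new_self - self_pos
      self_pos <- new_self

      for (i in seq_len(n_prey)) {
        if (!alive[i]) next
        np <- prey_step(prey_pos[[i]], self_pos, prey_speed[i], prey_pol, cfg)
        prey_vel[[i]] <- np - prey_pos[[i]]
        prey_pos[[i]] <- np
      }
      if (has_pred) {
        np <- predator_step(pred_pos, self_pos, cfg$predator_max_speed, cfg,
                            prey_pol$n_candidates)
        pred_vel <- np - pred_pos
        pred_pos <- np
      }
    }

    frames <- 0:end_frame
    idx <- frames + 1L
    roles <- c("self", rep("prey", n_prey), if (has_pred) "predator")
    ids <- c("self", paste0("prey", seq_len(n_prey)), if (has_pred) "predator")
    traj <- do.call(rbind, lapply(seq_len(n_agents), function(a) {
      x <- X[idx, a]; y <- Y[idx, a]
      data.frame(frame = frames, time_s = frames * cfg$frame_dt,
                 agent_role = roles[a], agent_id = ids[a], x = x, y = y,
                 vx = c(0, diff(x)), vy = c(0, diff(y)),
                 stringsAsFactors = FALSE)
    }))
    res <- list(outcome = outcome,
                capture_time = if (outcome == "capture")
                  end_frame * cfg$frame_dt else NA_real_,
                captured_prey = captured,
                reward_mL = if (outcome == "capture")
                  trial_spec$prey_values[captured] else 0,
                prey_values = trial_spec$prey_values,
                predator_present = has_pred,
                penalty_s = trial_spec$penalty_s,
                n_frames = end_frame + 1L,
                trajectory = traj)
    class(res) <- "trial_result"
    res
  })
}

#' Run a session of trials
#'
#' Draws trial types (predator present with probability
#' `cfg$predator_probability`, two prey with `cfg$two_prey_probability`,
#' prey values from the reward menu, distinct on two-prey trials), runs each
#' trial, and aggregates a session summary.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer session seed.
#' @param two_prey,predator Optional logical overrides forcing every trial's
#'   type (e.g. `predator = FALSE` for single-prey-only sessions).
#' @return `list(summary=, trials=)`; `summary` holds capture/caught/timeout
#'   rates, capture-time stats, and per-value choice counts on two-prey
#'   trials.
#' @export
run_session <- function(cfg, policy, n_trials, seed = NULL,
                        prey_pol = prey_policy(),
                        two_prey = NULL, predator = NULL) {
  stopifnot(n_trials >= 1)
  with_seed(seed, function() {
    trials <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      two <- if (is.null(two_prey))
        stats::runif(1) < cfg$two_prey_probability else two_prey
      pred <- if (is.null(predator))
        stats::runif(1) < cfg$predator_probability else predator
      vals <- sample(cfg$reward_menu, if (two) 2 else 1)
      spec <- list(prey_values = vals, predator = pred,
                   penalty_s = if (pred) sample(cfg$penalty_menu, 1) else NA)
      trials[[k]] <- run_trial(cfg, policy, spec, seed = NULL,
                               prey_pol = prey_pol)
    }
    list(summary = session_summary(trials), trials = trials)
  })
}

# Aggregate counts over a list of trial_results.
session_summary <- function(trials) {
  outcomes <- vapply(trials, `[[`, character(1), "outcome")
  ct <- vapply(trials, `[[`, numeric(1), "capture_time")
  two <- vapply(trials, function(t) length(t$prey_values) == 2, logical(1))
  choice <- NULL
  if (any(two)) {
    tw <- trials[two]
    cap <- vapply(tw, function(t) t$outcome == "capture", logical(1))
    if (any(cap)) {
      tw <- tw[cap]
      vdiff <- vapply(tw, function(t)
        t$prey_values[t$captured_prey] - t$prey_values[-t$captured_prey][1],
        numeric(1))
      chose_higher <- vapply(tw, function(t)
        t$prey_values[t$captured_prey] >= max(t$prey_values), logical(1))
      absdiff <- round(abs(vdiff), 10)
      choice <- data.frame(value_diff = sort(unique(absdiff)))
      choice$n <- vapply(choice$value_diff, function(d)
        sum(absdiff == d), numeric(1))
      choice$prop_higher <- vapply(choice$value_diff, function(d)
        mean(chose_higher[absdiff == d]), numeric(1))
    }
  }
  list(n_trials = length(trials),
       capture_rate = mean(outcomes == "capture"),
       caught_rate = mean(outcomes == "caught_by_predator"),
       timeout_rate = mean(outcomes == "timeout"),
       n_predator_trials = sum(vapply(trials, `[[`, logical(1),
                                      "predator_present")),
       capture_time_mean = mean(ct, na.rm = TRUE),
       capture_time_median = stats::median(ct, na.rm = TRUE),
       capture_times = ct[!is.na(ct)],
       choice_by_value_diff = choice)
}
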