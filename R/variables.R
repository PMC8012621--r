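# Task-variable definitions, binning, and one-hot design blocks.

#' Define a binned task variable
#'
#' A `variable_spec` fixes how one continuous task variable is discretized
#' for the LN model and which smoothing topology couples its bins:
#' `position2d` variables are an `n_x` x `n_y` grid penalized along rows and
#' columns separately, `circular` variables wrap around 360 degrees,
#' `linear` variables form a chain, and `discrete` variables have no
#' smoothing (they take the lasso penalty instead).
#'
#' All bins are half-open `[lo, hi)`; values exactly at the top edge belong
#' to the last bin. Linear variables with `clip = TRUE` clamp out-of-range
#' values into the end bins (used for distances, which have a long tail).
#'
#' @param name Variable name.
#' @param kind `"position2d"`, `"circular"`, `"linear"`, or `"discrete"`.
#' @param n_x,n_y Grid size for `position2d` (default 15 x 15).
#' @param x_range,y_range Grid extent for `position2d`.
#' @param n_bins Bin count for circular/linear/discrete.
#' @param edges Bin edges for `linear` (length `n_bins + 1`, strictly
#'   increasing); circular edges are always equal 360/n-degree sectors.
#' @param levels Levels for `discrete`.
#' @param clip Clamp out-of-range linear values into the end bins.
#' @return A list of class `variable_spec` with a `bin_count` field.
#' @export
variable_spec <- function(name,
                          kind = c("position2d", "circular", "linear", "discrete"),
                          n_x = 15, n_y = 15,
                          x_range = c(0, 1920), y_range = c(0, 1080),
                          n_bins = 12, edges = NULL, levels = NULL,
                          clip = FALSE) {
  kind <- match.arg(kind)
  spec <- list(name = name, kind = kind, clip = clip)
  if (kind == "position2d") {
    stopifnot(n_x >= 2, n_y >= 2)
    spec$n_x <- n_x; spec$n_y <- n_y
    spec$x_edges <- seq(x_range[1], x_range[2], length.out = n_x + 1)
    spec$y_edges <- seq(y_range[1], y_range[2], length.out = n_y + 1)
    spec$bin_count <- as.integer(n_x * n_y)
  } else if (kind == "circular") {
    stopifnot(n_bins >= 2)
    spec$edges <- seq(0, 360, length.out = n_bins + 1)
    spec$bin_count <- as.integer(n_bins)
  } else if (kind == "linear") {
    if (is.null(edges)) edges <- seq(0, 1, length.out = n_bins + 1)
    stopifnot(length(edges) >= 3, all(diff(edges) > 0))
    spec$edges <- edges
    spec$bin_count <- length(edges) - 1L
  } else {
    stopifnot(length(levels) >= 2)
    spec$levels <- levels
    spec$bin_count <- length(levels)
  }
  class(spec) <- "variable_spec"
  spec
}

bin_1d <- function(v, edges, clip = FALSE, what = "value") {
  if (clip) v <- pmin(pmax(v, edges[1]), edges[length(edges)])
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  if (anyNA(idx) || any(idx < 1L | idx > length(edges) - 1L))
    stop(sprintf("%s outside bin edges [%g, %g]", what, edges[1],
                 edges[length(edges)]))
  as.integer(idx)
}

#' Bin raw values into a one-hot design block
#'
#' Converts per-frame values of one task variable into the active-bin index
#' per frame (the compact form of the T x bin_count one-hot matrix X_i in
#' which every row has exactly one 1). Circular values must lie in
#' `[0, 360)`; linear values outside the edges raise an error unless the
#' spec was built with `clip = TRUE`.
#'
#' @param values Numeric vector, or a 2-column (x, y) matrix for
#'   `position2d` specs.
#' @param spec A [variable_spec()].
#' @return A `design_block`: `list(name, spec, index)` with `index` the
#'   integer active bin per frame. Use [as_design_matrix()] for the dense
#'   one-hot form.
#' @export
bin_state <- function(values, spec) {
  idx <- switch(spec$kind,
    position2d = {
      stopifnot(is.matrix(values) || is.data.frame(values))
      values <- as.matrix(values)
      ix <- bin_1d(values[, 1], spec$x_edges, clip = TRUE, what = spec$name)
      iy <- bin_1d(values[, 2], spec$y_edges, clip = TRUE, what = spec$name)
      (iy - 1L) * spec$n_x + ix
    },
    circular = {
      # serialization round trips can turn 359.999... into exactly 360
      values[values >= 360 & values < 360 + 1e-6] <- 0
      if (any(values < 0 | values >= 360, na.rm = TRUE))
        stop(sprintf("%s: circular values must lie in [0, 360)", spec$name))
      bin_1d(values, spec$edges, what = spec$name)
    },
    linear = bin_1d(values, spec$edges, clip = spec$clip, what = spec$name),
    discrete = {
      idx <- match(values, spec$levels)
      if (anyNA(idx)) stop(sprintf("%s: unknown discrete level", spec$name))
      as.integer(idx)
    })
  structure(list(name = spec$name, spec = spec, index = as.integer(idx)),
            class = "design_block")
}

#' Dense one-hot matrix of a design block
#'
#' @param block A `design_block` from [bin_state()].
#' @return A T x bin_count 0/1 matrix whose rows each sum to 1.
#' @export
as_design_matrix <- function(block) {
  m <- matrix(0L, length(block$index), block$spec$bin_count)
  m[cbind(seq_along(block$index), block$index)] <- 1L
  m
}

# Adjacent-bin pairs penalized by the smoothness regularizer.
# position2d: along-row and along-column neighbors; circular: chain + wrap;
# linear: chain; discrete: none.
penalty_pairs <- function(spec) {
  if (spec$kind == "position2d") {
    nx <- spec$n_x; ny <- spec$n_y
    idx <- function(ix, iy) (iy - 1L) * nx + ix
    horiz <- cbind(idx(rep(1:(nx - 1), ny), rep(1:ny, each = nx - 1)),
                   idx(rep(2:nx, ny), rep(1:ny, each = nx - 1)))
    vert <- cbind(idx(rep(1:nx, ny - 1), rep(1:(ny - 1), each = nx)),
                  idx(rep(1:nx, ny - 1), rep(2:ny, each = nx)))
    rbind(horiz, vert)
  } else if (spec$kind == "circular") {
    n <- spec$bin_count
    cbind(1:n, c(2:n, 1L))
  } else if (spec$kind == "linear") {
    n <- spec$bin_count
    cbind(1:(n - 1L), 2:n)
  } else {
    matrix(integer(0), 0, 2)
  }
}

#' Bin centers of a variable spec
#'
#' @param spec A [variable_spec()].
#' @return An (x, y) matrix for `position2d` specs, otherwise a numeric
#'   vector (degrees for circular specs, level indices for discrete ones).
#' @export
bin_centers <- function(spec) {
  if (spec$kind == "position2d") {
    cx <- (spec$x_edges[-1] + spec$x_edges[-(spec$n_x + 1)]) / 2
    cy <- (spec$y_edges[-1] + spec$y_edges[-(spec$n_y + 1)]) / 2
    cbind(rep(cx, spec$n_y), rep(cy, each = spec$n_x))
  } else if (spec$kind == "discrete") {
    seq_len(spec$bin_count)
  } else {
    (spec$edges[-1] + spec$edges[-length(spec$edges)]) / 2
  }
}

#' Default variable set for the pursuit task
#'
#' The task variables used throughout: agent positions on a 15 x 15 grid
#' over the field, headings in 12 circular bins of 30 degrees, speeds in 12
#' linear bins from 0 to each agent's cap (in px/s), and the avatar-centric
#' pair -- subject-prey (and subject-predator) distance in 12 log-spaced
#' bins from contact (avatar radius + prey half side) to 1000 px, and
#' relative angle in 12 circular bins.
#'
#' @param cfg A [world_config()].
#' @return Named list of [variable_spec()]s.
#' @export
default_variable_specs <- function(cfg = world_config()) {
  pos <- function(name) variable_spec(name, "position2d",
                                      x_range = c(0, cfg$field_width),
                                      y_range = c(0, cfg$field_height))
  speed <- function(name, cap_px_fr)
    variable_spec(name, "linear",
                  edges = seq(0, cap_px_fr / cfg$frame_dt, length.out = 13),
                  clip = TRUE)
  contact <- cfg$avatar_radius + cfg$prey_half_side
  dist_edges <- exp(seq(log(contact), log(1000), length.out = 13))
  list(
    self_pos = pos("self_pos"), prey_pos = pos("prey_pos"),
    pred_pos = pos("pred_pos"),
    self_dir = variable_spec("self_dir", "circular"),
    prey_dir = variable_spec("prey_dir", "circular"),
    pred_dir = variable_spec("pred_dir", "circular"),
    self_speed = speed("self_speed", cfg$subject_max_speed),
    prey_speed = speed("prey_speed", max(cfg$prey_speeds)),
    pred_speed = speed("pred_speed", cfg$predator_max_speed),
    prey_dist = variable_spec("prey_dist", "linear", edges = dist_edges,
                              clip = TRUE),
    pred_dist = variable_spec("pred_dist", "linear", edges = dist_edges,
                              clip = TRUE),
    prey_angle = variable_spec("prey_angle", "circular"),
    pred_angle = variable_spec("pred_angle", "circular"))
}

# Wrap degrees into [0, 360); guards the float edge case where x %% 360
# rounds up to exactly 360.
wrap_deg <- function(x) {
  x <- x %% 360
  x[x >= 360] <- 0
  x
}

# Heading of a velocity series in degrees [0, 360); frames slower than
# `min_speed` px/frame inherit the last valid heading (back-filled at the
# start). Heading is undefined at rest.
heading_deg <- function(vx, vy, min_speed = 0.5) {
  sp <- sqrt(vx^2 + vy^2)
  h <- wrap_deg(atan2(vy, vx) * 180 / pi)
  h[sp < min_speed] <- NA_real_
  if (all(is.na(h))) return(rep(0, length(h)))
  # forward-fill, then back-fill the leading NAs with the first valid heading
  ok <- which(!is.na(h))
  last_valid <- findInterval(seq_along(h), ok)
  h[ok[pmax(last_valid, 1L)]]
}

#' Per-frame task-state table of a session
#'
#' Flattens a list of trials into one frame-indexed table of the raw task
#' variables consumed by the LN model: positions, headings (deg), speeds
#' (px/s), subject-prey and subject-predator distance (px) and relative
#' angle (deg, 0 = prey dead ahead of the current heading), plus the pursued
#' prey's reward value. On multi-prey trials the "prey" columns follow
#' `prey_id` (default the first prey).
#'
#' @param trials List of `trial_result`s (or a [run_session()] output).
#' @param cfg A [world_config()].
#' @param prey_id Prey agent id to treat as the pursued prey.
#' @return A data frame with one row per frame.
#' @export
session_states <- function(trials, cfg = world_config(), prey_id = "prey1") {
  if (!is.null(trials$trials)) trials <- trials$trials
  out <- lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]$trajectory
    pick <- function(id) tr[tr$agent_id == id, , drop = FALSE]
    s <- pick("self"); p <- pick(prey_id)
    pd <- pick("predator")
    has_pred <- nrow(pd) > 0
    dt <- cfg$frame_dt
    self_dir <- heading_deg(s$vx, s$vy)
    bearing <- wrap_deg(atan2(p$y - s$y, p$x - s$x) * 180 / pi)
    ang <- wrap_deg(bearing - self_dir)
    d <- data.frame(
      trial = k, frame = s$frame, time_s = s$time_s,
      self_x = s$x, self_y = s$y,
      self_dir = self_dir, self_speed = sqrt(s$vx^2 + s$vy^2) / dt,
      prey_x = p$x, prey_y = p$y,
      prey_dir = heading_deg(p$vx, p$vy),
      prey_speed = sqrt(p$vx^2 + p$vy^2) / dt,
      prey_dist = sqrt((p$x - s$x)^2 + (p$y - s$y)^2),
      prey_angle = ang,
      prey_value = trials[[k]]$prey_values[1],
      predator_present = has_pred)
    if (has_pred) {
      d$pred_x <- pd$x; d$pred_y <- pd$y
      d$pred_dir <- heading_deg(pd$vx, pd$vy)
      d$pred_speed <- sqrt(pd$vx^2 + pd$vy^2) / dt
      d$pred_dist <- sqrt((pd$x - s$x)^2 + (pd$y - s$y)^2)
      d$pred_angle <- wrap_deg(
        wrap_deg(atan2(pd$y - s$y, pd$x - s$x) * 180 / pi) - self_dir)
    } else {
      d$pred_x <- NA_real_; d$pred_y <- NA_real_; d$pred_dir <- NA_real_
      d$pred_speed <- NA_real_; d$pred_dist <- NA_real_
      d$pred_angle <- NA_real_
    }
    if (!is.null(trials[[k]]$prey_values) &&
        prey_id == "prey1")
      d$prey_value <- trials[[k]]$prey_values[1]
    d
  })
  do.call(rbind, out)
}

# Raw values of one named variable from a session_states() table.
variable_values <- function(states, name) {
  switch(name,
    self_pos = cbind(states$self_x, states$self_y),
    prey_pos = cbind(states$prey_x, states$prey_y),
    pred_pos = cbind(states$pred_x, states$pred_y),
    self_dir = states$self_dir, prey_dir = states$prey_dir,
    pred_dir = states$pred_dir,
    self_speed = states$self_speed, prey_speed = states$prey_speed,
    pred_speed = states$pred_speed,
    prey_dist = states$prey_dist, pred_dist = states$pred_dist,
    prey_angle = states$prey_angle, pred_angle = states$pred_angle,
    stop(sprintf("unknown variable '%s'", name)))
}

#' Bin all requested variables of a session
#'
#' @param states A [session_states()] table.
#' @param specs Named list of [variable_spec()]s.
#' @param variables Which variables to bin (default all in `specs`).
#' @return Named list of `design_block`s sharing the frame axis.
#' @export
session_design <- function(states, specs, variables = names(specs)) {
  blocks <- lapply(variables, function(v)
    bin_state(variable_values(states, v), specs[[v]]))
  names(blocks) <- variables
  blocks
}
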