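# Behavioral analyses: trajectory-based trial sorting (TBTS),
# moment-by-moment chase/avoid labeling, and session summaries.

#' Dynamic time warping distance between two position tracks
#'
#' Classic O(mn) DTW with Euclidean local cost on (x, y) samples; no
#' step-size constraint. Used by TBTS on short sliding windows.
#'
#' @param a,b Matrices of (x, y) positions.
#' @return The accumulated DTW distance.
#' @export
dtw_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  m <- nrow(a); n <- nrow(b)
  stopifnot(m >= 1, n >= 1)
  D <- matrix(Inf, m + 1, n + 1)
  D[1, 1] <- 0
  for (i in seq_len(m)) {
    dx <- a[i, 1] - b[, 1]; dy <- a[i, 2] - b[, 2]
    cost <- sqrt(dx * dx + dy * dy)
    for (j in seq_len(n))
      D[i + 1, j + 1] <- cost[j] + min(D[i, j + 1], D[i + 1, j], D[i, j])
  }
  D[m + 1, n + 1]
}

boxcar <- function(x, width = 5) {
  # centered moving average with shrinking windows at the edges
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

minmax_norm <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Trajectory-based trial sorting: which prey is pursued?
#'
#' For every frame and prey, three signals are computed: the angle
#' difference between the subject's step heading and the bearing from the
#' subject to the prey (small when the subject is moving toward that prey),
#' the signed change of subject-prey distance, and the DTW distance between
#' the subject's and the prey's trajectory over a sliding window. Each component
#' is min-max normalized per trial (the raw quantities have incompatible
#' units), the three are multiplied into one scalar per prey, smoothed with
#' a five-frame boxcar, and the prey with the smallest scalar is labeled
#' pursued. A trial whose smoothed label changes is flagged as a switch
#' trial (excluded from single-target analyses downstream).
#'
#' @param trial A `trial_result`, or a list
#'   `list(self = <n x 2>, preys = list(<n x 2>, ...))` of aligned position
#'   tracks.
#' @param dtw_window Sliding DTW window length, frames.
#' @param boxcar_width Boxcar width, frames.
#' @return A `pursuit_labels`: per-frame `pursued` prey index, the smoothed
#'   `scalar` matrix (frames x preys), `switch` flag, and the raw
#'   `components`.
#' @export
tbts <- function(trial, dtw_window = 10, boxcar_width = 5) {
  if (inherits(trial, "trial_result")) {
    tr <- trial$trajectory
    self <- as.matrix(tr[tr$agent_id == "self", c("x", "y")])
    prey_ids <- unique(tr$agent_id[tr$agent_role == "prey"])
    preys <- lapply(prey_ids, function(id)
      as.matrix(tr[tr$agent_id == id, c("x", "y")]))
  } else {
    self <- as.matrix(trial$self)
    preys <- lapply(trial$preys, as.matrix)
  }
  n <- nrow(self)
  if (any(vapply(preys, nrow, integer(1)) != n))
    stop("subject and prey trajectories must have equal length")
  np <- length(preys)
  if (np == 1) {
    return(structure(list(pursued = rep(1L, n),
                          scalar = matrix(0, n, 1), switch = FALSE,
                          components = NULL), class = "pursuit_labels"))
  }
  step_heading <- function(xy) {
    v <- diff(xy)
    c(NA_real_, (atan2(v[, 2], v[, 1]) * 180 / pi) %% 360)
  }
  sh <- step_heading(self)
  comp <- array(NA_real_, c(n, np, 3),
                dimnames = list(NULL, NULL, c("angle", "ddist", "dtw")))
  for (p in seq_len(np)) {
    bearing <- (atan2(preys[[p]][, 2] - self[, 2],
                      preys[[p]][, 1] - self[, 1]) * 180 / pi) %% 360
    ang <- ang_diff_deg(sh, bearing)
    d <- sqrt(rowSums((preys[[p]] - self)^2))
    dd <- c(NA_real_, diff(d))
    dtwv <- vapply(seq_len(n), function(f) {
      lo <- max(1, f - dtw_window + 1)
      dtw_distance(self[lo:f, , drop = FALSE], preys[[p]][lo:f, , drop = FALSE])
    }, numeric(1))
    comp[, p, 1] <- ang; comp[, p, 2] <- dd; comp[, p, 3] <- dtwv
  }
  comp[1, , 1] <- 0; comp[1, , 2] <- 0  # headings/diffs undefined at frame 0
  scal <- matrix(1, n, np)
  for (k in 1:3) {
    normed <- minmax_norm(as.numeric(comp[, , k]))
    scal <- scal * matrix(normed, n, np)
  }
  smooth <- apply(scal, 2, boxcar, width = boxcar_width)
  pursued <- max.col(-smooth, ties.method = "first")
  structure(list(pursued = pursued, scalar = smooth,
                 switch = length(unique(pursued)) > 1,
                 components = comp), class = "pursuit_labels")
}

#' Moment-by-moment chase/avoid classification
#'
#' Per frame: the mode is `avoid` when, for the subject-predator pair, the
#' distance change, the velocity dot product, and the change of the dot
#' product are all positive (moving apart, moving alike, increasingly so);
#' otherwise `chase` when the subject-prey distance is shrinking and the
#' subject-prey velocity dot product is positive; otherwise `neither`.
#' Without a predator the avoid mode is undefined and only chase is scored.
#'
#' @param trial A `trial_result`, or a list with `self`, `prey`, and
#'   optionally `predator` position matrices.
#' @param prey_index Which prey to score chase against (default 1; pass the
#'   [tbts()] label for two-prey trials).
#' @return A `mode_series`: per-frame `mode` factor and the component
#'   signals, plus fraction-of-trial summaries.
#' @export
chase_avoid <- function(trial, prey_index = 1) {
  if (inherits(trial, "trial_result")) {
    tr <- trial$trajectory
    get_xy <- function(id) as.matrix(tr[tr$agent_id == id, c("x", "y")])
    self <- get_xy("self")
    prey <- get_xy(paste0("prey", prey_index))
    pred <- if (any(tr$agent_id == "predator")) get_xy("predator") else NULL
  } else {
    self <- as.matrix(trial$self)
    prey <- as.matrix(trial$prey)
    pred <- if (!is.null(trial$predator)) as.matrix(trial$predator) else NULL
  }
  n <- nrow(self)
  stopifnot(nrow(prey) == n, is.null(pred) || nrow(pred) == n)
  vel <- function(xy) rbind(c(0, 0), diff(xy))
  vs <- vel(self); vp <- vel(prey)
  pair_signals <- function(other_xy, other_v) {
    d <- sqrt(rowSums((other_xy - self)^2))
    dd <- c(NA_real_, diff(d))
    dot <- vs[, 1] * other_v[, 1] + vs[, 2] * other_v[, 2]
    ddot <- c(NA_real_, diff(dot))
    list(ddist = dd, dot = dot, ddot = ddot)
  }
  prey_sig <- pair_signals(prey, vp)
  pred_sig <- if (!is.null(pred)) pair_signals(pred, vel(pred)) else NULL
  avoid <- if (!is.null(pred_sig))
    pred_sig$ddist > 0 & pred_sig$dot > 0 & pred_sig$ddot > 0
  else rep(FALSE, n)
  avoid[is.na(avoid)] <- FALSE
  chase <- prey_sig$ddist < 0 & prey_sig$dot > 0
  chase[is.na(chase)] <- FALSE
  mode <- rep("neither", n)
  mode[chase] <- "chase"
  mode[avoid] <- "avoid"   # avoid takes precedence: modes stay exclusive
  structure(list(mode = factor(mode, levels = c("chase", "avoid", "neither")),
                 prey = prey_sig, predator = pred_sig,
                 fraction = c(chase = mean(mode == "chase"),
                              avoid = mean(mode == "avoid"),
                              neither = mean(mode == "neither"))),
            class = "mode_series")
}

#' Session-level behavioral summary
#'
#' Capture/caught/timeout rates, capture-time statistics, the proportion of
#' higher-value choices by prey-value difference on two-prey trials, and a
#' capture-time table by prey value.
#'
#' @param trials List of `trial_result`s (or a [run_session()] output).
#' @return A list; see [run_session()] for the core fields, plus
#'   `capture_time_by_value`.
#' @export
behavioral_summary <- function(trials) {
  if (!is.null(trials$trials)) trials <- trials$trials
  s <- session_summary(trials)
  cap <- Filter(function(t) t$outcome == "capture", trials)
  if (length(cap) > 0) {
    vals <- vapply(cap, function(t) t$prey_values[t$captured_prey], numeric(1))
    times <- vapply(cap, `[[`, numeric(1), "capture_time")
    s$capture_time_by_value <- do.call(rbind, lapply(sort(unique(vals)),
      function(v) data.frame(value = v, n = sum(vals == v),
                             mean_time = mean(times[vals == v]))))
  } else {
    s$capture_time_by_value <- NULL
  }
  s
}
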