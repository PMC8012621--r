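# Plain-text serialization: tidy trajectory/spike CSVs and JSON round trips
# for ground-truth neurons and fitted models.

#' Write / read a tidy trajectory table
#'
#' One CSV row per (trial, frame, agent): columns trial, frame, time_s,
#' agent_role, agent_id, x, y, vx, vy. Trial metadata (outcome, prey values,
#' reward) goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param trials List of `trial_result`s (or a [run_session()] output).
#' @param path Output CSV path.
#' @export
write_trajectory <- function(trials, path) {
  if (!is.null(trials$trials)) trials <- trials$trials
  tab <- do.call(rbind, lapply(seq_along(trials), function(k)
    cbind(trial = k, trials[[k]]$trajectory)))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- lapply(trials, function(t)
    list(outcome = t$outcome, capture_time = t$capture_time,
         prey_values = t$prey_values, reward_mL = t$reward_mL,
         predator_present = t$predator_present, n_frames = t$n_frames))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: `list(table, meta)`.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  list(table = tab, meta = meta)
}

#' Write / read a spike table
#'
#' Long CSV (neuron, frame, count); zero counts are stored too so the frame
#' axis round-trips exactly.
#'
#' @param counts Frames x neurons integer matrix.
#' @param path Output CSV path.
#' @export
write_spikes <- function(counts, path) {
  tab <- data.frame(neuron = rep(seq_len(ncol(counts)), each = nrow(counts)),
                    frame = rep(seq_len(nrow(counts)), ncol(counts)),
                    count = as.vector(counts))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @return `read_spikes`: the frames x neurons matrix.
#' @export
read_spikes <- function(path) {
  tab <- utils::read.csv(path)
  n_frames <- max(tab$frame)
  n_neurons <- max(tab$neuron)
  m <- matrix(0L, n_frames, n_neurons)
  m[cbind(tab$frame, tab$neuron)] <- as.integer(tab$count)
  m
}

#' JSON round trip for a ground-truth neuron
#'
#' @param neuron A [sample_ground_truth()] neuron.
#' @param path JSON path.
#' @export
write_neuron_json <- function(neuron, path) {
  x <- unclass(neuron)
  if (!is.null(x$reward_gain))
    x$reward_gain <- as.list(x$reward_gain)  # keep names (JSON object)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_neuron_json
#' @export
read_neuron_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$filters <- lapply(x$filters, as.numeric)
  if (!is.null(x$reward_gain)) x$reward_gain <- unlist(x$reward_gain)
  class(x) <- "ground_truth_neuron"
  x
}

#' JSON serialization of a selection result
#'
#' Stores the selected variable set, per-step statistics, fold LLi values,
#' and the final model's bias and weights.
#'
#' @param sel A `selection_result`.
#' @param path JSON path.
#' @export
write_selection_json <- function(sel, path) {
  out <- list(selected = sel$selected, steps = sel$steps,
              fold_lli = sel$fold_lli, single_lli = sel$single_lli,
              bias = sel$model$bias, weights = sel$model$weights,
              dt = sel$model$dt)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
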