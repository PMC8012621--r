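# Maximum-likelihood population decoding of task variables from simulated
# ensemble spikes, and decoding-error vs ensemble-size curves.

# Per-frame rates (spikes/s) of a fitted model over a session; variables the
# selection did not retain simply are not in the model (zero weights).
model_rates <- function(model, blocks, rows = NULL) {
  T_ <- if (is.null(rows)) length(blocks[[1]]$index) else length(rows)
  lp <- rep(model$bias, T_)
  for (v in model$variables) {
    i <- blocks[[v]]$index
    if (!is.null(rows)) i <- i[rows]
    lp <- lp + model$weights[[v]][i]
  }
  exp(lp) / model$dt
}

#' Simulate population spikes from fitted models
#'
#' Draws Poisson spike counts for every neuron from its selected model's
#' rate along a state sequence. Variables a neuron's selection did not
#' retain contribute zero weight by construction.
#'
#' @param models List of `fitted_model`s (one per neuron; pass
#'   `selection$model` for forward-selection outcomes).
#' @param blocks Session design blocks.
#' @return Integer matrix, frames x neurons.
#' @export
simulate_population_spikes <- function(models, blocks) {
  T_ <- length(blocks[[1]]$index)
  counts <- vapply(models, function(m)
    stats::rpois(T_, model_rates(m, blocks) * m$dt), integer(T_))
  counts
}

#' Decode one variable from a spike window
#'
#' Exhaustive maximum-likelihood decoding: for every candidate bin of the
#' target variable, the summed Poisson log-likelihood of the observed window
#' counts across neurons and window bins is evaluated with all other
#' variables clamped at their true binned values; the candidate with the
#' highest summed log-likelihood wins (ties to the lowest bin index).
#'
#' @param counts Frames x neurons spike-count matrix (the whole session).
#' @param models List of `fitted_model`s, one per neuron.
#' @param target Target variable name.
#' @param blocks Session design blocks (provide the true bins for clamping).
#' @param rows Frame indices of the window (`t - L + 1` to `t`).
#' @param spec The target's [variable_spec()] (defaults to the first model
#'   that carries it).
#' @return `list(bin, loglik)`: the decoded bin and the per-candidate summed
#'   log-likelihood (up to the shared `log n!` constant).
#' @export
decode_window <- function(counts, models, target, blocks, rows, spec = NULL) {
  if (is.null(spec)) {
    for (m in models) if (target %in% m$variables) { spec <- m$specs[[target]]; break }
    if (is.null(spec)) spec <- blocks[[target]]$spec
  }
  if (is.null(spec)) stop("empty candidate grid: target spec unknown")
  nb <- spec$bin_count
  nC <- length(models)
  stopifnot(ncol(counts) == nC)
  # W[b, c]: target weight of neuron c at candidate bin b (0 if not selected)
  W <- vapply(models, function(m)
    if (target %in% m$variables) m$weights[[target]] else rep(0, nb),
    numeric(nb))
  W <- matrix(W, nrow = nb)
  n_win <- counts[rows, , drop = FALSE]
  S <- colSums(n_win)                       # total spikes per neuron
  B <- vapply(seq_len(nC), function(c) {    # sum_t exp(base lp) per neuron
    m <- models[[c]]
    lp <- rep(m$bias, length(rows))
    for (v in setdiff(m$variables, target))
      lp <- lp + m$weights[[v]][blocks[[v]]$index[rows]]
    sum(exp(lp))
  }, numeric(1))
  ll <- drop(W %*% S - exp(W) %*% B)
  list(bin = which.max(ll), loglik = ll)
}

ang_diff_deg <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# Decoding error of a candidate bin against the window-average true state
# (the quantity a static-state decoder estimates over the window), in the
# variable's natural units: px for positions, degrees wrapped to [0, 180]
# for circular variables, the variable's own units otherwise.
decode_error <- function(spec, bin, states, rows, target) {
  centers <- bin_centers(spec)
  vals <- variable_values(states[rows, , drop = FALSE], target)
  if (spec$kind == "position2d") {
    truth <- colMeans(as.matrix(vals))
    sqrt(sum((centers[bin, ] - truth)^2))
  } else if (spec$kind == "circular") {
    rad <- vals * pi / 180
    truth <- (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
    ang_diff_deg(centers[bin], truth)
  } else {
    abs(centers[bin] - mean(vals))
  }
}

#' Decoding error vs ensemble size
#'
#' Simulates population spikes from the fitted models, then repeatedly
#' subsamples ensembles of each requested size and decodes the target
#' variable in randomly placed windows of `L` bins; the decoded bin center
#' is compared with the window-average true state (the quantity a
#' static-state decoder estimates over a window). Defaults follow the
#' published procedure: 50 windows of 121 bins (2000 ms), 30 random neuron
#' subsets, ensemble sizes 40 to 160.
#'
#' @param models List of `fitted_model`s, one per neuron.
#' @param blocks Session design blocks.
#' @param states Aligned [session_states()] table (for true values).
#' @param target Target variable name.
#' @param ensemble_sizes Ensemble sizes to test.
#' @param n_windows Windows per shuffle.
#' @param L Window length in bins.
#' @param n_shuffles Random neuron subsets per ensemble size.
#' @param counts Optional pre-simulated frames x neurons count matrix.
#' @param seed Optional integer seed.
#' @return A `decoding_result`: `errors` (long data frame: ensemble_size,
#'   shuffle, window, error) and `summary` (per-size median/mean/sd).
#' @export
error_curve <- function(models, blocks, states, target,
                        ensemble_sizes = c(40, 80, 120, 160),
                        n_windows = 50, L = 121, n_shuffles = 30,
                        counts = NULL, seed = NULL) {
  stopifnot(max(ensemble_sizes) <= length(models), L >= 1)
  with_seed(seed, function() {
    T_ <- length(blocks[[1]]$index)
    if (is.null(counts)) counts <- simulate_population_spikes(models, blocks)
    ends <- sample(L:T_, n_windows)
    spec <- NULL
    for (m in models) if (target %in% m$variables) { spec <- m$specs[[target]]; break }
    if (is.null(spec)) spec <- blocks[[target]]$spec
    out <- vector("list", length(ensemble_sizes) * n_shuffles)
    k <- 0L
    for (sz in ensemble_sizes) {
      for (sh in seq_len(n_shuffles)) {
        idx <- sample(length(models), sz)
        sub_counts <- counts[, idx, drop = FALSE]
        err <- vapply(seq_len(n_windows), function(w) {
          rows <- (ends[w] - L + 1L):ends[w]
          dec <- decode_window(sub_counts, models[idx], target, blocks, rows,
                               spec = spec)
          decode_error(spec, dec$bin, states, rows, target)
        }, numeric(1))
        k <- k + 1L
        out[[k]] <- data.frame(ensemble_size = sz, shuffle = sh,
                               window = seq_len(n_windows), error = err)
      }
    }
    errors <- do.call(rbind, out)
    agg <- do.call(rbind, lapply(split(errors, errors$ensemble_size),
      function(d) data.frame(ensemble_size = d$ensemble_size[1],
                             median_error = stats::median(d$error),
                             mean_error = mean(d$error),
                             sd_error = stats::sd(d$error))))
    structure(list(errors = errors, summary = agg[order(agg$ensemble_size), ],
                   target = target), class = "decoding_result")
  })
}
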