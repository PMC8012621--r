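# Ground-truth LN neurons and Poisson spike generation.

# Bin coordinates used for the spatial covariance of sampled filters, in bin
# units; circular variables use chord distance on the wrap-around circle so
# the filter is continuous across 360 degrees.
filter_distances <- function(spec) {
  if (spec$kind == "position2d") {
    xy <- cbind(rep(seq_len(spec$n_x), spec$n_y),
                rep(seq_len(spec$n_y), each = spec$n_x))
    as.matrix(stats::dist(xy))
  } else if (spec$kind == "circular") {
    n <- spec$bin_count
    i <- seq_len(n)
    d <- abs(outer(i, i, "-"))
    pmin(d, n - d)
  } else {
    i <- seq_len(spec$bin_count)
    abs(outer(i, i, "-"))
  }
}

#' Sample a ground-truth LN neuron
#'
#' Draws smooth random tuning filters (one weight per bin, in log-rate
#' units) for the requested variables from a Gaussian process with a
#' squared-exponential covariance over bin distance,
#' `corr(d) = exp(-d^2 / (2 * smoothness^2))`; untuned variables get no
#' filter. Filters are mean-centered so the bias alone sets the baseline
#' rate, which is drawn so `exp(bias)/dt` falls inside `baseline_range`.
#'
#' @param specs Named list of [variable_spec()]s.
#' @param tuned Character vector of tuned variable names (subset of
#'   `names(specs)`; empty gives a constant-rate neuron).
#' @param smoothness Correlation length of the filters, in bins; `Inf`
#'   yields a constant (all-zero after centering) filter.
#' @param strength Marginal standard deviation of filter weights (log-rate
#'   units).
#' @param baseline_range Baseline firing-rate range, spikes/s.
#' @param dt Time bin, seconds.
#' @param interaction Optional multiplicative interaction:
#'   `list(variable=, segment_bins=, gain=)` multiplies the rate by `gain`
#'   whenever `variable`'s active bin lies in `segment_bins`.
#' @param reward_gain Optional named numeric: rate multiplier per prey value.
#' @param combination `"multiplicative"` (exponential of the summed filters,
#'   the LN form) or `"additive"` (per-variable rates summed in the rate
#'   domain -- the alternative MF/AF must tell apart).
#' @return A list of class `ground_truth_neuron`.
#' @export
sample_ground_truth <- function(specs, tuned, smoothness = 2, strength = 0.8,
                                baseline_range = c(1, 20), dt = 0.01667,
                                interaction = NULL, reward_gain = NULL,
                                combination = c("multiplicative", "additive")) {
  combination <- match.arg(combination)
  bad <- setdiff(tuned, names(specs))
  if (length(bad) > 0)
    stop(sprintf("unknown variable(s): %s", paste(bad, collapse = ", ")))
  filters <- lapply(tuned, function(v) {
    spec <- specs[[v]]
    n <- spec$bin_count
    if (is.infinite(smoothness)) return(rep(0, n))
    d <- filter_distances(spec)
    K <- exp(-d^2 / (2 * smoothness^2))
    # eigendecomposition with clipped eigenvalues: the squared-exponential
    # kernel is numerically rank-deficient on dense grids
    e <- eigen(K, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    w <- strength * drop(e$vectors %*% (sqrt(lam) * stats::rnorm(n)))
    w - mean(w)
  })
  names(filters) <- tuned
  r0 <- stats::runif(1, baseline_range[1], baseline_range[2])
  if (!is.null(interaction))
    stopifnot(interaction$variable %in% tuned || interaction$variable %in% names(specs),
              interaction$gain > 0)
  neuron <- list(bias = log(r0 * dt), filters = filters,
                 interaction = interaction, reward_gain = reward_gain,
                 combination = combination, dt = dt)
  class(neuron) <- "ground_truth_neuron"
  neuron
}

#' Firing rate of a ground-truth neuron in one binned state
#'
#' For the multiplicative (LN) form the rate is
#' `exp(bias + sum_i w_i[bin_i]) / dt`, then multiplied by the interaction
#' gain and the reward gain when configured. The additive form sums
#' per-variable rates in the rate domain.
#'
#' @param neuron A [sample_ground_truth()] neuron.
#' @param active_bins Named integer vector/list: the active bin of every
#'   tuned variable (and of the interaction variable, if any).
#' @param dt Time bin, seconds (defaults to the neuron's own).
#' @param prey_value Prey value for the reward gain, or `NULL`.
#' @return Rate in spikes/s.
#' @export
rate_from_state <- function(neuron, active_bins, dt = neuron$dt,
                            prey_value = NULL) {
  need <- names(neuron$filters)
  if (!is.null(neuron$interaction))
    need <- union(need, neuron$interaction$variable)
  missing <- setdiff(need, names(active_bins))
  if (length(missing) > 0)
    stop(sprintf("missing state for variable(s): %s",
                 paste(missing, collapse = ", ")))
  vars <- names(neuron$filters)
  if (neuron$combination == "multiplicative" || length(vars) == 0) {
    lp <- neuron$bias +
      sum(vapply(vars, function(v)
        neuron$filters[[v]][active_bins[[v]]], numeric(1)))
    rate <- exp(lp) / dt
  } else {
    rate <- sum(vapply(vars, function(v)
      exp(neuron$bias - log(length(vars)) +
            neuron$filters[[v]][active_bins[[v]]]), numeric(1))) / dt
  }
  if (!is.null(neuron$interaction) &&
      active_bins[[neuron$interaction$variable]] %in%
        neuron$interaction$segment_bins)
    rate <- rate * neuron$interaction$gain
  if (!is.null(neuron$reward_gain) && !is.null(prey_value)) {
    g <- neuron$reward_gain[as.character(prey_value)]
    if (!is.na(g)) rate <- rate * g
  }
  rate
}

#' Per-frame firing rates of a neuron over a session
#'
#' Vectorized form of [rate_from_state()] over the design blocks of a
#' session.
#'
#' @param neuron A ground-truth neuron.
#' @param blocks Named list of `design_block`s ([session_design()]).
#' @param dt Time bin, seconds.
#' @param prey_value Optional per-frame prey value vector (for the reward
#'   gain).
#' @return Numeric vector of rates, spikes/s.
#' @export
neuron_rates <- function(neuron, blocks, dt = neuron$dt, prey_value = NULL) {
  vars <- names(neuron$filters)
  need <- if (!is.null(neuron$interaction))
    union(vars, neuron$interaction$variable) else vars
  missing <- setdiff(need, names(blocks))
  if (length(missing) > 0)
    stop(sprintf("missing design block(s): %s", paste(missing, collapse = ", ")))
  T_ <- if (length(blocks) > 0) length(blocks[[1]]$index) else
    stop("no design blocks supplied")
  if (neuron$combination == "multiplicative" || length(vars) == 0) {
    lp <- rep(neuron$bias, T_)
    for (v in vars) lp <- lp + neuron$filters[[v]][blocks[[v]]$index]
    rate <- exp(lp) / dt
  } else {
    rate <- rep(0, T_)
    for (v in vars)
      rate <- rate + exp(neuron$bias - log(length(vars)) +
                           neuron$filters[[v]][blocks[[v]]$index])
    rate <- rate / dt
  }
  if (!is.null(neuron$interaction)) {
    inb <- blocks[[neuron$interaction$variable]]$index %in%
      neuron$interaction$segment_bins
    rate[inb] <- rate[inb] * neuron$interaction$gain
  }
  if (!is.null(neuron$reward_gain) && !is.null(prey_value)) {
    g <- neuron$reward_gain[as.character(prey_value)]
    g[is.na(g)] <- 1
    rate <- rate * g
  }
  rate
}

#' View a ground-truth neuron as a fitted LN model
#'
#' Wraps a (multiplicative, interaction-free) ground-truth neuron in the
#' `fitted_model` interface, so decoding and response-profile code can run
#' on exact ground truth without a fitting step.
#'
#' @param neuron A [sample_ground_truth()] neuron.
#' @param specs Named list of [variable_spec()]s covering its filters.
#' @return A `fitted_model`.
#' @export
ground_truth_model <- function(neuron, specs) {
  stopifnot(neuron$combination == "multiplicative",
            is.null(neuron$interaction))
  vars <- names(neuron$filters)
  m <- list(variables = vars, bias = neuron$bias, weights = neuron$filters,
            specs = specs[vars], dt = neuron$dt,
            par = c(neuron$bias, unlist(neuron$filters, use.names = FALSE)),
            convergence = 0L, message = "ground truth")
  class(m) <- "fitted_model"
  m
}

#' Draw Poisson spike counts from a rate series
#'
#' Independent Poisson draws with mean `rate * dt` per frame.
#'
#' @param rates Non-negative rates, spikes/s.
#' @param dt Time bin, seconds.
#' @return Integer vector of spike counts.
#' @export
generate_spikes <- function(rates, dt) {
  if (any(rates < 0 | !is.finite(rates)))
    stop("rates must be finite and non-negative")
  stats::rpois(length(rates), rates * dt)
}

#' Simulate a spike table for an ensemble
#'
#' @param neurons List of ground-truth neurons.
#' @param blocks Session design blocks.
#' @param dt Time bin, seconds.
#' @param prey_value Optional per-frame prey value vector.
#' @return Integer matrix, frames x neurons.
#' @export
simulate_ensemble <- function(neurons, blocks, dt, prey_value = NULL) {
  counts <- vapply(neurons, function(nr)
    generate_spikes(neuron_rates(nr, blocks, dt, prey_value), dt),
    integer(length(blocks[[1]]$index)))
  colnames(counts) <- names(neurons)
  counts
}
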