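# Multiplicative vs. additive mixed selectivity: position-rate segments,
# conditional tuning curves, MF/AF, the range-vs-mean confirmation,
# occupancy-matched condition splits, and reward-value regression.

#' Segment position bins by firing rate
#'
#' Sorts the visited position bins by firing rate (ties broken by bin index)
#' and splits them into `n_segments` equal-count segments; remainder bins go
#' to the highest-rate segment. Labels are 1 (lowest rate) to `n_segments`.
#'
#' @param map A position `rate_map` (or numeric rate vector; `NA` =
#'   unvisited).
#' @param n_segments Number of segments (>= 2).
#' @return Integer labels per bin (`NA` for unvisited bins).
#' @export
segment_by_position_rate <- function(map, n_segments = 2) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  rate <- map_values(map)
  visited <- which(is.finite(rate))
  if (length(visited) < n_segments)
    stop("fewer visited bins than segments")
  ord <- visited[order(rate[visited], visited)]
  m <- length(ord)
  base <- m %/% n_segments
  sizes <- rep(base, n_segments)
  sizes[n_segments] <- sizes[n_segments] + m - base * n_segments
  labels <- rep(NA_integer_, length(rate))
  labels[ord] <- rep(seq_len(n_segments), times = sizes)
  labels
}

#' Conditional tuning curves per position segment
#'
#' Occupancy-normalized tuning curves of a second variable (direction or
#' speed), computed separately from the frames spent in each position
#' segment.
#'
#' @param counts Spike counts per frame.
#' @param pos_block Position `design_block`.
#' @param segment_labels Per-bin segment labels from
#'   [segment_by_position_rate()].
#' @param second_block `design_block` of the second variable.
#' @param dt Time bin, seconds.
#' @return A `segmented_tuning`: `curves` (segments x bins, spikes/s, `NA`
#'   where unvisited), `occupancy` (seconds), `segment_mean_rate`, and the
#'   per-frame segment assignment.
#' @export
conditional_tuning <- function(counts, pos_block, segment_labels,
                               second_block, dt) {
  seg_frame <- segment_labels[pos_block$index]
  n_seg <- max(segment_labels, na.rm = TRUE)
  nb <- second_block$spec$bin_count
  curves <- matrix(NA_real_, n_seg, nb)
  occ <- matrix(0, n_seg, nb)
  mean_rate <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    rows <- which(seg_frame == s)
    if (length(rows) == 0) stop(sprintf("segment %d is empty", s))
    o <- tabulate(second_block$index[rows], nb)
    spk <- vapply(seq_len(nb), function(b)
      sum(counts[rows[second_block$index[rows] == b]]), numeric(1))
    curves[s, ] <- ifelse(o > 0, spk / (o * dt), NA_real_)
    occ[s, ] <- o * dt
    mean_rate[s] <- sum(counts[rows]) / (length(rows) * dt)
  }
  structure(list(curves = curves, occupancy = occ,
                 segment_mean_rate = mean_rate,
                 frame_segment = seg_frame,
                 spec = second_block$spec),
            class = "segmented_tuning")
}

#' Multiplicative and additive factors of a tuning-curve pair
#'
#' Ordinary least-squares regression of the high-rate-context curve on the
#' low-rate-context curve: the slope is the multiplicative factor (MF; 1 =
#' no multiplicative interaction) and the intercept divided by the neuron's
#' mean firing rate is the additive factor (AF; 0 = no additive shift).
#' Bins are unweighted; bins missing in either curve are dropped.
#'
#' @param high,low Tuning curves (spikes/s) from the high- and low-rate
#'   position segments.
#' @param mean_rate The neuron's overall mean firing rate, spikes/s.
#' @return `list(mf, af, n_bins)`.
#' @export
mf_af <- function(high, low, mean_rate) {
  ok <- is.finite(high) & is.finite(low)
  if (sum(ok) < 5) stop("need at least 5 shared valid bins")
  if (stats::sd(low[ok]) == 0) stop("degenerate low-curve variance")
  fit <- stats::lm(high[ok] ~ low[ok])
  list(mf = unname(stats::coef(fit)[2]),
       af = unname(stats::coef(fit)[1]) / mean_rate,
       n_bins = sum(ok))
}

#' Range-vs-mean test of multiplicative tuning
#'
#' Under multiplicative mixed selectivity the range (max - min) of a tuning
#' curve grows with the mean firing rate of the position segment it was
#' measured in; under additive shifts the range is constant. Returns the
#' Pearson correlation between per-segment curve range and segment mean
#' rate (3 segments give the sign; cohorts are summarized by
#' [cohort_range_test()]).
#'
#' @param seg A `segmented_tuning` with >= 3 segments.
#' @return `list(r, ranges, means)`.
#' @export
range_vs_mean <- function(seg) {
  n_seg <- nrow(seg$curves)
  if (n_seg < 3) stop("need >= 3 segments")
  ranges <- apply(seg$curves, 1, function(cv) {
    cv <- cv[is.finite(cv)]
    if (length(cv) == 0) return(NA_real_)
    max(cv) - min(cv)
  })
  means <- seg$segment_mean_rate
  ok <- is.finite(ranges)
  r <- if (sum(ok) >= 3 && stats::sd(ranges[ok]) > 0 &&
           stats::sd(means[ok]) > 0)
    stats::cor(ranges[ok], means[ok]) else NA_real_
  list(r = r, ranges = ranges, means = means)
}

#' Cohort summary of range-vs-mean correlations
#'
#' Median per-neuron correlation plus a Wilcoxon signed-rank test against
#' zero.
#'
#' @param r_values Per-neuron correlations from [range_vs_mean()].
#' @return `list(median, p, n)`.
#' @export
cohort_range_test <- function(r_values) {
  r <- r_values[is.finite(r_values)]
  list(median = stats::median(r),
       p = stats::wilcox.test(r)$p.value,
       n = length(r))
}

#' Occupancy-matched split of two conditions
#'
#' Matches the per-bin occupancy of two conditions (e.g. low- vs high-value
#' prey) by randomly removing frames from the richer condition in every bin,
#' then matches the total spike counts by randomly thinning spikes from the
#' spike-richer condition (thinning spikes rather than frames keeps the
#' occupancy match exact). Bins occupied in only one condition are removed
#' from both and reported. The stochastic decimation is repeated `n_reps`
#' times (default 50) so downstream statistics can be averaged.
#'
#' @param index Per-frame bin index of the matched variable (direction, per
#'   the downsampling rule).
#' @param counts Spike counts per frame.
#' @param condition Logical or two-level factor per frame.
#' @param n_reps Number of repetitions.
#' @param seed Optional integer seed.
#' @return `list(reps, dropped_bins)`; each rep holds the kept frame indices
#'   and thinned counts per condition (`frames1`, `counts1`, `frames2`,
#'   `counts2`).
#' @export
occupancy_matched_split <- function(index, counts, condition, n_reps = 50,
                                    seed = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly 2 levels")
  i1 <- which(condition == levels(condition)[1])
  i2 <- which(condition == levels(condition)[2])
  if (length(i1) == 0 || length(i2) == 0) stop("both conditions must be non-empty")
  nb <- max(index)
  occ1 <- tabulate(index[i1], nb)
  occ2 <- tabulate(index[i2], nb)
  dropped <- which(xor(occ1 == 0, occ2 == 0))
  with_seed(seed, function() {
    reps <- lapply(seq_len(n_reps), function(rep) {
      k1 <- integer(0); k2 <- integer(0)
      for (b in seq_len(nb)) {
        f1 <- i1[index[i1] == b]
        f2 <- i2[index[i2] == b]
        n <- min(length(f1), length(f2))
        if (n == 0) next
        if (length(f1) > n) f1 <- sample(f1, n)
        if (length(f2) > n) f2 <- sample(f2, n)
        k1 <- c(k1, f1); k2 <- c(k2, f2)
      }
      c1 <- counts[k1]; c2 <- counts[k2]
      # spike-total matching by random thinning of the richer condition
      d <- sum(c1) - sum(c2)
      thin <- function(cv, nremove) {
        spikes <- rep(seq_along(cv), cv)
        drop <- sample(seq_along(spikes), nremove)
        tabulate(spikes[-drop], length(cv))
      }
      if (d > 0) c1 <- thin(c1, d) else if (d < 0) c2 <- thin(c2, -d)
      list(frames1 = k1, counts1 = c1, frames2 = k2, counts2 = c2)
    })
    list(reps = reps, dropped_bins = dropped)
  })
}

#' Reward-value regression on pre-capture activity
#'
#' Regresses each neuron's mean firing rate over the last second before
#' trial end on the pursued prey's reward value; the slope and its two-sided
#' test quantify reward encoding.
#'
#' @param counts Spike counts per frame (one neuron).
#' @param states A [session_states()] table aligned with `counts` (uses
#'   `trial` and `prey_value`).
#' @param dt Time bin, seconds.
#' @param window_s Pre-end window, seconds (default 1).
#' @return `list(slope, p, n_trials)`.
#' @export
reward_encoding <- function(counts, states, dt, window_s = 1) {
  n_frames <- round(window_s / dt)
  per_trial <- lapply(split(seq_len(nrow(states)), states$trial), function(rows) {
    tail_rows <- rows[max(1, length(rows) - n_frames + 1):length(rows)]
    c(rate = sum(counts[tail_rows]) / (length(tail_rows) * dt),
      value = states$prey_value[rows[1]])
  })
  df <- as.data.frame(do.call(rbind, per_trial))
  if (length(unique(df$value)) < 2)
    stop("need at least 2 reward levels")
  fit <- stats::lm(rate ~ value, data = df)
  sm <- stats::summary.lm(fit)$coefficients
  list(slope = unname(sm["value", "Estimate"]),
       p = unname(sm["value", "Pr(>|t|)"]),
       n_trials = nrow(df))
}

#' Fraction of reward-encoding neurons in a population
#'
#' @param count_matrix Frames x neurons spike counts.
#' @param states Aligned [session_states()] table.
#' @param dt Time bin, seconds.
#' @param alpha Significance level per neuron.
#' @param window_s Pre-end window, seconds.
#' @return `list(fraction, n_significant, n, p_binomial)` where
#'   `p_binomial` tests the significant fraction against `alpha`.
#' @export
reward_encoding_population <- function(count_matrix, states, dt,
                                       alpha = 0.05, window_s = 1) {
  ps <- apply(count_matrix, 2, function(cv)
    reward_encoding(cv, states, dt, window_s)$p)
  nsig <- sum(ps < alpha)
  list(fraction = nsig / length(ps), n_significant = nsig, n = length(ps),
       p_binomial = stats::binom.test(nsig, length(ps), alpha)$p.value)
}
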