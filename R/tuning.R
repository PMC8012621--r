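# Tuning objects and population statistics: response profiles, empirical and
# adaptively smoothed rate maps, SPAEF, effect sizes, LLi correlations, and
# filter clustering.

new_rate_map <- function(spec, rate, occupancy = NULL,
                         provenance = "model-derived") {
  stopifnot(length(rate) == spec$bin_count)
  structure(list(spec = spec, rate = rate, occupancy = occupancy,
                 provenance = provenance), class = "rate_map")
}

#' Response profile of a fitted LN model variable
#'
#' Converts one variable's weights into a tuning curve in spikes/s by
#' marginalizing out the other variables: the profile is
#' `exp(w_j) * alpha / dt` with scaling factor
#' `alpha = exp(bias) * prod_{i != j} mean(exp(w_i))`.
#'
#' @param model A `fitted_model` from [fit_ln()].
#' @param variable Variable whose profile to extract (must be in the model).
#' @return A `rate_map` (provenance `"model-derived"`).
#' @export
response_profile <- function(model, variable) {
  if (!variable %in% model$variables)
    stop(sprintf("variable '%s' is not in the fitted model", variable))
  others <- setdiff(model$variables, variable)
  alpha <- exp(model$bias) *
    prod(vapply(others, function(v) mean(exp(model$weights[[v]])), numeric(1)))
  new_rate_map(model$specs[[variable]],
               exp(model$weights[[variable]]) * alpha / model$dt)
}

#' Raw (occupancy-normalized) rate map
#'
#' Per-bin firing rate: spikes in bin / time in bin. Unvisited bins are
#' `NA`.
#'
#' @param counts Spike counts per frame.
#' @param block `design_block` of the mapped variable.
#' @param dt Time bin, seconds.
#' @return A `rate_map` with per-bin occupancy in seconds (provenance
#'   `"empirical"`).
#' @export
empirical_rate_map <- function(counts, block, dt) {
  nb <- block$spec$bin_count
  occ <- tabulate(block$index, nb)
  spk <- vapply(seq_len(nb), function(b) sum(counts[block$index == b]),
                numeric(1))
  rate <- ifelse(occ > 0, spk / (occ * dt), NA_real_)
  new_rate_map(block$spec, rate, occupancy = occ * dt,
               provenance = "empirical")
}

# Pairwise distances between bins of a spec, in bin units (wrapped for
# circular variables).
map_bin_distances <- function(spec) filter_distances(spec)

#' Adaptive rate-map smoothing
#'
#' For every bin, a circle (in bin units) is expanded around the bin until
#' `N_spikes >= a / (N_occ^2 * r^2)`, where `N_occ` is the number of
#' occupancy samples and `N_spikes` the number of spikes strictly inside the
#' circle and `r` its radius; the bin's rate is then `N_spikes / (N_occ * dt)`.
#' Dense data satisfy the criterion at r = 1 (a circle holding the bin
#' alone), leaving the raw map unchanged; sparse bins borrow from ever
#' larger neighborhoods. Bins that
#' never satisfy the criterion at the maximum radius are flagged missing
#' (`NA`).
#'
#' @param spike_counts Spikes per bin.
#' @param occupancy_samples Occupancy samples (frame counts) per bin.
#' @param spec The map's [variable_spec()].
#' @param a Scale parameter of the criterion (default 10,000).
#' @param dt Seconds per occupancy sample (set to 1 to get rate per sample).
#' @return A `rate_map` (provenance `"smoothed-empirical"`), with the chosen
#'   radius per bin in `$radius`.
#' @export
adaptive_smooth <- function(spike_counts, occupancy_samples, spec, a = 10000,
                            dt = 1) {
  stopifnot(length(spike_counts) == spec$bin_count,
            length(occupancy_samples) == spec$bin_count,
            all(occupancy_samples >= 0))
  if (all(occupancy_samples == 0)) stop("all-zero occupancy")
  D <- map_bin_distances(spec)
  max_r <- ceiling(max(D)) + 1L
  nb <- spec$bin_count
  rate <- rep(NA_real_, nb)
  radius <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    for (r in seq_len(max_r)) {
      # strictly inside: the r = 1 circle holds the bin alone, so dense data
      # reproduce the raw map exactly
      inside <- D[b, ] < r
      nocc <- sum(occupancy_samples[inside])
      nspk <- sum(spike_counts[inside])
      if (nocc > 0 && nspk >= a / (nocc^2 * r^2)) {
        rate[b] <- nspk / (nocc * dt)
        radius[b] <- r
        break
      }
    }
  }
  m <- new_rate_map(spec, rate, occupancy = occupancy_samples * dt,
                    provenance = "smoothed-empirical")
  m$radius <- radius
  m
}

map_values <- function(m) if (inherits(m, "rate_map")) m$rate else as.numeric(m)

#' SPAEF similarity between two maps
#'
#' Spatial efficiency metric
#' `SPAEF = 1 - sqrt((A-1)^2 + (B-1)^2 + (C-1)^2)` with `A` the Pearson
#' correlation between the maps, `B` the ratio of coefficients of variation
#' (map2 CV / map1 CV), and `C` the histogram intersection of the two
#' z-scored maps over shared bins (Freedman-Diaconis width on the pooled
#' values, with breaks symmetric about zero so mirror-image maps intersect
#' fully). Identical maps score exactly 1; 0 indicates orthogonal and
#' negative values anticorrelated maps.
#'
#' @param map1,map2 `rate_map`s or numeric vectors of equal length. Bins
#'   missing in either map are dropped from both.
#' @return SPAEF value in (-Inf, 1].
#' @export
spaef <- function(map1, map2) {
  x <- map_values(map1); y <- map_values(map2)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 shared bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("SPAEF undefined for a constant map")
  A <- stats::cor(x, y)
  B <- (stats::sd(y) / mean(y)) / (stats::sd(x) / mean(x))
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  pooled <- c(zx, zy)
  h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)  # Freedman-Diaconis
  half <- max(abs(pooled)) + 1e-12
  nb <- max(1L, ceiling(half / max(h, 1e-12)))
  breaks <- seq(-nb, nb) * (half / nb)
  hx <- graphics::hist(zx, breaks = breaks, plot = FALSE)$counts
  hy <- graphics::hist(zy, breaks = breaks, plot = FALSE)$counts
  C <- sum(pmin(hx, hy)) / length(zx)
  1 - sqrt((A - 1)^2 + (B - 1)^2 + (C - 1)^2)
}

#' Peak-to-trough effect size of a map
#'
#' Maximum minus minimum firing rate over visited bins, in spikes/s.
#'
#' @param map A `rate_map` or numeric vector.
#' @return Scalar effect size.
#' @export
effect_size <- function(map) {
  v <- map_values(map)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no visited bins")
  max(v) - min(v)
}

#' Cohort median effect size with bootstrap CI
#'
#' @param effects Per-neuron effect sizes (or any scalar statistic).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level of the percentile interval.
#' @return `list(median, ci, n)`.
#' @export
cohort_effect <- function(effects, n_boot = 1000, conf = 0.95) {
  stopifnot(length(effects) >= 1)
  med <- stats::median(effects)
  if (length(effects) == 1)
    return(list(median = med, ci = c(med, med), n = 1L))
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(effects, replace = TRUE)), numeric(1))
  alpha <- (1 - conf) / 2
  list(median = med,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n = length(effects))
}

#' Correlation of per-neuron log-likelihood increases
#'
#' Pearson correlation between two variables' per-neuron LLi values; a
#' positive correlation indicates that tuning for the two variables lives in
#' overlapping neurons rather than distinct subpopulations.
#'
#' @param x,y Per-neuron LLi vectors (paired; pairs with missing values are
#'   dropped).
#' @return `list(r, p, n)`.
#' @export
lli_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 neurons with both LLi defined")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate LLi variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cluster tuning profiles in PC space
#'
#' Centers the profiles, projects them onto the top two principal
#' components, and partitions the projection by k-means (seedable, 50
#' restarts). Reports the variance explained by the two components.
#'
#' @param profiles Matrix, one profile per row.
#' @param k Number of clusters (default 4, the elbow found on the original
#'   data).
#' @param n_restarts k-means restarts.
#' @param seed Optional integer seed.
#' @return `list(labels, projection, variance_explained, centers)`.
#' @export
cluster_profiles <- function(profiles, k = 4, n_restarts = 50, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k)
    stop("fewer profiles than clusters")
  pca <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  ncomp <- min(2L, ncol(pca$x))
  proj <- pca$x[, seq_len(ncomp), drop = FALSE]
  ve <- sum(pca$sdev[seq_len(ncomp)]^2) / sum(pca$sdev^2)
  km <- with_seed(seed, function()
    stats::kmeans(proj, centers = k, nstart = n_restarts))
  list(labels = km$cluster, projection = proj, variance_explained = ve,
       centers = km$centers)
}

#' Per-neuron tuning summary of a population
#'
#' Collects forward-selection outcomes into one row per neuron: tuned flags
#' and single-variable median LLi per candidate (columns `tuned_<v>` and
#' `lli_<v>`).
#'
#' @param selections List of `selection_result`s.
#' @param variables Candidate variable names.
#' @return A data frame, one row per neuron.
#' @export
population_tuning <- function(selections, variables) {
  rows <- lapply(seq_along(selections), function(i) {
    s <- selections[[i]]
    row <- data.frame(neuron = i)
    for (v in variables) {
      row[[paste0("tuned_", v)]] <- v %in% s$selected
      row[[paste0("lli_", v)]] <- if (!is.null(s$single_lli[[v]]))
        stats::median(s$single_lli[[v]]) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
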