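cfg <- world_config()
dt <- cfg$frame_dt

test_that("response profiles follow the marginalized exponential-link form", {
  spec <- variable_spec("v", "circular", n_bins = 6)
  other <- variable_spec("u", "linear", edges = 0:4)
  w_v <- c(0.2, -0.1, 0.5, 0, -0.4, 0.3)
  w_u <- c(0.1, -0.3, 0.2, 0)
  m <- structure(list(variables = c("v", "u"), bias = log(0.1),
                      weights = list(v = w_v, u = w_u),
                      specs = list(v = spec, u = other), dt = dt),
                 class = "fitted_model")
  prof <- response_profile(m, "v")
  alpha <- exp(log(0.1)) * mean(exp(w_u))
  expect_equal(prof$rate, exp(w_v) * alpha / dt, tolerance = 1e-12)

  # single-variable model: empty product, profile = exp(w) exp(bias) / dt
  m1 <- structure(list(variables = "v", bias = log(0.1),
                       weights = list(v = w_v), specs = list(v = spec),
                       dt = dt), class = "fitted_model")
  expect_equal(response_profile(m1, "v")$rate,
               exp(w_v) * exp(log(0.1)) / dt, tolerance = 1e-12)

  # adding c to w_j scales the profile by e^c
  m2 <- m1; m2$weights$v <- w_v + 0.9
  expect_equal(response_profile(m2, "v")$rate,
               response_profile(m1, "v")$rate * exp(0.9), tolerance = 1e-12)

  expect_error(response_profile(m1, "u"), "not in the fitted model")
})

test_that("a fitted profile tracks the empirical tuning curve on well-visited bins", {
  sess <- test_session()
  set.seed(9)
  nr <- sample_ground_truth(sess$specs, "self_dir", strength = 1.0,
                            baseline_range = c(8, 15))
  counts <- generate_spikes(neuron_rates(nr, sess$blocks), dt)
  m <- fit_ln(sess$blocks, counts, dt, "self_dir")
  prof <- response_profile(m, "self_dir")
  emp <- empirical_rate_map(counts, sess$blocks$self_dir, dt)
  well <- emp$occupancy > 30  # seconds
  expect_gt(sum(well), 4)
  expect_lt(max(abs(prof$rate[well] - emp$rate[well]) / emp$rate[well]), 0.10)
})

test_that("adaptive smoothing equals a naive incremental-radius oracle", {
  set.seed(10)
  spec <- variable_spec("ang", "circular", n_bins = 100)
  occ <- rpois(100, 30); occ[5:10] <- 0
  spk <- rpois(100, occ * 0.2)
  sm <- adaptive_smooth(spk, occ, spec, a = 10000)

  # independent oracle: literal expanding-circle scan on the wrapped line
  circ_d <- function(i, j) { d <- abs(i - j); pmin(d, 100 - d) }
  for (b in seq(1, 100, by = 7)) {
    found <- FALSE
    for (r in 1:51) {
      inside <- circ_d(b, 1:100) < r
      if (sum(occ[inside]) > 0 &&
          sum(spk[inside]) >= 10000 / (sum(occ[inside])^2 * r^2)) {
        expect_equal(sm$rate[b], sum(spk[inside]) / sum(occ[inside]))
        expect_equal(sm$radius[b], r)
        found <- TRUE
        break
      }
    }
    if (!found) expect_true(is.na(sm$rate[b]))
  }
})

test_that("adaptive smoothing reduces to the raw map for dense data", {
  spec <- variable_spec("ang", "circular", n_bins = 20)
  occ <- rep(500, 20)
  spk <- rpois(20, 100) + 50L
  sm <- adaptive_smooth(spk, occ, spec, a = 10000)
  # criterion holds at r = 1 everywhere; that circle holds the bin alone, so
  # the smoothed map equals the raw spikes/occupancy map
  expect_true(all(sm$radius == 1))
  expect_equal(sm$rate, spk / occ, tolerance = 1e-12)
  expect_error(adaptive_smooth(spk, rep(0, 20), spec), "occupancy")
})

test_that("the selected smoothing radius grows with the scale parameter", {
  set.seed(11)
  spec <- variable_spec("ang", "circular", n_bins = 50)
  occ <- rpois(50, 8)
  spk <- rpois(50, occ * 0.1)
  radii <- sapply(c(1e3, 1e4, 1e5), function(a)
    adaptive_smooth(spk, occ, spec, a = a)$radius)
  for (b in 1:50) {
    rr <- radii[b, ]
    rr <- rr[!is.na(rr)]
    if (length(rr) > 1) expect_true(all(diff(rr) >= 0))
  }
})

test_that("SPAEF identities: self-similarity, reflection, component oracle", {
  set.seed(12)
  m1 <- matrix(runif(225, 1, 10), 15)
  expect_equal(spaef(as.numeric(m1), as.numeric(m1)), 1, tolerance = 1e-12)

  # reflection about the mean of a histogram-symmetric map: A=-1, B=1, C=1
  sym <- c(1:9)  # symmetric values around 5
  refl <- 2 * mean(sym) - sym
  expect_equal(spaef(sym, refl), -1, tolerance = 1e-6)

  # component oracle on random 3x3 maps
  for (i in 1:20) {
    a <- runif(9, 1, 5); b <- runif(9, 1, 5)
    A <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    B <- (sd(b) / mean(b)) / (sd(a) / mean(a))
    za <- (a - mean(a)) / sd(a); zb <- (b - mean(b)) / sd(b)
    pooled <- c(za, zb)
    h <- 2 * IQR(pooled) / length(pooled)^(1 / 3)
    half <- max(abs(pooled)) + 1e-12
    nb <- max(1L, ceiling(half / h))
    breaks <- seq(-nb, nb) * (half / nb)
    ha <- hist(za, breaks = breaks, plot = FALSE)$counts
    hb <- hist(zb, breaks = breaks, plot = FALSE)$counts
    C <- sum(pmin(ha, hb)) / 9
    expect_equal(spaef(a, b), 1 - sqrt((A - 1)^2 + (B - 1)^2 + (C - 1)^2),
                 tolerance = 1e-12)
  }

  expect_error(spaef(rep(1, 9), runif(9)), "constant map")
})

test_that("SPAEF is asymmetric only through the CV ratio", {
  set.seed(13)
  a <- runif(25, 1, 3)
  b <- a * 2 + rnorm(25, 0, 0.4)  # different CV
  expect_false(isTRUE(all.equal(spaef(a, b), spaef(b, a))))
  expect_equal(spaef(a, a), 1, tolerance = 1e-12)
  expect_equal(spaef(b, b), 1, tolerance = 1e-12)
})

test_that("effect sizes and cohort medians match direct computation", {
  expect_equal(effect_size(rep(4.2, 10)), 0)
  one <- cohort_effect(7.7)
  expect_equal(one$median, 7.7)
  expect_equal(one$ci, c(7.7, 7.7))

  set.seed(14)
  for (i in 1:10) {
    x <- runif(sample(3:30, 1), 0, 20)
    s <- sort(x); n <- length(s)
    sort_median <- if (n %% 2 == 1) s[(n + 1) / 2] else
      (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(cohort_effect(x, n_boot = 10)$median, sort_median)
  }
  # bootstrap CI brackets the median
  set.seed(15)
  ce <- cohort_effect(runif(40, 5, 15), n_boot = 500)
  expect_true(ce$ci[1] <= ce$median && ce$median <= ce$ci[2])
})

test_that("LLi correlations reproduce the textbook formula", {
  expect_equal(lli_correlation(1:5, 1:5)$r, 1, tolerance = 1e-12)
  expect_equal(lli_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1,
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:100) {
    x <- rnorm(10); y <- rnorm(10)
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(lli_correlation(x, y)$r, manual, tolerance = 1e-12)
  }
  expect_error(lli_correlation(c(1, 2), c(2, 1)), "at least 3")
  expect_error(lli_correlation(rep(1, 5), 1:5), "degenerate")
})

test_that("profile clustering separates planted families and preserves rank-2 geometry", {
  set.seed(16)
  up <- t(replicate(15, seq(0, 5, length.out = 12) + rnorm(12, 0, 0.2)))
  ditonic <- t(replicate(15, 5 * sin(seq(0, pi, length.out = 12)) +
                           rnorm(12, 0, 0.2)))
  cl <- cluster_profiles(rbind(up, ditonic), k = 2, seed = 1)
  lab <- cl$labels
  expect_true(all(lab[1:15] == lab[1]) && all(lab[16:30] == lab[16]) &&
                lab[1] != lab[16])

  cl1 <- cluster_profiles(up, k = 1, seed = 1)
  expect_true(all(cl1$labels == 1))
  expect_error(cluster_profiles(up[1:3, ], k = 4), "fewer profiles")

  # rank-2 data: the 2-PC projection preserves pairwise distances exactly
  u <- rnorm(12); v <- rnorm(12)
  coef <- matrix(rnorm(20), 10)
  prof2 <- coef %*% rbind(u, v)
  cl2 <- cluster_profiles(prof2, k = 2, seed = 2)
  expect_equal(as.matrix(dist(cl2$projection)), as.matrix(dist(prof2)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cl2$variance_explained, 1, tolerance = 1e-12)
})

test_that("population tuning tables are consistent with their selection results", {
  sel1 <- structure(list(selected = "self_pos",
                         single_lli = list(self_pos = rep(0.2, 10),
                                           self_dir = rep(-0.01, 10))),
                    class = "selection_result")
  sel2 <- structure(list(selected = character(0),
                         single_lli = list(self_pos = rep(0, 10),
                                           self_dir = rep(0.001, 10))),
                    class = "selection_result")
  pop <- population_tuning(list(sel1, sel2), c("self_pos", "self_dir"))
  expect_equal(pop$tuned_self_pos, c(TRUE, FALSE))
  expect_equal(pop$lli_self_pos, c(0.2, 0))
})
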