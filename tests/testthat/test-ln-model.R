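cfg <- world_config()
dt <- cfg$frame_dt

test_that("binning produces exact one-hot design blocks", {
  pos_spec <- variable_spec("pos", "position2d", x_range = c(0, 1920),
                            y_range = c(0, 1080))
  b <- bin_state(cbind(c(0, 1919.9, 960), c(0, 1079.9, 540)), pos_spec)
  expect_equal(b$index[1], 1L)          # corner (0, 0): row 0, column 0
  expect_equal(b$index[2], 225L)        # opposite corner
  m <- as_design_matrix(b)
  expect_true(all(rowSums(m) == 1))

  dir_spec <- variable_spec("dir", "circular", n_bins = 12)
  expect_equal(bin_state(359.9, dir_spec)$index, 12L)  # wrap boundary
  expect_equal(bin_state(0, dir_spec)$index, 1L)
  expect_equal(bin_state(360, dir_spec)$index, 1L)     # float-epsilon wrap
  expect_error(bin_state(361, dir_spec), "\\[0, 360\\)")

  lin_spec <- variable_spec("sp", "linear", edges = seq(0, 10, length.out = 6))
  expect_equal(bin_state(10, lin_spec)$index, 5L)  # top edge -> last bin
  expect_error(bin_state(10.5, lin_spec), "outside bin edges")

  # column sums equal an independent histogram of the same values
  set.seed(1)
  v <- runif(500, 0, 10)
  b2 <- bin_state(v, lin_spec)
  hist_counts <- as.vector(table(cut(v, seq(0, 10, length.out = 6),
                                     include.lowest = TRUE, right = FALSE)))
  expect_equal(colSums(as_design_matrix(b2)), hist_counts)
})

test_that("penalized likelihood matches finite differences and closed forms", {
  set.seed(2)
  spec <- variable_spec("v", "circular", n_bins = 5)
  vals <- runif(10, 0, 360)
  blocks <- list(v = bin_state(vals, spec))
  counts <- rpois(10, 1)
  bias <- log(mean(counts) + 0.1)
  w <- list(v = rnorm(5, 0, 0.3))

  r <- penalized_nll(bias, w, blocks, counts, beta = 3, lambda = 1)
  # central finite differences on the 10-frame toy
  p0 <- c(bias, w$v)
  f <- function(p) penalized_nll(p[1], list(v = p[-1]), blocks, counts,
                                 beta = 3, lambda = 1)$value
  h <- 1e-6
  for (j in seq_along(p0)) {
    e <- rep(0, length(p0)); e[j] <- h
    num <- (f(p0 + e) - f(p0 - e)) / (2 * h)
    expect_lt(abs(num - r$gradient[j]) / max(abs(num), 1e-8), 1e-5)
  }

  # null-model identity: bias-only objective equals the closed-form Poisson NLL
  r0 <- penalized_nll(log(mean(counts)), list(), blocks, counts)
  mu <- mean(counts)
  expect_equal(r0$value, sum(mu - counts * log(mu)), tolerance = 1e-12)

  # doubling beta doubles the smoothness component exactly
  pen1 <- penalized_nll(bias, w, blocks, counts, beta = 3)$penalty
  pen2 <- penalized_nll(bias, w, blocks, counts, beta = 6)$penalty
  expect_equal(pen2, 2 * pen1, tolerance = 1e-12)
})

test_that("lasso penalty applies to discrete variables with a consistent gradient", {
  spec <- variable_spec("g", "discrete", levels = c("a", "b", "c"))
  blocks <- list(g = bin_state(rep(c("a", "b", "c"), 4), spec))
  counts <- rep(1L, 12)
  w <- list(g = c(0.4, -0.2, 0.1))
  r <- penalized_nll(0, w, blocks, counts, beta = 20, lambda = 2)
  expect_equal(r$penalty, 2 * sum(sqrt(w$g^2 + 1e-8)), tolerance = 1e-10)
  f <- function(p) penalized_nll(p[1], list(g = p[-1]), blocks, counts,
                                 beta = 20, lambda = 2)$value
  p0 <- c(0, w$g); h <- 1e-6
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    num <- (f(p0 + e) - f(p0 - e)) / (2 * h)
    expect_lt(abs(num - r$gradient[j]) / max(abs(num), 1e-8), 1e-5)
  }
})

test_that("fitting recovers the mean rate and is start-point invariant", {
  set.seed(3)
  spec <- variable_spec("v", "circular", n_bins = 12)
  vals <- runif(3000, 0, 360)
  blocks <- list(v = bin_state(vals, spec))

  # constant-rate neuron, bias-only model
  counts <- rpois(3000, 5 * dt)
  m0 <- fit_ln(blocks, counts, dt, character(0))
  expect_equal(exp(m0$bias) / dt, mean(counts) / dt, tolerance = 1e-6)

  # convex objective: two starting points agree to 1e-6
  w_true <- sin(2 * pi * (1:12) / 12)
  counts2 <- rpois(3000, exp(log(8 * dt) + w_true[blocks$v$index]))
  mA <- fit_ln(blocks, counts2, dt, "v", beta = 5)
  mB <- fit_ln(blocks, counts2, dt, "v", beta = 5,
               init = c(0.5, rnorm(12, 0, 0.5)))
  expect_lt(abs(mA$value - mB$value), 1e-6)
  expect_equal(mA$convergence, 0L)
})

test_that("cross-validation folds are a reproducible round-robin partition", {
  f1 <- make_folds(1000)
  f2 <- make_folds(1000)
  expect_identical(f1, f2)
  expect_equal(sort(unlist(f1)), 1:1000)
  expect_equal(lengths(f1), rep(100L, 10))
  # each fold is 5 chunks of 20 contiguous frames
  expect_equal(f1[[1]][1:20], 1:20)
  expect_equal(f1[[2]][1:20], 21:40)
})

test_that("the null model cross-validates to exactly zero LLi", {
  sess <- test_session()
  set.seed(4)
  counts <- rpois(nrow(sess$states), 5 * dt)
  cv <- cross_validate(sess$blocks, counts, dt, character(0))
  expect_identical(cv$lli, rep(0, 10))
})

test_that("cross-validation refuses sessions with spikeless folds", {
  spec <- variable_spec("v", "circular", n_bins = 4)
  blocks <- list(v = bin_state(runif(200, 0, 360), spec))
  counts <- integer(200); counts[1:3] <- 1L  # all spikes in one chunk
  expect_error(cross_validate(blocks, counts, dt, "v"), "no spikes")
})

test_that("training likelihood is monotone in model size but held-out LLi is not", {
  sess <- test_session()
  set.seed(6)
  counts <- generate_spikes(rep(6, nrow(sess$states)), dt)  # untuned neuron
  null <- fit_ln(sess$blocks, counts, dt, character(0))
  m <- fit_ln(sess$blocks, counts, dt, "self_pos")
  ll_null <- pursuitglm:::model_loglik(null, sess$blocks, counts)
  ll_m <- pursuitglm:::model_loglik(m, sess$blocks, counts)
  expect_gte(ll_m, ll_null)  # superset never loses on training data
  cv <- cross_validate(sess$blocks, counts, dt, "self_pos")
  # ... but overfits held-out data: spurious variable gains nothing
  expect_lt(median(cv$lli), ll_m - ll_null)
  p <- wilcox.test(cv$lli, alternative = "greater")$p.value
  expect_gt(p, 0.05)
})

test_that("forward selection recovers planted tuning and rejects noise", {
  sess <- test_session()
  cands <- c("self_pos", "self_dir", "self_speed")
  set.seed(7)
  nr <- sample_ground_truth(sess$specs, c("self_pos", "self_dir"),
                            strength = 1.0, baseline_range = c(4, 8))
  counts <- generate_spikes(neuron_rates(nr, sess$blocks), dt)
  sel <- forward_select(sess$blocks, counts, dt, candidates = cands)
  expect_setequal(sel$selected, c("self_pos", "self_dir"))
  expect_true(all(sel$steps$p < 0.05))
  expect_true(all(diff(c(0, sel$steps$median_lli)) > 0))
  expect_length(sel$single_lli, 3)

  # a homogeneous Poisson neuron is mostly declared untuned
  set.seed(8)
  empty <- vapply(1:10, function(i) {
    counts0 <- generate_spikes(rep(5, nrow(sess$states)), dt)
    length(forward_select(sess$blocks, counts0, dt,
                          candidates = cands)$selected) == 0
  }, logical(1))
  expect_gte(sum(empty), 8)
})
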