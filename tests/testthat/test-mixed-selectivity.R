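cfg <- world_config()
dt <- cfg$frame_dt

test_that("position-rate segmentation is rank-based with index tie-breaks", {
  expect_error(segment_by_position_rate(runif(20), 1), ">= 2")

  # constant map: equal halves split purely by bin index
  lab <- segment_by_position_rate(rep(3, 10), 2)
  expect_equal(lab, rep(c(1L, 2L), each = 5))

  set.seed(20)
  rate <- runif(225); rate[sample(225, 40)] <- NA  # unvisited bins
  lab1 <- segment_by_position_rate(rate, 3)
  lab2 <- segment_by_position_rate(exp(3 * rate), 3)  # monotone transform
  expect_identical(lab1, lab2)
  expect_true(all(is.na(lab1[is.na(rate)])))

  # segment mean rates non-decreasing in the label
  means <- tapply(rate[!is.na(rate)], lab1[!is.na(rate)], mean)
  expect_true(all(diff(means) >= 0))

  # remainder bins go to the highest segment
  lab3 <- segment_by_position_rate(runif(11), 3)
  expect_equal(as.vector(table(lab3)), c(3L, 3L, 5L))
})

test_that("conditional tuning curves match a direct histogram oracle", {
  sess <- test_session()
  set.seed(21)
  nr <- sample_ground_truth(sess$specs, "self_dir", strength = 0.8,
                            baseline_range = c(6, 10))
  counts <- generate_spikes(neuron_rates(nr, sess$blocks), dt)
  pos_map <- empirical_rate_map(counts, sess$blocks$self_pos, dt)
  lab <- segment_by_position_rate(pos_map, 2)
  seg <- conditional_tuning(counts, sess$blocks$self_pos, lab,
                            sess$blocks$self_dir, dt)
  # oracle: literal per-segment histogram
  seg_frame <- lab[sess$blocks$self_pos$index]
  for (s in 1:2) for (b in 1:12) {
    rows <- which(seg_frame == s & sess$blocks$self_dir$index == b)
    if (length(rows) == 0) {
      expect_true(is.na(seg$curves[s, b]))
    } else {
      expect_equal(seg$curves[s, b], sum(counts[rows]) / (length(rows) * dt),
                   tolerance = 1e-12)
    }
  }
  # a segment with no frames is an error
  toy_pos <- bin_state(cbind(rep(10, 50), rep(10, 50)), sess$specs$self_pos)
  toy_dir <- bin_state(runif(50, 0, 360), sess$specs$self_dir)
  toy_lab <- rep(NA_integer_, 225)
  toy_lab[toy_pos$index[1]] <- 1L
  toy_lab[toy_pos$index[1] + 1L] <- 2L  # never visited
  expect_error(conditional_tuning(rep(1L, 50), toy_pos, toy_lab, toy_dir, dt),
               "empty")
})

test_that("a position-blind neuron yields matching segment curves; a planted gain a constant ratio", {
  sess <- test_session()
  set.seed(22)
  # position-blind: curves agree within sampling error on well-visited bins
  nr <- sample_ground_truth(sess$specs, "self_dir", strength = 0.8,
                            baseline_range = c(10, 15))
  counts <- generate_spikes(neuron_rates(nr, sess$blocks), dt)
  occ <- tabulate(sess$blocks$self_pos$index, 225)
  lab <- rep(NA_integer_, 225)
  vis <- which(occ > 0)
  lab[vis] <- rep(1:2, length.out = length(vis))  # arbitrary split
  seg <- conditional_tuning(counts, sess$blocks$self_pos, lab,
                            sess$blocks$self_dir, dt)
  well <- colSums(seg$occupancy) > 30 & apply(is.finite(seg$curves), 2, all)
  expect_gt(sum(well), 3)
  expect_lt(max(abs(seg$curves[2, well] / seg$curves[1, well] - 1)), 0.15)

  # planted multiplicative gain: bin-wise high/low ratio constant within 10%
  seg_bins <- which(bin_centers(sess$specs$self_pos)[, 1] <
                      cfg$field_width / 2)
  nr2 <- sample_ground_truth(sess$specs, "self_dir", strength = 0.8,
                             baseline_range = c(10, 15),
                             interaction = list(variable = "self_pos",
                                                segment_bins = seg_bins,
                                                gain = 1.6))
  counts2 <- generate_spikes(neuron_rates(nr2, sess$blocks), dt)
  lab2 <- rep(NA_integer_, 225)
  lab2[vis] <- ifelse(vis %in% seg_bins, 2L, 1L)
  seg2 <- conditional_tuning(counts2, sess$blocks$self_pos, lab2,
                             sess$blocks$self_dir, dt)
  well2 <- colSums(seg2$occupancy) > 40 & apply(is.finite(seg2$curves), 2, all)
  ratio <- seg2$curves[2, well2] / seg2$curves[1, well2]
  expect_lt(max(abs(ratio / 1.6 - 1)), 0.10)
})

test_that("MF/AF identities hold exactly on noiseless curves", {
  low <- c(2, 4, 6, 8, 10, 12)
  r <- mf_af(low, low, mean_rate = 10)
  expect_equal(r$mf, 1, tolerance = 1e-12)
  expect_equal(r$af, 0, tolerance = 1e-12)

  r2 <- mf_af(1.6 * low, low, mean_rate = 10)
  expect_equal(r2$mf, 1.6, tolerance = 1e-12)
  expect_equal(r2$af, 0, tolerance = 1e-12)

  r3 <- mf_af(low + 3, low, mean_rate = 10)
  expect_equal(r3$mf, 1, tolerance = 1e-12)
  expect_equal(r3$af, 0.3, tolerance = 1e-12)

  expect_error(mf_af(c(1, 2, 3, 4), c(1, 2, 3, 4), 10), "5 shared")
  expect_error(mf_af(low, rep(2, 6), 10), "degenerate")
})

test_that("range-vs-mean separates multiplicative from additive interactions", {
  # multiplicative: curve ranges scale with segment gain -> r = +1 noiseless
  base <- 5 + 4 * sin(2 * pi * (1:12) / 12)
  gains <- c(1, 1.3, 1.6)
  segm <- structure(list(curves = t(sapply(gains, function(g) g * base)),
                         occupancy = matrix(1, 3, 12),
                         segment_mean_rate = gains * mean(base)),
                    class = "segmented_tuning")
  rvm <- range_vs_mean(segm)
  expect_equal(rvm$r, 1, tolerance = 1e-9)
  expect_equal(rvm$ranges, gains * (max(base) - min(base)), tolerance = 1e-9)

  # additive: constant range, correlation undefined -> NA
  sega <- structure(list(curves = t(sapply(c(0, 2, 4), function(a) base + a)),
                         occupancy = matrix(1, 3, 12),
                         segment_mean_rate = mean(base) + c(0, 2, 4)),
                    class = "segmented_tuning")
  expect_true(is.na(range_vs_mean(sega)$r))

  # noisy cohorts: multiplicative positive in >= 90%, additive centered on 0
  set.seed(23)
  rs_mult <- replicate(40, {
    curves <- t(sapply(gains, function(g) g * base + rnorm(12, 0, 0.3)))
    range_vs_mean(structure(list(curves = curves,
                                 occupancy = matrix(1, 3, 12),
                                 segment_mean_rate = gains * mean(base)),
                            class = "segmented_tuning"))$r
  })
  expect_gte(mean(rs_mult > 0), 0.9)
  rs_add <- replicate(40, {
    curves <- t(sapply(c(0, 2, 4), function(a) base + a + rnorm(12, 0, 0.3)))
    range_vs_mean(structure(list(curves = curves,
                                 occupancy = matrix(1, 3, 12),
                                 segment_mean_rate = mean(base) + c(0, 2, 4)),
                            class = "segmented_tuning"))$r
  })
  expect_lt(abs(median(rs_add)), 0.8)
  ct <- cohort_range_test(rs_mult)
  expect_lt(ct$p, 0.01)
  expect_gt(ct$median, 0)
})

test_that("occupancy-matched splits balance occupancy exactly and spikes to zero", {
  sess <- test_session()
  set.seed(24)
  n <- nrow(sess$states)
  counts <- generate_spikes(rep(8, n), dt)
  cond <- sess$states$prey_value > 0.45

  # identical conditions: nothing removed
  idx <- sess$blocks$self_dir$index
  half <- rep(c(TRUE, FALSE), length.out = n)
  idx_dup <- c(idx, idx); counts_dup <- c(counts, counts)
  cond_dup <- rep(c(TRUE, FALSE), each = n)
  sp0 <- occupancy_matched_split(idx_dup, counts_dup, cond_dup, n_reps = 1,
                                 seed = 1)
  expect_length(sp0$reps[[1]]$frames1, n)
  expect_length(sp0$reps[[1]]$frames2, n)

  sp <- occupancy_matched_split(idx, counts, cond, n_reps = 50, seed = 2)
  expect_length(sp$reps, 50)
  occ_all_1 <- tabulate(idx[cond], 12)
  occ_all_2 <- tabulate(idx[!cond], 12)
  for (rep in sp$reps) {
    o1 <- tabulate(idx[rep$frames1], 12)
    o2 <- tabulate(idx[rep$frames2], 12)
    expect_identical(o1, o2)                      # occupancy matched per bin
    expect_lte(abs(sum(rep$counts1) - sum(rep$counts2)), 1)  # spikes matched
    # removal-only: never exceeds either condition's original occupancy
    expect_true(all(o1 <= pmin(occ_all_1, occ_all_2)))
    expect_true(all(rep$counts1 <= counts[rep$frames1]))
  }
})

test_that("reward regression detects planted value gain and stays calibrated", {
  sess <- test_session()
  set.seed(25)
  # constant spikes: slope exactly 0
  r0 <- suppressWarnings(
    reward_encoding(rep(2L, nrow(sess$states)), sess$states, dt))
  expect_equal(r0$slope, 0, tolerance = 1e-9)

  one_level <- sess$states[sess$states$prey_value ==
                             sess$states$prey_value[1], ]
  expect_error(reward_encoding(rpois(nrow(one_level), 1), one_level, dt),
               "2 reward levels")

  # planted multiplicative reward gain on high value
  vals <- sort(unique(sess$states$prey_value))
  gain <- stats::setNames(1.5^(seq_along(vals) - 1), vals)
  hits <- vapply(1:10, function(i) {
    nr <- sample_ground_truth(sess$specs, "self_dir", strength = 0.3,
                              baseline_range = c(8, 12), reward_gain = gain)
    counts <- generate_spikes(
      neuron_rates(nr, sess$blocks, prey_value = sess$states$prey_value), dt)
    reward_encoding(counts, sess$states, dt)$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)

  # value-blind neurons: significant fraction near alpha
  counts_mat <- vapply(1:40, function(i) generate_spikes(rep(6, nrow(sess$states)), dt),
                       integer(nrow(sess$states)))
  pop <- reward_encoding_population(counts_mat, sess$states, dt)
  expect_lte(pop$fraction, 0.15)
  expect_equal(pop$n, 40L)
})
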