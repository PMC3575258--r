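test_that("reference selection follows the median +/- IQR rule", {
  g <- electrode_grid(2, 2)
  # identical features: IQR = 0 degrades to equality -> all channels kept
  ft <- feature_table(g, p_lt = 0.01, p_linet = 0.05, rms = 1)
  ref <- select_reference(ft)
  expect_equal(ref$members, 1:4)

  # a single line-contaminated channel among ~uniform ones is excluded
  g2 <- electrode_grid(10, 10)
  set.seed(5)
  p_line <- matrix(rnorm(100, 0.02, 0.002), 10)
  p_line[4, 7] <- 0.9
  ft2 <- feature_table(g2, p_lt = matrix(rnorm(100, 0.01, 0.001), 10),
                       p_linet = p_line, rms = 1)
  ref2 <- select_reference(ft2)
  expect_false(grid_channel_index(g2, 4, 7) %in% ref2$members)

  # tight unimodal features: at least 90% of channels retained
  set.seed(6)
  ft3 <- feature_table(g2, p_lt = matrix(rnorm(100, 0.01, 0.001), 10),
                       p_linet = matrix(rnorm(100, 0.02, 0.002), 10), rms = 1)
  expect_gte(length(select_reference(ft3)$members), 90)
})

test_that("global thresholds match the constant-times-median parse and the cap", {
  g <- electrode_grid(2, 2)
  # reference p_linet all 0.4, k_line 2.5 -> raw 1.0 capped at 0.85
  ft <- feature_table(g, p_lt = 0.01, p_linet = 0.4, rms = 1)
  th <- compute_global_thresholds(select_reference(ft), detector_config())
  expect_equal(th$thresh_linet, 0.85)
  # reference p_lt all 0.01, k1 11.2, IQR 0 -> 0.112
  expect_equal(th$thresh_lt, 11.2 * 0.01)

  # random reference features agree with a from-scratch median/IQR recomputation
  g2 <- electrode_grid(6, 10)
  set.seed(9)
  ft2 <- feature_table(g2, p_lt = matrix(runif(60, 0, 0.02), 6),
                       p_linet = matrix(runif(60, 0, 0.1), 6), rms = 1)
  ref2 <- select_reference(ft2)
  th2 <- compute_global_thresholds(ref2, detector_config())
  plt <- ft2$p_lt[ref2$members]; plin <- ft2$p_linet[ref2$members]
  expect_equal(th2$thresh_lt, 11.2 * naive_median(plt) + 1.5 * naive_iqr(plt))
  expect_equal(th2$thresh_linet,
               min(0.85, 2.5 * naive_median(plin) + 1.5 * naive_iqr(plin)))
})

test_that("neighbourhood RMS threshold follows the pair construction", {
  g <- electrode_grid(3, 3)
  # all six neighbours at 1.0: zero spread -> threshold 1.0
  ft <- feature_table(g, 0.01, 0.02, rms = 1)
  expect_equal(neighbor_rms_threshold(ft, 2, 2, k2 = 0.2), 1.0)

  # hand case: p_a=[2,2], p_b=[1,3], p_c=[2,2] -> 2 + 0.2*sd([1,3]) = 2 + 0.2*sqrt(2)
  rms <- matrix(2, 3, 3)
  rms[1, 1] <- 1; rms[3, 3] <- 3
  ft2 <- feature_table(g, 0.01, 0.02, rms = rms)
  expect_equal(neighbor_rms_threshold(ft2, 2, 2, k2 = 0.2), 2 + 0.2 * sqrt(2))

  # border channel: equals the value computed on an explicitly mirror-padded grid
  g4 <- electrode_grid(4, 5)
  set.seed(11)
  r4 <- matrix(runif(20, 0.5, 1.5), 4, 5)
  ft4 <- feature_table(g4, 0.01, 0.02, rms = r4)
  pad <- rbind(r4[2, ], r4, r4[3, ])           # mirror rows about the borders
  pad <- cbind(pad[, 2], pad, pad[, ncol(pad) - 1])
  for (cc in 1:5) {
    i <- 2; j <- cc + 1                        # row 1 in padded coordinates
    pa <- c(pad[i - 1, j], pad[i + 1, j])
    pb <- c(pad[i - 1, j - 1], pad[i + 1, j + 1])
    pc <- c(pad[i + 1, j - 1], pad[i - 1, j + 1])
    expected <- min(mean(pa), mean(pb), mean(pc)) +
      0.2 * max(sd(pa), sd(pb), sd(pc))
    expect_equal(neighbor_rms_threshold(ft4, 1, cc, k2 = 0.2), expected)
  }

  g1 <- electrode_grid(1, 4)
  ft1 <- feature_table(g1, 0.01, 0.02, rms = 1)
  expect_error(neighbor_rms_threshold(ft1, 1, 2), class = "undefined_neighborhood_error")
})

test_that("classification flags exactly the engineered artifact channels", {
  # clean homogeneous synthetic sets -> (almost) no flags: specificity >= 99%
  sets <- make_labeled_sets(20, seed = 400, prevalence = c(0, 0))
  fp <- sum(vapply(sets, function(s)
    sum(classify_channels(s$features)$flagged), numeric(1)))
  expect_lt(fp / (20 * 102), 0.01)

  # a single saturated power-line channel: that channel only, rule "line"
  rec <- fixture_recording(seed = 41)
  rec <- inject_artifact(rec, 2, 7, "powerline", severity = 8, seed = 1)
  mask <- classify_channels(channel_features(rec))
  expect_true(mask$flagged[2, 7])
  expect_match(mask$rules[2, 7], "line")

  # isolated low-amplitude channel inside the active blob -> rule "rms";
  # a channel of the same amplitude whose neighbours are equally low -> clean
  g <- fixture_grid()
  base <- target_rms_profile(g, fixture_blobs(g), 0.01)
  low <- base
  low[3, 5] <- 0.05 * base[3, 5]               # isolated deficit in active region
  ft <- feature_table(g, 0.003, 0.09, rms = low)
  m <- classify_channels(ft)
  expect_true(m$flagged[3, 5])
  expect_equal(m$rules[3, 5], "rms")

  # a low but spatially consistent region (all neighbours equally low) stays
  # clean away from its boundary with the active area
  flat <- base
  flat[, 14:17] <- 0.05 * base[3, 5]
  ftf <- feature_table(g, 0.003, 0.09, rms = flat)
  mf <- classify_channels(ftf)
  expect_false(any(mf$flagged[, 16:17]))
})

test_that("detection performance reproduces hand-computed confusion indexes", {
  truth <- matrix(FALSE, 10, 10); truth[1, 1:5] <- TRUE
  perf <- evaluate_detection(truth, truth)
  expect_equal(c(perf$s, perf$sp, perf$p, perf$acc), c(1, 1, 1, 1))

  # TP=3, FN=1, TN=95, FP=1
  pred <- matrix(FALSE, 10, 10)
  pred[1, 1:3] <- TRUE                          # 3 hits
  pred[5, 5] <- TRUE                            # 1 false alarm
  truth2 <- matrix(FALSE, 10, 10); truth2[1, 1:4] <- TRUE
  perf2 <- evaluate_detection(pred, truth2)
  expect_equal(perf2$s, 0.75)
  expect_equal(perf2$sp, 95 / 96)
  expect_equal(perf2$p, 0.75)
  expect_equal(perf2$acc, 0.98)

  empty <- matrix(FALSE, 5, 5)
  perf3 <- evaluate_detection(empty, empty)
  expect_equal(perf3$sp, 1); expect_equal(perf3$acc, 1)
  expect_true(is.na(perf3$s)); expect_true(is.na(perf3$p))

  expect_error(evaluate_detection(empty, matrix(FALSE, 4, 4)),
               class = "invalid_argument")
})

test_that("rule monotonicity and scale invariance hold across constants", {
  sets <- make_labeled_sets(4, seed = 300)
  ft <- sets[[2]]$features
  lowfreq_count <- function(k1) {
    m <- classify_channels(ft, detector_config(k1 = k1))
    sum(grepl("lowfreq", m$rules))
  }
  counts <- vapply(c(2, 5, 9, 11.2, 20), lowfreq_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
  rms_count <- function(k2) {
    m <- classify_channels(ft, detector_config(k2 = k2))
    sum(grepl("rms", m$rules))
  }
  counts2 <- vapply(c(0.05, 0.2, 0.6, 1.5), rms_count, numeric(1))
  expect_true(all(diff(counts2) >= 0))

  # multiplying all signals by a constant leaves the mask unchanged
  rec <- fixture_recording(seed = 55)
  rec <- inject_artifact(rec, 3, 4, "isolated_amplitude", 0.05)
  m1 <- classify_channels(channel_features(rec))
  rec$samples <- rec$samples * 120
  m2 <- classify_channels(channel_features(rec))
  expect_identical(m1$flagged, m2$flagged)
})

test_that("operating-point tuning selects by distance with documented tie-breaks", {
  sets <- make_labeled_sets(6, seed = 500)
  roc <- tune_constants(sets, criterion = "roc")
  pr <- tune_constants(sets, criterion = "pr")
  # both criteria must return grid members and a full curve
  expect_true(all(c(roc$k1, pr$k1) %in% c(2, 4, 7.1, 11.2, 16)))
  expect_equal(nrow(roc$curve), 5 * 4)
  # a perfect point is selected by both criteria (zero distance)
  expect_gte(pr$performance$p, roc$performance$p)
  expect_lte(pr$performance$s, roc$performance$s + 1e-12)

  expect_error(tune_constants(sets, k1_grid = numeric(0)),
               class = "invalid_argument")
  clean <- make_labeled_sets(2, seed = 501, prevalence = c(0, 0))
  expect_error(tune_constants(clean), class = "invalid_argument")
})

test_that("majority vote and Fleiss' kappa match first-principles computation", {
  expect_equal(majority_vote(rbind(c(1, 0), c(1, 0), c(0, 0))), c(1L, 0L))
  expect_error(majority_vote(rbind(c(1, 0), c(1, 0))), class = "invalid_argument")

  set.seed(8)
  lab <- matrix(rbinom(3 * 40, 1, 0.3), nrow = 3)
  expect_equal(majority_vote(lab), as.integer(colSums(lab) >= 2))

  # perfect agreement on mixed items
  one <- rbind(rep(c(0, 1), 25), rep(c(0, 1), 25), rep(c(0, 1), 25))
  expect_equal(fleiss_kappa(one), 1)

  # independent random raters: near-zero agreement
  set.seed(9)
  rnd <- matrix(rbinom(3 * 1000, 1, 0.5), nrow = 3)
  expect_lt(abs(fleiss_kappa(rnd)), 0.05)

  # toy table equals the published-formula oracle
  set.seed(10)
  toy <- matrix(rbinom(18, 1, 0.4), nrow = 3)
  expect_equal(fleiss_kappa(toy), naive_fleiss(toy))

  # single category everywhere: undefined
  expect_true(is.na(fleiss_kappa(matrix(1, 3, 6))))
})
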