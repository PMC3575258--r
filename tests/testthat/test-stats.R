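test_that("blocked Friedman matches closed forms and reference implementations", {
  # identical values everywhere: midranks give chi2 = 0, p = 1
  same <- matrix(5, 6, 4)
  r0 <- friedman_blocked(same)
  expect_equal(r0$chi2, 0); expect_equal(r0$p, 1)

  # unanimous strict ranking, no replication: chi2 = n (k - 1)
  for (n in c(4, 7, 12)) for (k in c(3, 5)) {
    v <- t(replicate(n, seq_len(k))) + 0
    expect_equal(friedman_blocked(v)$chi2, n * (k - 1))
  }

  # random layouts (with ties): identical to stats::friedman.test
  for (s in 1:10) {
    set.seed(s)
    v <- matrix(sample(1:5, 8 * 4, replace = TRUE) + 0, 8, 4)
    ours <- friedman_blocked(v)
    ref <- stats::friedman.test(v)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  # replicated layout: asymptotic p agrees with a permutation oracle
  set.seed(77)
  v <- matrix(rnorm(4 * 2 * 3), nrow = 8, ncol = 3)
  v[, 3] <- v[, 3] + 1.2
  p_asym <- friedman_blocked(v, reps = 2)$p
  p_perm <- perm_friedman_p(v, reps = 2, B = 4000, seed = 2)
  expect_lt(abs(p_asym - p_perm), 0.04)

  expect_error(friedman_blocked(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "incomplete_design")
  expect_error(friedman_blocked(matrix(1:9, 3, 3), reps = 2),
               class = "incomplete_design")
})

test_that("repeated-measures Friedman applies the Bonferroni critical value", {
  # all subjects share one ranking over 12 conditions: chi2 = 11 n, significant
  v <- t(replicate(12, 1:12)) + 0
  r <- friedman_repeated(v)
  expect_equal(r$chi2, 12 * 11)
  expect_equal(r$critical, chi2_critical(11, 0.05 / 12))
  expect_true(r$significant)

  cst <- matrix(3, 9, 12)
  r2 <- friedman_repeated(cst)
  expect_equal(r2$chi2, 0)
  expect_false(r2$significant)

  expect_error(friedman_repeated(matrix(c(1, NA), 1, 2)),
               class = "incomplete_design")
})

test_that("chi-square critical values agree with numeric CDF inversion", {
  expect_equal(round(chi2_critical(1, 0.05), 2), 3.84)
  expect_equal(round(chi2_critical(11, 0.05 / 12), 2), 27.28)

  # independent oracle: invert the integrated chi-square density
  crit_oracle <- function(dof, alpha) {
    cdf <- function(q) stats::integrate(function(x) stats::dchisq(x, dof),
                                        0, q, rel.tol = 1e-12)$value
    stats::uniroot(function(q) cdf(q) - (1 - alpha), c(1e-6, 200),
                   tol = 1e-10)$root
  }
  for (dof in c(1, 5, 11, 20)) for (a in c(0.05, 0.01, 0.05 / 12)) {
    expect_equal(chi2_critical(dof, a), crit_oracle(dof, a), tolerance = 1e-6)
  }
  expect_error(chi2_critical(0, 0.05), class = "invalid_argument")
  expect_error(chi2_critical(3, 1.2), class = "invalid_argument")
})

test_that("Wilcoxon signed rank handles shifts, symmetry, and degeneracy", {
  x <- c(1.2, 2.1, 0.7, 3.3, 2.8, 1.9, 2.2, 1.1)
  r <- wilcoxon_signed_rank(x + 1.5, x)
  expect_lt(r$p, 0.05)

  # exactly symmetric differences: the rank sum splits evenly, p near 1
  x2 <- c(1:8, -(1:8)) + 0
  r2 <- wilcoxon_signed_rank(x2, numeric(16))
  expect_gt(r2$p, 0.8)

  expect_error(wilcoxon_signed_rank(x, x), class = "degenerate_test")
})

test_that("leave-one-out LDA separates, guesses at chance, and pools counts", {
  set.seed(15)
  # two far-separated spherical classes: perfect accuracy
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  r <- lda_loo(x, y)
  expect_equal(r$acc, 1)
  expect_equal(sum(r$confusion), 40)

  # permuted labels over 4 balanced classes: accuracy near chance (25%)
  set.seed(16)
  x4 <- matrix(rnorm(400 * 3), ncol = 3)
  y4 <- sample(rep(letters[1:4], each = 100))
  r4 <- lda_loo(x4, y4)
  expect_lt(abs(mean(diag(r4$confusion)) * 4 / sum(r4$confusion) - 0.25), 0.08)
  # micro-averaged indexes recompute exactly from pooled counts
  expect_equal(r4$s, r4$tp / (r4$tp + r4$fn))
  expect_equal(r4$sp, r4$tn / (r4$tn + r4$fp))
  expect_equal(r4$acc, (r4$tp + r4$tn) / (r4$tp + r4$tn + r4$fp + r4$fn))
  expect_equal(sum(r4$confusion), 400)

  expect_error(lda_loo(x[1:3, ], c("a", "a", "b")), class = "invalid_argument")

  # collinear features force the ridge fallback
  xc <- cbind(rep(c(0, 4), each = 10), rep(c(0, 4), each = 10))
  yc <- rep(c("a", "b"), each = 10)
  expect_message(rc <- lda_loo(xc + rnorm(40, sd = 1e-9), yc), "ridge")
  expect_equal(rc$acc, 1)
})

test_that("per-muscle normalisation is exact and scale invariant", {
  ft <- data.frame(muscle = rep(c("m1", "m2"), each = 6),
                   rms_av_hd = c(rnorm(6, 10), rnorm(6, 2)),
                   rms_av_bip = rep(4, 12))
  out <- normalize_per_muscle(ft, c("rms_av_hd", "rms_av_bip"))
  expect_equal(as.numeric(tapply(out$rms_av_hd, out$muscle, mean)), c(1, 1))
  expect_true(all(out$rms_av_bip == 1))

  ft2 <- ft; ft2$rms_av_hd[ft2$muscle == "m1"] <- 10 * ft$rms_av_hd[ft$muscle == "m1"]
  out2 <- normalize_per_muscle(ft2, "rms_av_hd")
  expect_equal(out2$rms_av_hd, out$rms_av_hd)

  ftz <- data.frame(muscle = "m", rms_av_hd = c(0, 0))
  expect_error(normalize_per_muscle(ftz, "rms_av_hd"), class = "invalid_argument")
})
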