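#' Upper-tail chi-square critical value
#'
#' @param dof degrees of freedom (>= 1).
#' @param alpha upper-tail probability in (0, 1); for Bonferroni-corrected
#'   decisions pass the corrected level (e.g. `0.05 / 12`).
#' @return the critical value `q` with `P(X > q) = alpha`.
#' @examples
#' chi2_critical(1, 0.05)        # 3.84
#' chi2_critical(11, 0.05 / 12)  # 27.28
#' @export
chi2_critical <- function(dof, alpha) {
  if (!is.numeric(dof) || any(dof < 1)) {
    stop_hdemg("invalid_argument", "`dof` must be >= 1")
  }
  if (!is.numeric(alpha) || any(alpha <= 0 | alpha >= 1)) {
    stop_hdemg("invalid_argument", "`alpha` must be in (0, 1)")
  }
  stats::qchisq(1 - alpha, df = dof)
}

#' Friedman test for a blocked two-way layout with replication
#'
#' Rank-based test of treatment effects with blocks, allowing `reps`
#' replicate observations per (block, treatment) cell: all `reps * k` values
#' of a block are ranked jointly (midranks for ties), treatment rank sums
#' are compared against their null expectation, and the statistic is
#' referred to the chi-square distribution with `k - 1` degrees of freedom.
#' With `reps = 1` this is the classic Friedman test (identical, including
#' tie correction, to the textbook tie-corrected statistic). Under a
#' unanimous strict ranking with `reps = 1` the statistic equals
#' `n * (k - 1)`.
#'
#' @param values numeric matrix with `n_blocks * reps` rows and `k`
#'   (treatments) columns; consecutive groups of `reps` rows form one block.
#' @param reps replicates per cell (default 1).
#' @param alpha significance level (default 0.05).
#' @return an object of class `friedman_result`: `chi2`, `dof`, `p`,
#'   `significant`.
#' @export
friedman_blocked <- function(values, reps = 1, alpha = 0.05) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_hdemg("incomplete_design", "missing cells in the layout")
  k <- ncol(values)
  if (k < 2L) stop_hdemg("invalid_argument", "need >= 2 treatments")
  if (nrow(values) %% reps != 0L) {
    stop_hdemg("incomplete_design", "row count is not a multiple of `reps`")
  }
  n <- nrow(values) %/% reps
  if (n < 2L) stop_hdemg("invalid_argument", "need >= 2 blocks")
  N <- reps * k
  Rj <- numeric(k)
  V <- 0
  for (b in seq_len(n)) {
    block <- values[((b - 1L) * reps + 1L):(b * reps), , drop = FALSE]
    r <- matrix(rank(block), nrow = reps)     # joint midranks within the block
    Rj <- Rj + colSums(r)
    s2 <- sum((r - (N + 1) / 2)^2) / (N - 1)  # empirical rank variance (ties)
    V <- V + reps * (N - reps) / N * s2
  }
  E <- n * reps * (N + 1) / 2
  chi2 <- if (V > 0) (k - 1) / k * sum((Rj - E)^2) / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = k - 1, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, dof = k - 1L, p = p,
                 significant = is.finite(p) && p < alpha,
                 alpha = alpha, n_blocks = n, reps = reps),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman_result> chi2(%d) = %.4g, p = %.4g%s\n",
              x$dof, x$chi2, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Repeated-measures Friedman test over task-by-effort conditions
#'
#' Friedman test over the repeated condition measures of each subject
#' (by default the 12 conditions of 4 tasks x 3 efforts), with significance
#' judged against the Bonferroni-corrected chi-square critical value for the
#' number of comparisons at family level `alpha` (for 12 conditions:
#' `chi2(11) > 27.28` at alpha = 0.05).
#'
#' @param measures numeric matrix, subjects x conditions (complete).
#' @param alpha family significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (defaults to the number of
#'   conditions).
#' @return a `friedman_result` with the Bonferroni-corrected decision and
#'   the critical value used.
#' @export
friedman_repeated <- function(measures, alpha = 0.05,
                              n_comparisons = ncol(measures)) {
  measures <- as.matrix(measures)
  if (anyNA(measures)) stop_hdemg("incomplete_design", "incomplete subject rows")
  res <- friedman_blocked(measures, reps = 1, alpha = alpha)
  crit <- chi2_critical(res$dof, alpha / n_comparisons)
  res$critical <- crit
  res$n_comparisons <- n_comparisons
  res$significant <- res$chi2 > crit
  res
}

#' Wilcoxon signed rank test for paired samples
#'
#' Two-sided signed-rank test with midranks for ties and zero differences
#' dropped (asymptotic p-value).
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V), `p`, and `n_used` (non-zero
#'   differences).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_hdemg("invalid_argument", "x and y lengths differ")
  d <- x - y
  nz <- d != 0
  if (!any(nz)) stop_hdemg("degenerate_test", "all paired differences are zero")
  wt <- suppressWarnings(stats::wilcox.test(x[nz], y[nz], paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n_used = sum(nz))
}

# pooled-covariance linear discriminant scores with optional ridge
lda_ridge_predict <- function(train_x, train_y, test_x, ridge = 1e-6) {
  classes <- levels(train_y)
  p <- ncol(train_x)
  means <- t(vapply(classes, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]), numeric(p)))
  pooled <- matrix(0, p, p)
  for (cl in classes) {
    xc <- scale(train_x[train_y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (nrow(train_x) - length(classes))
  pooled <- pooled + ridge * mean(diag(pooled)) * diag(p)
  Sinv <- solve(pooled)
  scores <- vapply(classes, function(cl) {
    m <- means[cl, ]
    as.numeric(test_x %*% Sinv %*% m - 0.5 * sum(m * (Sinv %*% m)))
  }, numeric(nrow(test_x)))
  classes[max.col(matrix(scores, nrow = nrow(test_x)))]
}

#' Leave-one-out linear discriminant classification
#'
#' Each sample is classified by a linear discriminant (pooled within-class
#' covariance, uniform priors, matching the balanced design) fitted on all
#' remaining samples. When the pooled covariance is singular a small ridge
#' is added (with a message). The pooled confusion matrix is summarised by
#' micro-averaged one-vs-rest counts and the four performance indexes.
#'
#' @param features numeric matrix or data.frame of feature columns.
#' @param labels class labels (factor or coercible).
#' @return an object of class `classification_result`: `confusion` (true x
#'   predicted), pooled `tp`, `fp`, `tn`, `fn`, and `acc`, `s`, `sp`, `p`.
#' @export
lda_loo <- function(features, labels) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- factor(labels)
  if (any(table(y) < 2L)) stop_hdemg("invalid_argument", "need >= 2 samples per class")
  if (ncol(x) >= nrow(x) - 1L) {
    stop_hdemg("invalid_argument", "feature count must be below sample count - 1")
  }
  n <- nrow(x)
  pred <- character(n)
  prior <- rep(1 / nlevels(y), nlevels(y))
  for (i in seq_len(n)) {
    fit <- tryCatch(
      MASS::lda(x[-i, , drop = FALSE], grouping = droplevels(y[-i]), prior =
                  rep(1 / nlevels(droplevels(y[-i])), nlevels(droplevels(y[-i])))),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("pooled covariance singular; adding ridge regularisation")
      pred[i] <- lda_ridge_predict(x[-i, , drop = FALSE], droplevels(y[-i]),
                                   x[i, , drop = FALSE])
    } else {
      pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE])$class)
    }
  }
  pred <- factor(pred, levels = levels(y))
  confusion <- table(true = y, predicted = pred)
  classification_metrics(confusion)
}

#' Multiclass performance indexes from a confusion matrix
#'
#' Micro-averaged one-vs-rest counts: correctly classified samples are true
#' positives, samples missing from their class are false negatives, samples
#' wrongly assigned to a class are its false positives, and the remaining
#' per-class complements are true negatives.
#'
#' @param confusion square counts table (true x predicted).
#' @return an object of class `classification_result`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  tp_k <- diag(confusion)
  fn_k <- rowSums(confusion) - tp_k
  fp_k <- colSums(confusion) - tp_k
  tn_k <- total - tp_k - fn_k - fp_k
  tp <- sum(tp_k); fp <- sum(fp_k); tn <- sum(tn_k); fn <- sum(fn_k)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(confusion = confusion, tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = safe(tp + tn, tp + tn + fp + fn),
                 s = safe(tp, tp + fn), sp = safe(tn, tn + fp),
                 p = safe(tp, tp + fp)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d classes, Acc=%.3f S=%.3f SP=%.3f P=%.3f\n",
              nrow(x$confusion), x$acc, x$s, x$sp, x$p))
  invisible(x)
}

#' Normalise features by per-muscle grand means
#'
#' Divides each feature value by the grand mean of that muscle's values over
#' all tasks and contraction levels, removing between-recording-type and
#' between-muscle scale so that bipolar- and map-derived intensities are
#' comparable.
#'
#' @param features data.frame with a `muscle` column.
#' @param cols names of the numeric feature columns to normalise.
#' @return the data.frame with normalised columns.
#' @export
normalize_per_muscle <- function(features, cols) {
  for (cl in cols) {
    means <- tapply(features[[cl]], features$muscle, mean)
    if (any(!is.finite(means)) || any(means == 0)) {
      stop_hdemg("invalid_argument",
                 sprintf("zero or non-finite grand mean for column '%s'", cl))
    }
    features[[cl]] <- features[[cl]] / means[as.character(features$muscle)]
  }
  features
}
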