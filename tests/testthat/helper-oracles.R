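# Independent brute-force oracles, deliberately naive: direct definitions,
# double loops, iterate-until-stable. Never call the implementation paths
# they are used to check.

naive_reconstruct <- function(marker, mask, connectivity = 8) {
  nr <- nrow(marker); nc <- ncol(marker)
  cur <- marker
  repeat {
    nxt <- cur
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      best <- cur[i, j]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (connectivity == 4 && abs(di) + abs(dj) != 1) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          best <- max(best, cur[ii, jj])
        }
      }
      nxt[i, j] <- min(best, mask[i, j])
    }
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

naive_se_apply <- function(m, radius, element, op) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (element == "cross" && abs(di) + abs(dj) > radius) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- op(vals)
  }
  out
}

naive_open <- function(m, radius = 1, element = "cross") {
  naive_se_apply(naive_se_apply(m, radius, element, min), radius, element, max)
}

# type-7 quantile from first principles (sorted values + linear interpolation)
naive_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
naive_iqr <- function(x) naive_quantile7(x, 0.75) - naive_quantile7(x, 0.25)
naive_median <- function(x) naive_quantile7(x, 0.5)

# permutation Friedman: permute jointly-ranked cells within blocks
perm_friedman_p <- function(values, reps, B = 2000, seed = 1) {
  obs <- friedman_blocked(values, reps)$chi2
  n <- nrow(values) %/% reps
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(B)) {
    perm <- values
    for (bl in seq_len(n)) {
      rows <- ((bl - 1) * reps + 1):(bl * reps)
      block <- values[rows, , drop = FALSE]
      perm[rows, ] <- matrix(sample(block), nrow = reps)
    }
    if (friedman_blocked(perm, reps)$chi2 >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / B
}

# Fleiss' kappa straight from the published recipe
naive_fleiss <- function(labels) {
  n <- nrow(labels); N <- ncol(labels)
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    n1 <- sum(labels[, i]); n0 <- n - n1
    P_i[i] <- (n0 * (n0 - 1) + n1 * (n1 - 1)) / (n * (n - 1))
  }
  p1 <- sum(labels) / (n * N); p0 <- 1 - p1
  Pe <- p0^2 + p1^2
  (mean(P_i) - Pe) / (1 - Pe)
}
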