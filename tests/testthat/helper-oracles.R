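# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# earliest start time (min) of a run of consecutive below-threshold samples
# spanning >= dwell_s; NA if none. Plain double loop.
oracleOcclusionScan <- function(time_s, flow, threshold = 0.001,
                                dwell_s = 180) {
  n <- length(flow)
  i <- 1L
  while (i <= n) {
    if (flow[i] < threshold) {
      j <- i
      while (j < n && flow[j + 1L] < threshold) j <- j + 1L
      if (time_s[j] - time_s[i] >= dwell_s) return(time_s[i] / 60)
      i <- j + 1L
    }
    i <- i + 1L
  }
  NA_real_
}

# element-wise central difference of raw volumes, one-sided at the edges,
# in mL/min
oracleCentralDifference <- function(time_s, vol_mL) {
  n <- length(vol_mL)
  f <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) f[i] <- (vol_mL[2] - vol_mL[1]) / (time_s[2] - time_s[1])
    else if (i == n) f[i] <- (vol_mL[n] - vol_mL[n - 1]) /
        (time_s[n] - time_s[n - 1])
    else f[i] <- (vol_mL[i + 1] - vol_mL[i - 1]) /
        (time_s[i + 1] - time_s[i - 1])
  }
  f * 60
}

# per-pixel maximum across slices by explicit triple loop
oracleMIP <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1]))
    for (r in seq_len(d[2]))
      for (cc in seq_len(d[3]))
        out[r, cc] <- max(out[r, cc], stack[z, r, cc])
  out
}

oracleSum <- function(image) {
  s <- 0
  for (v in as.vector(image)) s <- s + v
  s
}

# two-way fully-within-subject ANOVA via explicit sums of squares;
# returns F and p for both main effects and the interaction
oracleRmAnova2x2 <- function(value, A, B, donor) {
  A <- factor(A); B <- factor(B); donor <- factor(donor)
  n <- nlevels(donor)
  M <- mean(value)
  mA <- tapply(value, A, mean); mB <- tapply(value, B, mean)
  mS <- tapply(value, donor, mean)
  mAB <- tapply(value, list(A, B), mean)
  mAS <- tapply(value, list(A, donor), mean)
  mBS <- tapply(value, list(B, donor), mean)
  ssA <- 2 * n * sum((mA - M)^2)
  ssB <- 2 * n * sum((mB - M)^2)
  ssS <- 4 * sum((mS - M)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + M)^2)
  ssAS <- 2 * sum((mAS - outer(mA, rep(1, n)) -
                     outer(rep(1, 2), mS) + M)^2)
  ssBS <- 2 * sum((mBS - outer(mB, rep(1, n)) -
                     outer(rep(1, 2), mS) + M)^2)
  ssTot <- sum((value - M)^2)
  ssABS <- ssTot - ssA - ssB - ssS - ssAB - ssAS - ssBS
  f <- c(A = (ssA / 1) / (ssAS / (n - 1)),
         B = (ssB / 1) / (ssBS / (n - 1)),
         AB = (ssAB / 1) / (ssABS / (n - 1)))
  p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  list(F = f, p = p)
}

# Friedman chi-squared from explicit within-donor ranks
oracleFriedman <- function(m) {
  ranks <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 * n / (k * (k + 1)) * sum((colMeans(ranks) - (k + 1) / 2)^2)
}

# analytic logistic solution f(t) for df/dt = r f (1 - f), f(0) = f0
logisticClosedForm <- function(t, r, f0) {
  1 / (1 + (1 - f0) / f0 * exp(-r * t))
}

# small quenched-scenario config used across tests (small images)
quickConfig <- function(seed, ...) {
  simConfig("pressure_relief_quenched", seed = seed,
            imageRows = 12L, imageCols = 16L, ...)
}
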