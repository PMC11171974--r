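# Independent brute-force oracles used across the test files.

# queen contiguity by pairwise vertex-set intersection
oracle_queen <- function(areas, digits = 9) {
  n <- length(areas)
  vsets <- lapply(areas, function(a) {
    v <- do.call(rbind, lapply(a$rings, function(r) r[-nrow(r), , drop = FALSE]))
    unique(paste(round(v[, 1], digits), round(v[, 2], digits)))
  })
  m <- matrix(0L, n, n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      if (length(intersect(vsets[[j]], vsets[[k]])) > 0) m[j, k] <- m[k, j] <- 1L
    }
  }
  m
}

# distance band by nested-loop thresholding
oracle_distance <- function(cen, band) {
  n <- nrow(cen)
  m <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) {
        d <- sqrt(sum((cen[j, ] - cen[k, ])^2))
        if (d > 0 && d <= band) m[j, k] <- 1L
      }
    }
  }
  m
}

oracle_min_band <- function(cen) {
  n <- nrow(cen)
  worst <- -Inf
  for (j in seq_len(n)) {
    nn <- Inf
    for (k in seq_len(n)) {
      if (k != j) nn <- min(nn, sqrt(sum((cen[j, ] - cen[k, ])^2)))
    }
    worst <- max(worst, nn)
  }
  worst
}

# direct-arithmetic WAIC on a small matrix
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  list(lppd = lppd, p_waic = p, waic = -2 * (lppd - p))
}

# PSRF by the hand formula
oracle_psrf <- function(chains) {
  nr <- length(chains[[1]])
  Ww <- mean(sapply(chains, var))
  B <- nr * var(sapply(chains, mean))
  sqrt(((nr - 1) / nr * Ww + B / nr) / Ww)
}

# a small patient table with known outcome, for design/crosstab tests
tiny_records <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    area_id = sample(c("a001", "a002", "a003", "a004"), n, TRUE),
    year = sample(2015:2021, n, TRUE),
    institution = sample(c("Private", "Public"), n, TRUE),
    poor_qol = rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE)
}
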