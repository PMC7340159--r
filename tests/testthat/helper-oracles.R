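# Independent oracles used to freeze expected values. Each is deliberately a
# different computation route from the package implementation it checks.

# Hardy-Weinberg exact test by recurrence-ratio enumeration of the
# conditional heterozygote distribution (the implementation uses direct
# log-factorials instead).
hwe_oracle_dist <- function(n, nA) {
  h0 <- nA %% 2L
  hmax <- min(nA, 2L * n - nA)
  hets <- seq.int(h0, hmax, by = 2L)
  vals <- numeric(length(hets))
  vals[1] <- 1
  if (length(hets) > 1L) {
    for (k in seq_len(length(hets) - 1L)) {
      h <- hets[k]
      vals[k + 1L] <- vals[k] * 4 * ((nA - h) / 2) * ((2 * n - nA - h) / 2) /
        ((h + 1) * (h + 2))
    }
  }
  probs <- vals / sum(vals)
  names(probs) <- hets
  probs
}

hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  probs <- hwe_oracle_dist(n, nA)
  p_obs <- probs[[as.character(n_Aa)]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# AUC by exhaustive pair counting (the implementation uses midranks).
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Nagelkerke R2 via iterative grid-search maximization of the two logistic
# log-likelihoods (no IRLS, no glm).
nagelkerke_grid_oracle <- function(scores, labels) {
  y <- as.integer(labels)
  n <- length(y)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * scores
    mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  center <- c(0, 0)
  span <- c(8, 8 / max(stats::sd(scores), 1e-8))
  best <- -Inf
  for (stage in 1:6) {
    b0s <- seq(center[1] - span[1], center[1] + span[1], length.out = 41)
    b1s <- seq(center[2] - span[2], center[2] + span[2], length.out = 41)
    grid <- outer(b0s, b1s, Vectorize(ll))
    ix <- arrayInd(which.max(grid), dim(grid))
    best <- max(grid)
    center <- c(b0s[ix[1]], b1s[ix[2]])
    span <- span / 6
  }
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  r2_cs <- 1 - exp(-(2 / n) * (best - ll0))
  r2_cs / (1 - exp((2 / n) * ll0))
}
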