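# Independent oracles used across the suite.

# AUC by exhaustive pair enumeration: concordant pairs + half ties over
# all positive x negative pairs.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Youden maximizer by direct scan over every candidate threshold
# (midpoints of adjacent sorted unique scores plus the infinite extremes),
# rule "positive if score > cutoff", ties toward the smaller threshold.
youden_scan <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best_j <- -Inf; best_c <- NA
  for (cand in cands) {
    sens <- sum(scores > cand & labels == 1) / n1
    spec <- sum(scores <= cand & labels == 0) / n0
    j <- sens + spec - 1
    if (j > best_j + 1e-15) { best_j <- j; best_c <- cand }
  }
  list(cutoff = best_c, j = best_j)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (zero differences
# dropped, no ties assumed), using the standard doubling rule.
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (w_obs >= mu) {
    p <- 2 * mean(w_all >= w_obs)
  } else {
    p <- 2 * mean(w_all <= w_obs)
  }
  min(p, 1)
}

# Enumerate relational observations (every earlier-later stage pair plus
# the baseline singleton) by explicit loops.
relational_enumerate <- function(n_timepoints) {
  count <- 1  # baseline singleton
  for (j in seq_len(n_timepoints)) {
    for (i in seq_len(n_timepoints)) {
      if (i < j) count <- count + 1
    }
  }
  count
}

# Small deterministic cohort for integration-style tests.
tiny_cohort <- function(n = 6, seed = 421, noise_scale = 1, ...) {
  generate_cohort(n, generator_config(seed = seed, noise_scale = noise_scale,
                                      ...))
}
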