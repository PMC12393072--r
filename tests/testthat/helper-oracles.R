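## Independent oracles used across the suite.

## brute-force relative effect P(X < Y) + 0.5 P(X = Y) by pair enumeration
bmPhatOracle <- function(x, y) {
  (sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))) /
    (length(x) * length(y))
}

## naive double-loop Euclidean distances
naiveEuclidean <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  D
}

## closed-form two-class Fisher direction S_w^{-1} (mu2 - mu1)
fisherDirection <- function(m, labels) {
  f <- factor(labels)
  stopifnot(nlevels(f) == 2L)
  m1 <- colMeans(m[f == levels(f)[1], , drop = FALSE])
  m2 <- colMeans(m[f == levels(f)[2], , drop = FALSE])
  W <- matrix(0, ncol(m), ncol(m))
  for (l in levels(f)) {
    cm <- sweep(m[f == l, , drop = FALSE], 2,
                colMeans(m[f == l, , drop = FALSE]))
    W <- W + crossprod(cm)
  }
  Sw <- W / (nrow(m) - 2)
  solve(Sw, m2 - m1)
}

cosineSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

## sensor spec table with every response term switched off
flatSpecs <- function(names = "S1", baseline = 1000) {
  data.frame(name = names, baseline = baseline, drift_rate = 0,
             temp_coef = 0, hum_coef = 0, odor_gain = 1, noise_sd = 0,
             warmup_tau = 0, warmup_amp = 0, stringsAsFactors = FALSE)
}

## two tight, fully separated clusters for ANOSIM / LDA checks
separatedClusters <- function(nPer = 4, gap = 50, p = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- rbind(matrix(rnorm(nPer * p, 0, 0.1), nPer, p),
               matrix(rnorm(nPer * p, gap, 0.1), nPer, p))
    list(m = m, groups = rep(c("a", "b"), each = nPer))
  })
}
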