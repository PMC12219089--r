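# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they validate.

# Entry-by-entry pairwise Euclidean distances (double loop).
brute_distance_matrix <- function(traj) {
  n <- nrow(traj)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((traj[i, ] - traj[j, ])^2))
    }
  }
  D
}

# Tie-corrected rank-statistic AUC: mean over all positive/negative pairs of
# 1 (positive scores higher), 1/2 (tie), 0.
rank_auc <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]
  sn <- scores[!y]
  total <- 0
  for (p in sp) total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# Exhaustive accuracy scan over every threshold between observed scores, in
# both orientations, computed pointwise.
brute_best_accuracy <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  s <- sort(unique(scores))
  gaps <- if (length(s) > 1) min(diff(s)) / 2 else 1
  cand <- c(s - gaps, s + gaps)
  best <- -1
  for (t in cand) {
    for (orient in c(1, -1)) {
      pred <- if (orient == 1) as.integer(scores > t) else as.integer(scores < t)
      best <- max(best, mean(pred == y))
    }
  }
  best
}

# Canonical ordering of a (birth, death) pair matrix for multiset comparison.
sort_pairs <- function(p) {
  p <- matrix(p, ncol = 2)
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# Random test image: integer- or continuous-valued, with duplicates likely.
random_image <- function(h, w, mode = c("int", "float")) {
  mode <- match.arg(mode)
  vals <- switch(mode,
    int = sample(0:6, h * w, replace = TRUE),
    float = round(runif(h * w, 0, 3), 1)
  )
  matrix(vals, h, w)
}
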