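# Coerce labels to 0/1: accepts logical, 0/1 numeric, or a two-level
# factor/character (second sorted level = positive).
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2L) {
    stop("labels must be binary (logical, 0/1, or two distinct values); got ",
         length(u), " distinct value(s)")
  }
  as.integer(as.character(labels) == u[2])
}

check_scored_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  y <- as_binary_labels(labels)
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("both classes must be present")
  }
  y
}

#' ROC curve of a score against binary labels
#'
#' Computes the receiver operating characteristic for the rule "positive
#' when score >= threshold". Thresholds are the distinct scores (plus an
#' `Inf` sentinel), so tied scores cross the threshold together; the curve
#' starts at (0, 0), ends at (1, 1), and is monotone non-decreasing in
#' both coordinates.
#'
#' @param scores Numeric vector of scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or any two values; the
#'   larger sorted value is the positive class).
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- check_scored_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- cumsum(y)[grp_end] / n_pos
  fpr <- cumsum(1 - y)[grp_end] / n_neg
  data.frame(
    threshold = c(Inf, s[grp_end]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of [roc_curve()]. Equals the tie-corrected
#' Mann-Whitney statistic (ties credited 1/2) divided by
#' `n_pos * n_neg`, and is invariant under strictly increasing transforms
#' of the scores.
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Best single-threshold accuracy of a score
#'
#' Exhaustively scans every threshold (midpoints between consecutive
#' distinct sorted scores, plus sentinels outside the score range) in both
#' orientations — positive when the score is above, or below, the
#' threshold — and returns the maximizer. The orientation search matters
#' because NMF component scale and orientation are arbitrary. Ties in
#' accuracy prefer the "high" orientation, then the lowest threshold.
#'
#' @inheritParams roc_curve
#' @return List with `threshold`, `accuracy`, and `orientation` (`"high"`
#'   if positives score above the threshold, else `"low"`).
#' @export
best_threshold_accuracy <- function(scores, labels) {
  y <- check_scored_labels(scores, labels)
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) {
    c(s - 1, s + 1)
  } else {
    c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  }
  n <- length(y)
  best <- list(threshold = NA_real_, accuracy = -1, orientation = "high")
  for (orient in c("high", "low")) {
    for (t in cand) {
      pred <- if (orient == "high") as.integer(scores > t) else as.integer(scores < t)
      a <- mean(pred == y)
      better <- a > best$accuracy + 1e-15 ||
        (abs(a - best$accuracy) <= 1e-15 && orient == best$orientation &&
           !is.na(best$threshold) && t < best$threshold)
      if (better) best <- list(threshold = t, accuracy = a, orientation = orient)
    }
  }
  best
}

#' Write ROC points or metric tables as delimited text
#'
#' @param df Data frame (e.g. from [roc_curve()] or pipeline metrics).
#' @param path Output path.
#' @export
write_metrics <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
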