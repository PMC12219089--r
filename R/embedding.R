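#' Delay-embed a univariate time series
#'
#' Maps a scalar series `x` of length `T` to the trajectory matrix whose
#' i-th row is `(x[i], x[i + tau], ..., x[i + (k-1) tau])`, the standard
#' delay embedding used to reconstruct attractor geometry from a single
#' observable. With the default `tau = 1` consecutive samples are used and
#' the embedding has `T - k + 1` rows.
#'
#' @param x Numeric vector, all values finite.
#' @param k Embedding dimension (positive integer). Default 3, the value
#'   used throughout the downstream recurrence-plot analysis.
#' @param tau Delay between coordinates, in samples (positive integer).
#' @return A numeric matrix with `T - (k-1)*tau` rows and `k` columns, with
#'   attributes `k` and `tau`.
#' @examples
#' delay_embed(1:5, k = 3)
#' @seealso [recurrence_distance_matrix()]
#' @export
delay_embed <- function(x, k = 3L, tau = 1L) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) {
    stop("series contains non-finite values (NaN/Inf/NA)")
  }
  k <- as.integer(k)
  tau <- as.integer(tau)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  if (length(tau) != 1L || is.na(tau) || tau < 1L) stop("tau must be a positive integer")
  T_len <- length(x)
  need <- (k - 1L) * tau + 1L
  if (T_len < need) {
    stop(sprintf(
      "series too short for embedding: T = %d but k = %d and tau = %d require T >= %d",
      T_len, k, tau, need
    ))
  }
  n <- T_len - (k - 1L) * tau
  idx <- outer(seq_len(n), (seq_len(k) - 1L) * tau, "+")
  m <- matrix(x[idx], nrow = n, ncol = k)
  attr(m, "k") <- k
  attr(m, "tau") <- tau
  m
}

#' Recurrence distance matrix of an embedded trajectory
#'
#' Computes the square matrix `D` with `D[i, j]` the Euclidean distance
#' between trajectory rows i and j. Viewed as a grayscale image this is the
#' (unthresholded) recurrence plot of the series; it is symmetric,
#' non-negative, and has a zero diagonal.
#'
#' @param traj Numeric matrix of embedded states (rows = time points), as
#'   returned by [delay_embed()], with at least one row.
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @return An M x M numeric matrix with attribute `metric`.
#' @examples
#' recurrence_distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)))
#' @export
recurrence_distance_matrix <- function(traj, metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  traj <- as.matrix(traj)
  if (nrow(traj) < 1L) stop("trajectory must have at least one row")
  if (any(!is.finite(traj))) stop("trajectory contains non-finite values")
  D <- as.matrix(dist(traj, method = "euclidean"))
  dimnames(D) <- NULL
  attr(D, "metric") <- metric
  D
}

#' Recurrence plot of a raw series
#'
#' Convenience composition of [delay_embed()] and
#' [recurrence_distance_matrix()].
#'
#' @inheritParams delay_embed
#' @inheritParams recurrence_distance_matrix
#' @return An M x M distance matrix with `M = length(x) - (k-1)*tau`.
#' @export
recurrence_matrix <- function(x, k = 3L, tau = 1L, metric = "euclidean") {
  recurrence_distance_matrix(delay_embed(x, k = k, tau = tau), metric = metric)
}

#' Read a collection of time series from delimited text
#'
#' One series per row. The field separator is auto-detected (tab, comma,
#' then whitespace) unless given. With `label_col = TRUE` the first field of
#' each row is read as a class label, the dialect used by the UCR/UEA time
#' series classification archives. Rows may have different lengths.
#'
#' @param path Path to a delimited text file.
#' @param label_col Logical; is the first column a class label?
#' @param sep Field separator, or `NULL` to auto-detect.
#' @return A list with elements `series` (list of numeric vectors) and
#'   `labels` (character vector, or `NULL` when `label_col = FALSE`).
#' @export
read_series <- function(path, label_col = FALSE, sep = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no series found in ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[[1]])) "\t" else if (grepl(",", lines[[1]])) "," else "[[:space:]]+"
  }
  fields <- strsplit(trimws(lines), sep)
  labels <- NULL
  if (label_col) {
    labels <- vapply(fields, `[[`, character(1), 1L)
    fields <- lapply(fields, `[`, -1L)
  }
  series <- lapply(seq_along(fields), function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric value on line %d of %s", i, path))
    }
    v
  })
  list(series = series, labels = labels)
}

#' Write a collection of time series as delimited text
#'
#' Inverse of [read_series()]: one series per row at full (`%.17g`)
#' precision, with an optional leading label column.
#'
#' @param series List of numeric vectors (or a single vector).
#' @param path Output path.
#' @param labels Optional vector of class labels, one per series.
#' @param sep Field separator (default tab).
#' @export
write_series <- function(series, path, labels = NULL, sep = "\t") {
  if (is.numeric(series)) series <- list(series)
  lines <- vapply(seq_along(series), function(i) {
    row <- paste(fmt_full(series[[i]]), collapse = sep)
    if (!is.null(labels)) row <- paste(labels[[i]], row, sep = sep)
    row
  }, character(1))
  writeLines(lines, path)
}

#' Read/write a numeric matrix as delimited text at full precision
#'
#' Values are written with `%.17g` so that write-then-read round-trips
#' doubles exactly. Used for distance matrices, feature matrices, and NMF
#' factors.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `read_matrix_txt` returns a numeric matrix.
#' @export
write_matrix_txt <- function(m, path, sep = "\t") {
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(row) paste(fmt_full(row), collapse = sep))
  writeLines(lines, path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(lines, sep), as.numeric)
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("ragged rows in ", path)
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}
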