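#' Pipeline configuration
#'
#' Bundles every tunable of the four-stage pipeline (embed, persistence,
#' persistence image, NMF) with documented defaults. Configurations
#' round-trip exactly through [write_config()] / [read_config()].
#'
#' @param k Embedding dimension (default 3).
#' @param tau Embedding delay in samples (default 1).
#' @param resolution Persistence-image resolution `(nb, nd)`.
#' @param sigma Kernel bandwidth override (`NULL` = derive from cohort).
#' @param sigma_factor Bandwidth as a fraction of the cohort death span.
#' @param weight_mode PI weight evaluation, `"grid"` or `"point"`.
#' @param essential Essential-class handling in PIs, `"drop"` or `"cap"`.
#' @param rank NMF rank (default 2).
#' @param seed Integer seed for NMF initialization.
#' @param max_iter,tol NMF convergence controls.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(k = 3L, tau = 1L, resolution = c(64L, 64L),
                            sigma = NULL, sigma_factor = 0.05,
                            weight_mode = "grid", essential = "drop",
                            rank = 2L, seed = 1L, max_iter = 2000L,
                            tol = 1e-6) {
  structure(
    list(
      k = as.integer(k), tau = as.integer(tau),
      resolution = as.integer(resolution), sigma = sigma,
      sigma_factor = sigma_factor, weight_mode = weight_mode,
      essential = essential, rank = as.integer(rank),
      seed = as.integer(seed), max_iter = as.integer(max_iter), tol = tol
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full feature-extraction pipeline on a cohort
#'
#' For every series: delay-embed, build the recurrence distance matrix,
#' compute its H0 persistence diagram. All diagrams are then rasterized on
#' one shared cohort-wide grid (so the feature vectors live in a common
#' space) and the stacked feature matrix is reduced by NMF. When `train`
#' indices are given, the NMF basis is fit on the training rows only and
#' held-out rows are projected onto it with [nmf_transform()]; with binary
#' labels, per-component AUC and best-threshold accuracy are reported.
#'
#' @param series List of numeric vectors (or a single vector). Mixed
#'   lengths are allowed (diagrams and images are length-agnostic) but
#'   trigger a warning.
#' @param config A [pipeline_config()].
#' @param labels Optional class labels, one per series.
#' @param train Optional integer indices of the training subset.
#' @param output_dir Optional directory; when given, features, scores,
#'   model, config, and metrics are written there with full provenance.
#' @return List with `diagrams`, `grid`, `features` (N x nb*nd), `model`
#'   (`nmf_model`), `scores` (N x rank; training rows from the fit,
#'   held-out rows projected), `train`, `labels`, and `metrics` (data
#'   frame, or `NULL` without binary labels).
#' @examples
#' cohort <- make_labeled_cohort(c(sine = 4, logistic = 4), length = 80, seed = 1)
#' res <- run_pipeline(cohort$series, pipeline_config(resolution = c(16, 16)),
#'                     labels = cohort$labels)
#' @export
run_pipeline <- function(series, config = pipeline_config(), labels = NULL,
                         train = NULL, output_dir = NULL) {
  if (is.numeric(series)) series <- list(series)
  n <- length(series)
  if (n == 0L) stop("empty cohort")
  if (!is.null(labels) && length(labels) != n) {
    stop("labels must match the number of series")
  }
  if (length(unique(lengths(series))) > 1L) {
    warning("series have mixed lengths; diagrams remain comparable but sample sizes differ")
  }
  diagrams <- lapply(series, function(x) {
    persistence_h0(recurrence_matrix(x, k = config$k, tau = config$tau))
  })
  grid <- grid_from_diagrams(diagrams, resolution = config$resolution,
                             sigma = config$sigma,
                             sigma_factor = config$sigma_factor,
                             weight_mode = config$weight_mode)
  V <- pi_feature_matrix(diagrams, grid, essential = config$essential)

  fit_idx <- if (is.null(train)) seq_len(n) else sort(unique(as.integer(train)))
  rank <- config$rank
  max_rank <- min(length(fit_idx), ncol(V))
  if (rank > max_rank) {
    warning(sprintf("rank %d not supported by %d fitting sample(s); using rank %d",
                    rank, length(fit_idx), max_rank))
    rank <- max_rank
  }
  model <- nmf_fit(V[fit_idx, , drop = FALSE], rank = rank,
                   seed = config$seed, max_iter = config$max_iter,
                   tol = config$tol)
  scores <- matrix(NA_real_, n, rank)
  scores[fit_idx, ] <- model$P
  hold <- setdiff(seq_len(n), fit_idx)
  if (length(hold)) {
    scores[hold, ] <- nmf_transform(V[hold, , drop = FALSE], model)
  }
  colnames(scores) <- paste0("NMF", seq_len(rank))

  metrics <- NULL
  if (!is.null(labels) && length(unique(labels)) == 2L) {
    eval_idx <- if (length(hold)) hold else fit_idx
    metrics <- do.call(rbind, lapply(seq_len(rank), function(j) {
      bt <- best_threshold_accuracy(scores[eval_idx, j], labels[eval_idx])
      data.frame(
        component = paste0("NMF", j),
        auc = auc(scores[eval_idx, j], labels[eval_idx]),
        accuracy = bt$accuracy,
        threshold = bt$threshold,
        orientation = bt$orientation
      )
    }))
  }

  out <- list(diagrams = diagrams, grid = grid, features = V, model = model,
              scores = scores, train = fit_idx, labels = labels,
              metrics = metrics, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(V, file.path(output_dir, "features.tsv"), grid)
    write_matrix_txt(scores, file.path(output_dir, "scores.tsv"))
    write_nmf_model(model, file.path(output_dir, "nmf"))
    write_config(config, file.path(output_dir, "config.yaml"))
    if (!is.null(metrics)) write_metrics(metrics, file.path(output_dir, "metrics.tsv"))
    if (!is.null(labels)) writeLines(as.character(labels),
                                     file.path(output_dir, "labels.txt"))
  }
  out
}

#' Sweep the Chua bifurcation parameter and track NMF scores
#'
#' Simulates Chua's oscillator at every `beta` on a grid, runs the
#' recurrence-persistence pipeline on the resulting series, and factorizes
#' all persistence images with a single shared NMF (rank 4 by default) so
#' that component scores are comparable along the sweep. Transitions
#' between dynamical regimes (periodic windows, single- and double-scroll
#' chaos) appear as switches in which component dominates.
#'
#' @param beta_min,beta_max,step Sweep grid (inclusive endpoints).
#' @param series_length Samples per simulated series.
#' @param config A [pipeline_config()]; default rank 4.
#' @param ... Extra arguments passed to [simulate_chua()].
#' @return Object of class `beta_sweep`: list with `beta` (grid),
#'   `scores` (grid length x rank), `basis` (rank x nb*nd), `grid`
#'   (`pi_grid`), `model`, and `config`.
#' @export
beta_sweep <- function(beta_min = 30.0, beta_max = 32.0, step = 0.1,
                       series_length = 500L,
                       config = pipeline_config(rank = 4L), ...) {
  if (beta_min >= beta_max) stop("beta_min must be < beta_max")
  if (step <= 0) stop("step must be positive")
  betas <- seq(beta_min, beta_max, by = step)
  series <- lapply(betas, function(b) {
    tryCatch(
      simulate_chua(series_length, beta = b, ...),
      error = function(e) stop("simulation failed at beta = ", b, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  res <- run_pipeline(series, config = config)
  structure(
    list(beta = betas, scores = res$scores, basis = res$model$Q,
         grid = res$grid, model = res$model, config = config),
    class = "beta_sweep"
  )
}

#' Contiguous regime segments of a sweep
#'
#' Labels every sweep point by its dominant (largest-score) NMF component
#' and collapses runs of equal labels into segments; the boundary between
#' two segments is the midpoint of the adjacent `beta` values. This is a
#' minimal change-point reading of the score profile.
#'
#' @param sweep A `beta_sweep`.
#' @return List with `segments` (data frame: `component`, `beta_start`,
#'   `beta_end`) and `boundaries` (numeric vector of segment boundaries).
#' @export
regime_segments <- function(sweep) {
  lab <- apply(sweep$scores, 1L, which.max)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  segments <- data.frame(
    component = r$values,
    beta_start = sweep$beta[starts],
    beta_end = sweep$beta[ends]
  )
  boundaries <- if (length(ends) > 1L) {
    (sweep$beta[ends[-length(ends)]] + sweep$beta[ends[-length(ends)] + 1L]) / 2
  } else {
    numeric(0)
  }
  list(segments = segments, boundaries = boundaries)
}

#' @export
print.beta_sweep <- function(x, ...) {
  seg <- regime_segments(x)
  cat(sprintf("beta sweep: %d points in [%g, %g], rank %d, %d regime segment(s)\n",
              length(x$beta), min(x$beta), max(x$beta), ncol(x$scores),
              nrow(seg$segments)))
  print(seg$segments)
  invisible(x)
}
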