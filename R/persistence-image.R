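#' Persistence-image grid specification
#'
#' Defines the raster on which persistence diagrams are vectorized: the
#' birth/death ranges, the resolution, the Gaussian kernel bandwidth
#' `sigma`, and where the squared-lifetime weight `(d - b)^2` is evaluated.
#' With `weight_mode = "grid"` the weight is evaluated at the grid location
#' (clamped to 0 below the diagonal), following the closed-form definition
#' `PI(b, d) = w(b, d) * sum_i K(b_i - b, d_i - d)`; `"point"` evaluates
#' the weight at each diagram point `(b_i, d_i)` instead, the convention
#' most common in the persistence-image literature.
#'
#' @param birth_range,death_range Numeric `(min, max)` with `max > min`.
#' @param resolution Integer `(nb, nd)`, the number of cells per axis.
#' @param sigma Gaussian kernel bandwidth (> 0), in the units of the
#'   filtration values (distances).
#' @param weight_mode `"grid"` or `"point"` (see above).
#' @return An object of class `pi_grid`.
#' @export
pi_grid <- function(birth_range, death_range, resolution = c(64L, 64L),
                    sigma, weight_mode = c("grid", "point")) {
  weight_mode <- match.arg(weight_mode)
  resolution <- as.integer(resolution)
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  if (any(resolution < 1L)) stop("resolution must be >= 1 on both axes")
  if (diff(birth_range) <= 0 || diff(death_range) <= 0) {
    stop("grid ranges must satisfy max > min")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  structure(
    list(
      birth_range = as.numeric(birth_range),
      death_range = as.numeric(death_range),
      resolution = resolution,
      sigma = as.numeric(sigma),
      weight_mode = weight_mode
    ),
    class = "pi_grid"
  )
}

#' @export
print.pi_grid <- function(x, ...) {
  cat(sprintf(
    "persistence-image grid: %dx%d, birth [%g, %g], death [%g, %g], sigma %g, %s weight\n",
    x$resolution[1], x$resolution[2], x$birth_range[1], x$birth_range[2],
    x$death_range[1], x$death_range[2], x$sigma, x$weight_mode
  ))
  invisible(x)
}

# Cell centers along both axes.
pi_centers <- function(grid) {
  nb <- grid$resolution[1]
  nd <- grid$resolution[2]
  br <- grid$birth_range
  dr <- grid$death_range
  list(
    b = br[1] + (seq_len(nb) - 0.5) * diff(br) / nb,
    d = dr[1] + (seq_len(nd) - 0.5) * diff(dr) / nd
  )
}

#' Cell area of a persistence-image grid
#' @param grid A `pi_grid`.
#' @return Scalar area of one grid cell.
#' @export
pi_cell_area <- function(grid) {
  prod(diff(grid$birth_range), diff(grid$death_range)) /
    prod(grid$resolution)
}

#' Shared grid derived from a cohort of diagrams
#'
#' For features of different samples to live in one vector space (as the
#' downstream matrix factorization requires), every diagram must be
#' rasterized on the same grid. Both axes span `[0 - 3 sigma,
#' max_death + 3 sigma]`, where `max_death` is the largest finite death in
#' the cohort, so no kernel mass is clipped; by default `sigma` is 5% of
#' the death span (`sigma_factor * (max_death - min_birth)`).
#'
#' @param diagrams A `persistence_diagram` or a list of them; at least one
#'   must contain a finite pair.
#' @param resolution Integer `(nb, nd)`; default 64 x 64.
#' @param sigma Bandwidth override; when `NULL`, use the `sigma_factor`
#'   rule.
#' @param sigma_factor Fraction of the death span used for `sigma`.
#' @param weight_mode Passed to [pi_grid()].
#' @return A `pi_grid`.
#' @export
grid_from_diagrams <- function(diagrams, resolution = c(64L, 64L),
                               sigma = NULL, sigma_factor = 0.05,
                               weight_mode = c("grid", "point")) {
  weight_mode <- match.arg(weight_mode)
  if (inherits(diagrams, "persistence_diagram")) diagrams <- list(diagrams)
  pairs <- do.call(rbind, lapply(diagrams, function(d) d$pairs))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("all diagrams are empty; cannot derive a grid")
  }
  min_birth <- min(0, pairs[, 1])
  max_death <- max(pairs[, 2])
  if (is.null(sigma)) sigma <- sigma_factor * (max_death - min_birth)
  if (sigma <= 0) stop("derived sigma is not positive; supply sigma explicitly")
  lo <- min_birth - 3 * sigma
  hi <- max_death + 3 * sigma
  pi_grid(c(lo, hi), c(lo, hi), resolution = resolution, sigma = sigma,
          weight_mode = weight_mode)
}

#' Vectorize a persistence diagram as a persistence image
#'
#' Rasterizes the finite pairs of `diagram` on `grid`: each grid-cell
#' center `(b, d)` receives `w(b, d) * sum_i g(b_i - b, d_i - d)` where `g`
#' is the isotropic bivariate Gaussian density with bandwidth
#' `grid$sigma` (normalized to unit mass, prefactor `1/(2 pi sigma^2)`) and
#' the weight is the squared lifetime `(d - b)^2` — evaluated at the grid
#' cell (clamped to 0 below the diagonal) or at each diagram point,
#' according to `grid$weight_mode`. The output is additive over diagram
#' points, non-negative everywhere, and suppresses short-lived (near
#' diagonal) features, which is what makes it robust to small input
#' perturbations.
#'
#' Essential classes (infinite death) are dropped by default; with
#' `essential = "cap"` they are included as pairs dying at the source
#' image's maximum value (requires `diagram$max_value`).
#'
#' @param diagram A `persistence_diagram`.
#' @param grid A `pi_grid`.
#' @param essential `"drop"` or `"cap"`.
#' @return Numeric vector of length `nb * nd`, row-major over the grid
#'   (birth-major: the first `nd` entries are death cells at the first
#'   birth center), with attribute `grid`.
#' @examples
#' d <- persistence_h0(toy_recurrence_matrix())
#' g <- grid_from_diagrams(d, resolution = c(16, 16))
#' pi_vec <- persistence_image(d, g)
#' @export
persistence_image <- function(diagram, grid, essential = c("drop", "cap")) {
  essential <- match.arg(essential)
  stopifnot(inherits(grid, "pi_grid"))
  pairs <- diagram$pairs
  if (essential == "cap" && length(diagram$essential_births)) {
    if (is.na(diagram$max_value)) {
      stop("essential = \"cap\" requires diagram$max_value")
    }
    pairs <- rbind(pairs, cbind(diagram$essential_births, diagram$max_value))
  }
  nb <- grid$resolution[1]
  nd <- grid$resolution[2]
  ctr <- pi_centers(grid)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- numeric(nb * nd)
    attr(out, "grid") <- grid
    return(out)
  }
  s2 <- 2 * grid$sigma^2
  # Separable Gaussian: sum_i K = (Gb w_i) %*% Gd with blockwise products.
  Gb <- exp(-outer(ctr$b, pairs[, 1], "-")^2 / s2)  # nb x n
  Gd <- exp(-outer(ctr$d, pairs[, 2], "-")^2 / s2)  # nd x n
  if (grid$weight_mode == "point") {
    wpt <- (pairs[, 2] - pairs[, 1])^2
    img <- (Gb %*% (wpt * t(Gd))) / (2 * pi * grid$sigma^2)
  } else {
    img <- (Gb %*% t(Gd)) / (2 * pi * grid$sigma^2)
    wgrid <- outer(ctr$b, ctr$d, function(b, d) pmax(d - b, 0)^2)
    img <- img * wgrid
  }
  out <- as.vector(t(img))  # row-major: birth index varies slowest
  attr(out, "grid") <- grid
  out
}

#' Persistence-image feature matrix for a cohort of diagrams
#'
#' Applies [persistence_image()] to every diagram on one shared grid and
#' stacks the vectors as rows, the `V` matrix consumed by [nmf_fit()].
#'
#' @param diagrams List of `persistence_diagram` objects.
#' @param grid A shared `pi_grid` (e.g. from [grid_from_diagrams()]).
#' @param essential Passed to [persistence_image()].
#' @return N x (nb*nd) numeric matrix with attribute `grid`.
#' @export
pi_feature_matrix <- function(diagrams, grid, essential = "drop") {
  rows <- lapply(diagrams, persistence_image, grid = grid, essential = essential)
  V <- do.call(rbind, lapply(rows, as.numeric))
  attr(V, "grid") <- grid
  V
}

#' Write a feature matrix with its grid metadata sidecar
#'
#' The matrix goes to `path` as delimited text (one sample per row, full
#' precision) and the grid specification (ranges, resolution, sigma, weight
#' mode) to `<path>.meta.json`, so that vectors from different runs are
#' comparable only when their metadata agree.
#'
#' @param V Feature matrix with attribute `grid` (or pass `grid`).
#' @param path Output path.
#' @param grid Optional `pi_grid` overriding the attribute.
#' @return `read_feature_matrix` returns the matrix with its `grid`
#'   attribute restored.
#' @export
write_feature_matrix <- function(V, path, grid = attr(V, "grid")) {
  write_matrix_txt(V, path)
  if (!is.null(grid)) {
    meta <- list(
      birth_range = grid$birth_range, death_range = grid$death_range,
      resolution = grid$resolution, sigma = grid$sigma,
      weight_mode = grid$weight_mode
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  V <- read_matrix_txt(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(V, "grid") <- pi_grid(meta$birth_range, meta$death_range,
                               meta$resolution, meta$sigma, meta$weight_mode)
  }
  V
}
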