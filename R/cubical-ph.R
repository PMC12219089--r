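#' Connected components of a sublevel set (flood-fill oracle)
#'
#' Counts the connected components of the set of pixels with value `<= r`
#' under V-construction adjacency (pixels connect only when they share an
#' edge; corner contact does not connect). This is a direct breadth-first
#' flood fill, deliberately independent of the union-find reduction in
#' [persistence_h0()], and is kept in the package as the brute-force oracle
#' against which the persistence computation is validated.
#'
#' @param image Numeric matrix (grayscale image), all values finite.
#' @param r Threshold; the sublevel set is `{(i,j) : image[i,j] <= r}`.
#' @return Integer number of connected components (0 for an empty set).
#' @examples
#' sublevel_betti0(toy_recurrence_matrix(), 2)
#' @export
sublevel_betti0 <- function(image, r) {
  image <- as.matrix(image)
  H <- nrow(image)
  W <- ncol(image)
  mask <- image <= r
  if (!any(mask)) return(0L)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          a <- p[1] + d[1]
          b <- p[2] + d[2]
          if (a >= 1L && a <= H && b >= 1L && b <= W &&
              mask[a, b] && !seen[a, b]) {
            seen[a, b] <- TRUE
            queue[[length(queue) + 1L]] <- c(a, b)
          }
        }
      }
    }
  }
  count
}

new_persistence_diagram <- function(pairs, essential_births,
                                    birth_locations = NULL,
                                    essential_locations = NULL,
                                    max_value = NA_real_) {
  pairs <- matrix(as.numeric(pairs), ncol = 2,
                  dimnames = list(NULL, c("birth", "death")))
  structure(
    list(
      pairs = pairs,
      essential_births = as.numeric(essential_births),
      birth_locations = birth_locations,
      essential_locations = essential_locations,
      max_value = max_value
    ),
    class = "persistence_diagram"
  )
}

#' Construct a persistence diagram object
#'
#' Container for the output of 0-dimensional persistence: a multiset of
#' finite (birth, death) pairs and the births of essential classes
#' (connected components of the full image, which never die).
#'
#' @param pairs Two-column numeric matrix of finite (birth, death) pairs.
#' @param essential_births Numeric vector of essential birth values.
#' @param max_value Largest pixel value of the source image (used when
#'   capping essential classes for vectorization); may be `NA`.
#' @return An object of class `persistence_diagram`.
#' @export
persistence_diagram <- function(pairs = matrix(numeric(0), ncol = 2),
                                essential_births = numeric(0),
                                max_value = NA_real_) {
  if (length(pairs) && any(pairs[, 2] < pairs[, 1])) {
    stop("death < birth in persistence pairs")
  }
  new_persistence_diagram(pairs, essential_births, max_value = max_value)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf(
    "persistence diagram (H0): %d finite pair(s), %d essential class(es)\n",
    nrow(x$pairs), length(x$essential_births)
  ))
  if (nrow(x$pairs)) {
    print(utils::head(x$pairs, 10))
    if (nrow(x$pairs) > 10) cat(sprintf("... %d more\n", nrow(x$pairs) - 10))
  }
  if (length(x$essential_births)) {
    cat("essential births:", paste(signif(x$essential_births, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' 0-dimensional persistent homology of a grayscale image
#'
#' Computes the H0 persistence diagram of the sublevel filtration
#' `S(r) = {(i,j) : image[i,j] <= r}` on the cubical complex with
#' V-construction (edge, 4-neighbour) adjacency. Pixels are activated in
#' ascending (value, row-major index) order and merged by union-find: a
#' component is born at the value of its first (minimal) pixel, and when two
#' components meet at value `v` the one with the larger birth dies at `v`
#' (elder rule; ties on birth are broken by earlier activation surviving).
#' Components that survive the whole sweep are reported as essential
#' classes. Births mark local minima of the image and deaths mark the
#' saddles at which components are absorbed.
#'
#' @param image Numeric matrix, all values finite.
#' @param keep_zero_persistence Keep pairs with `death == birth`? These
#'   arise from plateaus of equal-valued pixels, carry zero weight in any
#'   lifetime-weighted vectorization, and are discarded by default.
#' @return A `persistence_diagram` with components `pairs` (finite
#'   birth/death matrix), `essential_births`, `birth_locations` (1-based
#'   (row, col) of each dying component's minimal pixel),
#'   `essential_locations`, and `max_value`.
#' @examples
#' persistence_h0(toy_recurrence_matrix())
#' @export
persistence_h0 <- function(image, keep_zero_persistence = FALSE) {
  image <- as.matrix(image)
  if (!is.numeric(image) || any(!is.finite(image))) {
    stop("image must be a finite numeric matrix")
  }
  res <- ph0_cubical(image)
  pairs <- res$pairs
  locs <- res$locations
  if (!keep_zero_persistence && nrow(pairs)) {
    keep <- pairs[, 2] > pairs[, 1]
    pairs <- pairs[keep, , drop = FALSE]
    locs <- locs[keep, , drop = FALSE]
  }
  new_persistence_diagram(
    pairs, res$essential,
    birth_locations = locs,
    essential_locations = res$essential_locations,
    max_value = max(image)
  )
}

#' Betti-0 curve implied by a persistence diagram
#'
#' Number of components alive at threshold `r`: finite pairs with
#' `birth <= r < death` plus essential classes with `birth <= r`. For a
#' correct diagram this equals [sublevel_betti0()] at every `r`.
#'
#' @param diagram A `persistence_diagram`.
#' @param r Threshold value.
#' @return Integer component count.
#' @export
pd_betti0 <- function(diagram, r) {
  p <- diagram$pairs
  sum(p[, 1] <= r & r < p[, 2]) + sum(diagram$essential_births <= r)
}

#' A hand-traceable 5x5 example matrix
#'
#' A small synthetic distance-like matrix (symmetric, zero diagonal)
#' constructed so that its sublevel filtration can be followed by hand:
#' the five diagonal zeros give five components at r = 0; two pairs of them
#' merge through value-1 cells at r = 1 while two new components are born
#' in opposite corners; one merge happens at r = 2; at r = 3 the image is
#' fully connected. Its H0 diagram is the multiset
#' \{(0,1), (0,1), (0,2), (0,3), (1,3), (1,3)\} plus one essential class
#' born at 0. Used throughout the documentation and tests.
#'
#' @return A 5x5 numeric matrix.
#' @examples
#' persistence_h0(toy_recurrence_matrix())
#' @export
toy_recurrence_matrix <- function() {
  matrix(c(
    0, 1, 3, 3, 1,
    1, 0, 2, 3, 3,
    3, 2, 0, 1, 3,
    3, 3, 1, 0, 3,
    1, 3, 3, 3, 0
  ), nrow = 5, byrow = TRUE)
}

#' Write / read a persistence diagram as delimited text
#'
#' Plain-text interchange with columns `dim,birth,death` (dim is always 0
#' here); essential classes are rows whose death field is the literal token
#' `inf`. Values are written at full precision so the round-trip is exact.
#'
#' @param diagram A `persistence_diagram`.
#' @param path File path.
#' @return `read_pd` returns a `persistence_diagram` (without pixel
#'   locations, which are not serialized).
#' @export
write_pd <- function(diagram, path) {
  p <- diagram$pairs
  lines <- c(
    "dim,birth,death",
    if (nrow(p)) sprintf("0,%s,%s", fmt_full(p[, 1]), fmt_full(p[, 2])),
    if (length(diagram$essential_births)) {
      sprintf("0,%s,inf", fmt_full(diagram$essential_births))
    }
  )
  writeLines(lines, path)
}

#' @rdname write_pd
#' @export
read_pd <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[[1]] != "dim,birth,death") {
    stop("malformed persistence diagram file ", path, ": missing header (line 1)")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  births <- deaths <- numeric(0)
  essential <- numeric(0)
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], ",")[[1]]
    if (length(f) != 3L) {
      stop(sprintf("malformed persistence diagram file %s: expected 3 fields on line %d",
                   path, i + 1L))
    }
    b <- suppressWarnings(as.numeric(f[2]))
    if (is.na(b)) {
      stop(sprintf("malformed persistence diagram file %s: bad birth on line %d",
                   path, i + 1L))
    }
    if (identical(f[3], "inf")) {
      essential <- c(essential, b)
    } else {
      d <- suppressWarnings(as.numeric(f[3]))
      if (is.na(d)) {
        stop(sprintf("malformed persistence diagram file %s: bad death on line %d",
                     path, i + 1L))
      }
      births <- c(births, b)
      deaths <- c(deaths, d)
    }
  }
  new_persistence_diagram(cbind(births, deaths), essential)
}
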