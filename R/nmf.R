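#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative sample-by-feature matrix `V` (N x D) as
#' `V ~ P Q` with `P` (N x rank) the per-sample scores and `Q` (rank x D)
#' the non-negative basis, minimizing the Frobenius norm `||V - P Q||` by
#' Lee-Seung multiplicative updates. Each update multiplies a factor
#' entrywise by a non-negative ratio, so non-negativity is preserved and
#' the objective is non-increasing at every iteration.
#'
#' Components are reordered by descending Euclidean norm of the rows of `Q`
#' before returning, so that component 1 is always the dominant basis;
#' without this the column order of an NMF is arbitrary.
#'
#' @param V Non-negative numeric matrix (rows = samples).
#' @param rank Number of components, `<= min(dim(V))`.
#' @param seed Integer seed for the random initialization; fits are
#'   bitwise reproducible for a fixed seed. The caller's RNG state is left
#'   untouched.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Stop when the relative improvement of the Frobenius error
#'   between sweeps falls below this.
#' @param init `"random"` (entries uniform, scaled to the data magnitude)
#'   or `"nndsvd"` (SVD-based deterministic seeding).
#' @return An object of class `nmf_model` with elements `P`, `Q`, `rank`,
#'   `error_trace` (Frobenius error before the first and after every
#'   sweep), `seed`, `n_iter`, `init`.
#' @examples
#' V <- outer(runif(20), runif(30))
#' fit <- nmf_fit(V, rank = 1, seed = 1)
#' @export
nmf_fit <- function(V, rank, seed = 1L, max_iter = 2000L, tol = 1e-6,
                    init = c("random", "nndsvd")) {
  init <- match.arg(init)
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("V must be finite")
  if (any(V < 0)) stop("V must be non-negative")
  N <- nrow(V)
  D <- ncol(V)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(N, D)) {
    stop(sprintf("rank must be in 1..min(N, D) = 1..%d, got %d", min(N, D), rank))
  }
  if (init == "random") {
    scale <- sqrt(max(mean(V), .Machine$double.eps) / rank)
    fac <- with_seed(seed, list(
      P = matrix(runif(N * rank), N, rank) * scale,
      Q = matrix(runif(rank * D), rank, D) * scale
    ))
    P <- fac$P
    Q <- fac$Q
  } else {
    fac <- nndsvd_init(V, rank)
    P <- fac$P
    Q <- fac$Q
  }
  eps <- .Machine$double.eps
  err <- norm(V - P %*% Q, "F")
  trace <- err
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    P <- P * (V %*% t(Q)) / (P %*% (Q %*% t(Q)) + eps)
    Q <- Q * (t(P) %*% V) / (crossprod(P) %*% Q + eps)
    new_err <- norm(V - P %*% Q, "F")
    trace <- c(trace, new_err)
    n_iter <- it
    if (err > 0 && (err - new_err) / err < tol) {
      err <- new_err
      break
    }
    err <- new_err
  }
  ord <- order(sqrt(rowSums(Q^2)), decreasing = TRUE)
  structure(
    list(
      P = P[, ord, drop = FALSE],
      Q = Q[ord, , drop = FALSE],
      rank = rank,
      error_trace = trace,
      seed = as.integer(seed),
      n_iter = n_iter,
      init = init
    ),
    class = "nmf_model"
  )
}

# SVD-based deterministic NMF seeding: split each singular vector pair into
# its positive and negative parts and keep the dominant one.
nndsvd_init <- function(V, rank) {
  sv <- svd(V, nu = rank, nv = rank)
  P <- matrix(0, nrow(V), rank)
  Q <- matrix(0, rank, ncol(V))
  P[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  Q[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (rank > 1) {
    for (k in 2:rank) {
      u <- sv$u[, k]
      v <- sv$v[, k]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      pnorm <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nnorm <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (pnorm >= nnorm && pnorm > 0) {
        P[, k] <- sqrt(sv$d[k] * pnorm) * up / sqrt(sum(up^2))
        Q[k, ] <- sqrt(sv$d[k] * pnorm) * vp / sqrt(sum(vp^2))
      } else if (nnorm > 0) {
        P[, k] <- sqrt(sv$d[k] * nnorm) * un / sqrt(sum(un^2))
        Q[k, ] <- sqrt(sv$d[k] * nnorm) * vn / sqrt(sum(vn^2))
      }
    }
  }
  mean_pos <- mean(V[V > 0])
  if (!is.finite(mean_pos)) mean_pos <- 1
  P[P == 0] <- mean_pos * 1e-4
  Q[Q == 0] <- mean_pos * 1e-4
  list(P = P, Q = Q)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf(
    "NMF model: rank %d, %d x %d, %d iteration(s), final Frobenius error %.6g\n",
    x$rank, nrow(x$P), ncol(x$Q), x$n_iter,
    x$error_trace[length(x$error_trace)]
  ))
  invisible(x)
}

#' Project new samples onto a fitted NMF basis
#'
#' Computes non-negative scores `P_new` minimizing `||V_new - P_new Q||`
#' with the basis `Q` held fixed, by the multiplicative update restricted
#' to `P` from a deterministic positive initialization. This is how scores
#' for held-out samples are obtained from a basis learned on training data.
#'
#' @param V_new Non-negative matrix with the same number of columns as the
#'   model's basis.
#' @param model An `nmf_model`.
#' @param max_iter,tol Convergence controls for the restricted update.
#' @return Non-negative score matrix, `nrow(V_new)` x `model$rank`.
#' @export
nmf_transform <- function(V_new, model, max_iter = 1000L, tol = 1e-9) {
  V_new <- as.matrix(V_new)
  if (ncol(V_new) != ncol(model$Q)) {
    stop(sprintf("V_new has %d columns but the basis has %d",
                 ncol(V_new), ncol(model$Q)))
  }
  if (any(V_new < 0)) stop("V_new must be non-negative")
  Q <- model$Q
  eps <- .Machine$double.eps
  scale <- max(mean(V_new), eps) / max(mean(Q), eps) / model$rank
  P <- matrix(scale, nrow(V_new), model$rank)
  QQt <- Q %*% t(Q)
  VQt <- V_new %*% t(Q)
  err <- norm(V_new - P %*% Q, "F")
  for (it in seq_len(max_iter)) {
    P <- P * VQt / (P %*% QQt + eps)
    new_err <- norm(V_new - P %*% Q, "F")
    if (err > 0 && (err - new_err) / err < tol) break
    err <- new_err
  }
  P
}

#' Resolve NMF scale indeterminacy
#'
#' Rescales each basis row of `Q` to unit Euclidean norm and compensates
#' the corresponding score column of `P`, leaving the product `P Q`
#' unchanged. Zero-norm components are left untouched.
#'
#' @param model An `nmf_model`.
#' @return The model with normalized factors.
#' @export
nmf_normalize <- function(model) {
  s <- sqrt(rowSums(model$Q^2))
  s[s == 0] <- 1
  model$Q <- model$Q / s
  model$P <- sweep(model$P, 2L, s, "*")
  model
}

#' Write / read an NMF model as delimited text
#'
#' Factors `P` and `Q` go to `P.tsv` / `Q.tsv` in `dir` at full precision
#' and the fit metadata (rank, seed, iterations, error trace, init) to
#' `meta.json`; the round-trip is exact.
#'
#' @param model An `nmf_model`.
#' @param dir Directory (created if missing).
#' @return `read_nmf_model` returns an `nmf_model`.
#' @export
write_nmf_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_txt(model$P, file.path(dir, "P.tsv"))
  write_matrix_txt(model$Q, file.path(dir, "Q.tsv"))
  meta <- list(
    rank = model$rank, seed = model$seed, n_iter = model$n_iter,
    init = model$init, error_trace = model$error_trace
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_nmf_model
#' @export
read_nmf_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(
    list(
      P = read_matrix_txt(file.path(dir, "P.tsv")),
      Q = read_matrix_txt(file.path(dir, "Q.tsv")),
      rank = as.integer(meta$rank),
      error_trace = meta$error_trace,
      seed = as.integer(meta$seed),
      n_iter = as.integer(meta$n_iter),
      init = meta$init
    ),
    class = "nmf_model"
  )
}
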