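#' Piecewise-linear nonlinearity of Chua's circuit
#'
#' `h(x) = m1 x + (m0 - m1)(|x + 1| - |x - 1|) / 2`: slope `m0` in the
#' inner region `|x| <= 1` and slope `m1` outside. Odd in `x`.
#'
#' @param x Numeric vector.
#' @param m0 Inner slope.
#' @param m1 Outer slope.
#' @return `h(x)`, vectorized over `x`.
#' @export
chua_nonlinearity <- function(x, m0 = -8 / 7, m1 = -5 / 7) {
  m1 * x + 0.5 * (m0 - m1) * (abs(x + 1) - abs(x - 1))
}

#' Simulate Chua's oscillator
#'
#' Integrates the dimensionless Chua circuit
#' \deqn{\dot x = \alpha (y - x - h(x)), \quad \dot y = x - y + z, \quad
#'   \dot z = -\beta y,}
#' where `h` is the piecewise-linear diode characteristic
#' [chua_nonlinearity()],
#' with fixed-step classical 4th-order Runge-Kutta, discards an initial
#' transient, and returns `n` samples of `x` spaced `sample_interval` time
#' units apart. With `alpha = 15.6`, `m0 = -8/7`, `m1 = -5/7` the system
#' passes through alternating periodic and chaotic regimes as `beta` moves
#' through roughly [30, 32], which is the sweep explored by
#' [beta_sweep()]. The simulation is fully deterministic given its
#' arguments.
#'
#' @param n Number of retained samples.
#' @param beta Bifurcation parameter.
#' @param alpha,m0,m1 Remaining circuit parameters.
#' @param dt Integration step (time units); `sample_interval` must be an
#'   integer multiple of it.
#' @param sample_interval Time units between retained samples (default 1,
#'   i.e. unit-time sampling).
#' @param transient Time units discarded before sampling starts.
#' @param init Initial state `(x, y, z)`. The origin is an equilibrium, so
#'   a small offset is used by default.
#' @param full_state Return the full `(x, y, z)` matrix instead of `x`?
#' @return Numeric vector of length `n` (or an `n` x 3 matrix).
#' @examples
#' x <- simulate_chua(100, beta = 30.0)
#' @export
simulate_chua <- function(n = 1000L, beta = 30.0, alpha = 15.6,
                          m0 = -8 / 7, m1 = -5 / 7, dt = 0.01,
                          sample_interval = 1.0, transient = 500,
                          init = c(0.1, 0, 0), full_state = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  keep_every <- round(sample_interval / dt)
  if (keep_every < 1L || abs(keep_every * dt - sample_interval) > 1e-9) {
    stop("sample_interval must be a positive integer multiple of dt")
  }
  skip <- round(transient / dt)
  out <- chua_rk4(as.numeric(init), alpha, beta, m0, m1, dt,
                  as.integer(skip), as.integer(keep_every), n)
  if (full_state) out else out[, 1]
}

#' Iterate the logistic map
#'
#' Returns `n` values starting at `x0` under `x <- r x (1 - x)`. At
#' `r = 4` the map is chaotic on (0, 1); lower `r` gives fixed points and
#' periodic windows.
#'
#' @param r Map parameter.
#' @param x0 Initial value in (0, 1).
#' @param n Number of values returned (including `x0`).
#' @return Numeric vector of length `n`.
#' @export
simulate_logistic <- function(r, x0, n) {
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly in (0, 1)")
  n <- as.integer(n)
  x <- numeric(n)
  x[1] <- x0
  for (i in seq_len(n - 1L)) x[i + 1L] <- r * x[i] * (1 - x[i])
  x
}

#' Largest autocorrelation beyond lag zero
#'
#' The maximum of the sample autocorrelation over lags `1..lag.max`. Used
#' as a cheap deterministic periodicity criterion: sampled periodic orbits
#' show a peak near 1 at (a multiple of) their period, chaotic orbits do
#' not.
#'
#' @param x Numeric series.
#' @param lag.max Largest lag examined.
#' @return Scalar in [-1, 1].
#' @export
max_autocorrelation <- function(x, lag.max = 500L) {
  lag.max <- min(as.integer(lag.max), length(x) - 2L)
  a <- acf(x, lag.max = lag.max, plot = FALSE, demean = TRUE)$acf[-1]
  max(a)
}

#' Label a series periodic or chaotic by its autocorrelation
#'
#' @inheritParams max_autocorrelation
#' @param threshold Autocorrelation above which the series is called
#'   periodic.
#' @return `"periodic"` or `"chaotic"`.
#' @export
classify_regime <- function(x, lag.max = 500L, threshold = 0.95) {
  if (max_autocorrelation(x, lag.max) > threshold) "periodic" else "chaotic"
}

#' Generate a labeled synthetic cohort of time series
#'
#' Reproducible mixtures of three elementary signal classes, used to
#' exercise the full pipeline without external data:
#' \describe{
#'   \item{`sine`}{unit-amplitude sinusoid of period `sine_period` samples
#'     with a random phase plus Gaussian noise of sd `noise_sd` (a periodic
#'     signal with measurement noise);}
#'   \item{`logistic`}{the chaotic logistic map at r = 4 from a random
#'     initial point;}
#'   \item{`noise`}{white Gaussian noise (sd 1).}
#' }
#'
#' @param spec Named integer vector of class sizes, e.g.
#'   `c(sine = 20, logistic = 20)`. Names must come from the vocabulary
#'   above.
#' @param length Length of every series.
#' @param seed Integer seed; cohorts are bitwise reproducible. The
#'   caller's RNG state is untouched.
#' @param noise_sd Noise level of the sine class.
#' @param sine_period Period of the sine class, in samples.
#' @return List with `series` (list of numeric vectors) and `labels`
#'   (character vector).
#' @examples
#' cohort <- make_labeled_cohort(c(sine = 5, logistic = 5), length = 100, seed = 1)
#' @export
make_labeled_cohort <- function(spec, length = 200L, seed = 1L,
                                noise_sd = 0.05, sine_period = 20) {
  known <- c("sine", "logistic", "noise")
  if (is.null(names(spec)) || !all(names(spec) %in% known)) {
    stop("unknown generator name; available: ", paste(known, collapse = ", "))
  }
  if (any(spec < 1)) stop("class sizes must be >= 1")
  length <- as.integer(length)
  with_seed(seed, {
    series <- list()
    labels <- character(0)
    for (cls in names(spec)) {
      for (i in seq_len(spec[[cls]])) {
        s <- switch(cls,
          sine = {
            phase <- runif(1, 0, 2 * pi)
            sin(2 * pi * seq_len(length) / sine_period + phase) +
              rnorm(length, sd = noise_sd)
          },
          logistic = simulate_logistic(4, runif(1, 0.2, 0.8), length),
          noise = rnorm(length)
        )
        series[[base::length(series) + 1L]] <- s
        labels <- c(labels, cls)
      }
    }
    list(series = series, labels = labels)
  })
}
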