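test_that("the diode characteristic matches its closed forms and is odd", {
  m0 <- -8 / 7
  m1 <- -5 / 7
  expect_equal(chua_nonlinearity(0, m0, m1), 0)
  expect_equal(chua_nonlinearity(1, m0, m1), m0)       # inner slope
  expect_equal(chua_nonlinearity(10, m0, m1), -53 / 7) # outer closed form
  x <- seq(-5, 5, by = 0.37)
  expect_equal(chua_nonlinearity(-x, m0, m1), -chua_nonlinearity(x, m0, m1))
})

test_that("the origin is an equilibrium of the circuit", {
  expect_equal(simulate_chua(50, beta = 31, init = c(0, 0, 0)), rep(0, 50))
})

test_that("the integrator matches deSolve's fixed-step RK4 on the same grid", {
  rhs <- function(t, s, p) {
    list(c(15.6 * (s[2] - s[1] - chua_nonlinearity(s[1])),
           s[1] - s[2] + s[3],
           -30 * s[2]))
  }
  ref <- deSolve::ode(c(x = 0.1, y = 0, z = 0), seq(0, 10, by = 0.01), rhs,
                      NULL, method = "rk4")
  mine <- simulate_chua(1001, beta = 30, dt = 0.01, sample_interval = 0.01,
                        transient = 0)
  expect_lt(max(abs(ref[, "x"] - mine)), 1e-12)
})

test_that("halving the step leaves short-horizon trajectories unchanged to 4th order", {
  a <- simulate_chua(101, beta = 30, dt = 0.01, sample_interval = 0.05, transient = 0)
  b <- simulate_chua(101, beta = 30, dt = 0.005, sample_interval = 0.05, transient = 0)
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-4)
})

test_that("trajectories stay bounded across the studied beta range", {
  for (beta in seq(30, 32, by = 0.1)) {
    x <- simulate_chua(100, beta = beta)
    expect_lt(max(abs(x)), 10)
  }
})

test_that("autocorrelation separates periodic from chaotic regimes", {
  x_per <- simulate_chua(1000, beta = 30.0)
  expect_gt(max_autocorrelation(x_per, 500), 0.95)
  expect_identical(classify_regime(x_per), "periodic")
  x_cha <- simulate_chua(1000, beta = 31.8)
  expect_lt(max_autocorrelation(x_cha, 500), 0.95)
  expect_identical(classify_regime(x_cha), "chaotic")
})

test_that("integration failures and bad sampling parameters are reported", {
  expect_error(simulate_chua(10, beta = 30, sample_interval = 0.015, dt = 0.01),
               "integer multiple")
  expect_error(simulate_chua(10, beta = 30, dt = -0.1), "dt")
  # an expansive outer slope drives the trajectory to infinity, error names dt
  expect_error(simulate_chua(100, beta = 30, m1 = -5), "diverged.*dt = 0.01")
  # so does a step far beyond the RK4 stability region
  expect_error(simulate_chua(100, beta = 30, dt = 1, sample_interval = 1),
               "diverged")
})

test_that("logistic iterates follow their closed-form behaviour", {
  expect_equal(simulate_logistic(4, 0.5, 5), c(0.5, 1, 0, 0, 0))
  # period-2 window at r = 3.2
  x <- simulate_logistic(3.2, 0.3, 600)
  expect_lt(abs(x[600] - x[598]), 1e-6)
  expect_gt(abs(x[600] - x[599]), 0.1)
  # fixed point 1 - 1/r at r = 2.5
  expect_equal(simulate_logistic(2.5, 0.3, 500)[500], 0.6, tolerance = 1e-6)
  expect_error(simulate_logistic(4, 1.5, 10), "x0")
})

test_that("labeled cohorts are reproducible, labeled, and reject unknown generators", {
  c1 <- make_labeled_cohort(c(sine = 5, logistic = 5, noise = 3), length = 120, seed = 7)
  c2 <- make_labeled_cohort(c(sine = 5, logistic = 5, noise = 3), length = 120, seed = 7)
  expect_identical(c1, c2)
  expect_identical(c1$labels,
                   rep(c("sine", "logistic", "noise"), times = c(5, 5, 3)))
  expect_true(all(lengths(c1$series) == 120))
  expect_false(identical(
    c1$series[[1]],
    make_labeled_cohort(c(sine = 5, logistic = 5, noise = 3), 120, seed = 8)$series[[1]]
  ))
  expect_error(make_labeled_cohort(c(square = 3)), "unknown generator")
})

test_that("a noise-free sine gives an exactly periodic recurrence plot", {
  co <- make_labeled_cohort(c(sine = 1), length = 100, seed = 2, noise_sd = 0,
                            sine_period = 20)
  D <- recurrence_matrix(co$series[[1]], k = 3)
  P <- 20
  n <- nrow(D)
  expect_lt(max(abs(D[1:(n - P), 1:(n - P)] - D[(P + 1):n, (P + 1):n])), 1e-9)
})
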