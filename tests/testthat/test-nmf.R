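test_that("an exact rank-1 matrix is recovered almost perfectly", {
  set.seed(30)
  V <- outer(abs(rnorm(30)), abs(rnorm(50)))
  fit <- nmf_fit(V, rank = 1, seed = 1, max_iter = 500)
  expect_lt(norm(V - fit$P %*% fit$Q, "F") / norm(V, "F"), 1e-3)
})

test_that("factors stay non-negative and the error trace never increases", {
  set.seed(31)
  for (trial in 1:5) {
    V <- matrix(abs(rnorm(40 * 25)), 40, 25)
    fit <- nmf_fit(V, rank = sample(2:4, 1), seed = trial, max_iter = 200)
    expect_true(all(fit$P >= 0) && all(fit$Q >= 0))
    expect_true(all(diff(fit$error_trace) <= 1e-10 * (1 + fit$error_trace[1])))
  }
})

test_that("fits are bitwise reproducible for a fixed seed and leave the RNG alone", {
  V <- matrix(abs(sin(1:600)), 30, 20)
  set.seed(123)
  reference <- rnorm(5)
  set.seed(123)
  rnorm(2)
  f1 <- nmf_fit(V, rank = 3, seed = 42, max_iter = 50)
  after <- rnorm(3)
  f2 <- nmf_fit(V, rank = 3, seed = 42, max_iter = 50)
  expect_identical(f1$P, f2$P)
  expect_identical(f1$Q, f2$Q)
  expect_identical(after, reference[3:5])  # caller RNG stream untouched
  expect_false(identical(f1$P, nmf_fit(V, rank = 3, seed = 43, max_iter = 50)$P))
})

test_that("basis components come out ordered by descending basis norm", {
  set.seed(32)
  V <- matrix(abs(rnorm(50 * 30)), 50, 30)
  fit <- nmf_fit(V, rank = 4, seed = 2, max_iter = 300)
  norms <- sqrt(rowSums(fit$Q^2))
  expect_true(all(diff(norms) <= 0))
})

test_that("renormalizing the basis compensates the scores without changing the product", {
  set.seed(33)
  V <- matrix(abs(rnorm(20 * 15)), 20, 15)
  fit <- nmf_fit(V, rank = 3, seed = 1, max_iter = 100)
  nrm <- nmf_normalize(fit)
  expect_equal(sqrt(rowSums(nrm$Q^2)), rep(1, 3))
  expect_equal(nrm$P %*% nrm$Q, fit$P %*% fit$Q)
})

test_that("a planted rank-3 factorization is recovered within 5% Frobenius error", {
  set.seed(34)
  P0 <- matrix(abs(rnorm(200 * 3)), 200, 3)
  Q0 <- matrix(abs(rnorm(3 * 256)), 3, 256)
  V <- P0 %*% Q0
  fit <- nmf_fit(V, rank = 3, seed = 5)
  expect_lt(norm(V - fit$P %*% fit$Q, "F") / norm(V, "F"), 0.05)
})

test_that("transforming the training data reproduces the fitted scores", {
  set.seed(35)
  V <- matrix(abs(rnorm(60 * 40)), 60, 40) + outer(abs(rnorm(60)), abs(rnorm(40)))
  fit <- nmf_fit(V, rank = 2, seed = 3, max_iter = 10000, tol = 1e-12)
  P_new <- nmf_transform(V, fit, max_iter = 5000, tol = 1e-13)
  expect_lt(norm(P_new - fit$P, "F") / norm(fit$P, "F"), 0.01)
})

test_that("transform maps zero rows to zero scores and checks shapes", {
  set.seed(36)
  V <- matrix(abs(rnorm(30 * 20)), 30, 20)
  fit <- nmf_fit(V, rank = 2, seed = 1, max_iter = 100)
  z <- nmf_transform(matrix(0, 1, 20), fit)
  expect_equal(as.numeric(z), c(0, 0))
  expect_error(nmf_transform(matrix(1, 2, 19), fit), "19")
})

test_that("scores of new samples generated from the same basis are recovered", {
  set.seed(37)
  P0 <- matrix(abs(rnorm(120 * 3)), 120, 3)
  Q0 <- matrix(abs(rnorm(3 * 80)), 3, 80)
  fit <- nmf_fit(P0 %*% Q0, rank = 3, seed = 9)
  P0_new <- matrix(abs(rnorm(40 * 3)), 40, 3)
  P_new <- nmf_transform(P0_new %*% Q0, fit)
  for (j in 1:3) {
    expect_gt(max(abs(cor(P0_new[, j], P_new))), 0.95)
  }
})

test_that("invalid factorization requests fail loudly", {
  V <- matrix(abs(rnorm(20)), 4, 5)
  expect_error(nmf_fit(V, rank = 5), "rank")
  expect_error(nmf_fit(-V, rank = 2), "non-negative")
  expect_error(nmf_fit(V * NA, rank = 2), "finite")
})

test_that("NNDSVD initialization is deterministic and competitive", {
  set.seed(38)
  V <- matrix(abs(rnorm(40 * 30)), 40, 30)
  f1 <- nmf_fit(V, rank = 3, init = "nndsvd", max_iter = 200)
  f2 <- nmf_fit(V, rank = 3, init = "nndsvd", max_iter = 200)
  expect_identical(f1$P, f2$P)
  expect_true(all(f1$P >= 0) && all(f1$Q >= 0))
})

test_that("models round-trip through their on-disk representation", {
  tmp <- withr::local_tempdir()
  V <- matrix(abs(sin(1:200)), 20, 10)
  fit <- nmf_fit(V, rank = 2, seed = 4, max_iter = 60)
  write_nmf_model(fit, tmp)
  got <- read_nmf_model(tmp)
  expect_identical(got$P, fit$P)
  expect_identical(got$Q, fit$Q)
  expect_identical(got$rank, fit$rank)
  expect_equal(got$error_trace, fit$error_trace)
})
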