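grid16 <- pi_grid(c(-0.5, 1.5), c(-0.5, 1.5), c(16, 16), sigma = 0.1)

test_that("an empty diagram maps to the zero vector, not an error", {
  v <- persistence_image(persistence_diagram(), grid16)
  expect_length(v, 256)
  expect_true(all(v == 0))
})

test_that("persistence images are additive and non-negative over random diagrams", {
  set.seed(20)
  for (trial in 1:10) {
    pa <- cbind(runif(5), runif(5) + 1)
    pb <- cbind(runif(3), runif(3) + 1)
    va <- persistence_image(persistence_diagram(pa), grid16)
    vb <- persistence_image(persistence_diagram(pb), grid16)
    vab <- persistence_image(persistence_diagram(rbind(pa, pb)), grid16)
    expect_true(all(va >= 0) && all(vb >= 0))
    expect_equal(as.numeric(vab), as.numeric(va + vb), tolerance = 1e-10)
  }
  # duplicating a point exactly doubles the image
  one <- persistence_image(persistence_diagram(cbind(0, 1)), grid16)
  two <- persistence_image(persistence_diagram(rbind(c(0, 1), c(0, 1))), grid16)
  expect_equal(as.numeric(two), as.numeric(2 * one))
})

test_that("a unit-weight Gaussian inside the grid carries unit mass", {
  g <- pi_grid(c(-0.5, 1.5), c(-0.5, 1.5), c(200, 200), sigma = 0.05,
               weight_mode = "point")
  # the point (0, 1) has lifetime 1, so the point-evaluated weight is exactly 1
  v <- persistence_image(persistence_diagram(cbind(0, 1)), g)
  expect_equal(sum(v) * pi_cell_area(g), 1.0, tolerance = 0.01)
})

test_that("longer lifetimes dominate the image (squared-lifetime weighting)", {
  for (mode in c("grid", "point")) {
    g <- pi_grid(c(-1, 4), c(-1, 4), c(32, 32), sigma = 0.15, weight_mode = mode)
    peaks <- sapply(c(0.5, 1, 2, 3), function(death) {
      max(persistence_image(persistence_diagram(cbind(0, death)), g))
    })
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("diagonal features are suppressed", {
  # point-evaluated weight kills a zero-lifetime point outright
  gp <- pi_grid(c(-1, 2), c(-1, 2), c(32, 32), sigma = 0.1, weight_mode = "point")
  v <- persistence_image(persistence_diagram(cbind(0.5, 0.5)), gp)
  expect_true(all(v == 0))
  # grid-evaluated weight vanishes on and below the diagonal
  gg <- pi_grid(c(-1, 2), c(-1, 2), c(32, 32), sigma = 0.1, weight_mode = "grid")
  v <- matrix(persistence_image(persistence_diagram(cbind(0.5, 0.5)), gg),
              32, 32, byrow = TRUE)
  ctr <- seq(-1 + 3 / 64, 2 - 3 / 64, length.out = 32)
  below <- outer(ctr, ctr, function(b, d) d <= b)
  expect_true(all(v[below] == 0))
  expect_gt(max(v), 0)
})

test_that("cohort grids follow the documented bandwidth and padding rule", {
  g <- grid_from_diagrams(persistence_diagram(cbind(0, 2)))
  expect_equal(g$sigma, 0.1)
  expect_equal(g$birth_range, c(-0.3, 2.3))
  expect_equal(g$death_range, c(-0.3, 2.3))
  # cohort-wide bounds use the largest death across diagrams
  g2 <- grid_from_diagrams(list(persistence_diagram(cbind(0, 1)),
                                persistence_diagram(cbind(0, 3))))
  expect_equal(g2$sigma, 0.15)
  expect_equal(g2$birth_range, c(-0.45, 3.45))
  # the worked 5x5 example has max death 3 as well
  g3 <- grid_from_diagrams(persistence_h0(toy_recurrence_matrix()))
  expect_equal(g3$sigma, 0.15)
  expect_error(grid_from_diagrams(persistence_diagram()), "empty")
  expect_error(pi_grid(c(0, 1), c(0, 1), c(16, 16), sigma = -1), "sigma")
  expect_error(pi_grid(c(1, 0), c(0, 1), c(16, 16), sigma = 0.1), "max > min")
})

test_that("essential classes are dropped by default and capped on request", {
  d <- persistence_h0(toy_recurrence_matrix())
  v_drop <- persistence_image(d, grid16)
  d_no_ess <- persistence_diagram(d$pairs)
  expect_equal(as.numeric(v_drop),
               as.numeric(persistence_image(d_no_ess, grid16)))
  v_cap <- persistence_image(d, grid16, essential = "cap")
  capped <- persistence_diagram(rbind(d$pairs, c(0, 3)))
  expect_equal(as.numeric(v_cap),
               as.numeric(persistence_image(capped, grid16)))
})

test_that("feature matrices round-trip with their grid metadata", {
  tmp <- withr::local_tempfile()
  diags <- list(persistence_h0(toy_recurrence_matrix()),
                persistence_h0(toy_recurrence_matrix() * 0.5))
  g <- grid_from_diagrams(diags, resolution = c(8, 8))
  V <- pi_feature_matrix(diags, g)
  expect_equal(dim(V), c(2, 64))
  write_feature_matrix(V, tmp)
  got <- read_feature_matrix(tmp)
  expect_identical(unname(got[, ]), unname(V[, ]))
  expect_equal(attr(got, "grid")$sigma, g$sigma)
  expect_equal(attr(got, "grid")$weight_mode, g$weight_mode)
})
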