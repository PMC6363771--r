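test_that("LGL nodes and weights match closed forms", {
  g2 <- lgl_grid(2)
  expect_equal(g2$nodes, c(-1, 0, 1), tolerance = 1e-14)
  expect_equal(g2$weights, c(1 / 3, 4 / 3, 1 / 3), tolerance = 1e-14)
  g1 <- lgl_grid(1)
  expect_equal(g1$nodes, c(-1, 1))
  expect_equal(g1$D, matrix(c(-0.5, -0.5, 0.5, 0.5), 2, 2),
               tolerance = 1e-14)
  for (N in c(1, 2, 3, 5, 10, 20, 40, 80)) {
    g <- lgl_grid(N)
    expect_equal(sum(g$weights), 2, tolerance = 1e-12)
    expect_equal(g$nodes[1], -1)
    expect_equal(g$nodes[N + 1], 1)
    expect_true(all(diff(g$nodes) > 0))
    expect_true(all(g$weights > 0))
    # D annihilates constants
    expect_lt(max(abs(apply_differentiation(g, rep(1, N + 1)))), 1e-10)
  }
})

test_that("differentiation matrix is exact on monomials up to degree N", {
  for (N in c(5, 12, 25, 40)) {
    g <- lgl_grid(N)
    for (m in 1:N) {
      d <- apply_differentiation(g, g$nodes^m)
      expect_lt(max(abs(d - m * g$nodes^(m - 1))), 1e-10)
    }
  }
  g <- lgl_grid(10)
  expect_equal(apply_differentiation(g, g$nodes), rep(1, 11),
               tolerance = 1e-12)
  expect_error(apply_differentiation(g, rep(1, 5)), "node values")
  expect_error(lgl_grid(0), "integer")
})

test_that("quadrature integrates polynomials of degree 2N - 1 exactly", {
  for (N in c(3, 8, 15)) {
    g <- lgl_grid(N)
    for (m in seq(0, 2 * N - 1, by = 3)) {
      exact <- (1 - (-1)^(m + 1)) / (m + 1)
      expect_equal(sum(g$weights * g$nodes^m), exact, tolerance = 1e-12)
    }
  }
})

test_that("barycentric interpolation reproduces polynomial values", {
  g <- lgl_grid(12, 0, 240)
  f <- function(t) 3 + 0.02 * t + 1e-4 * t^2 - 2e-7 * t^3
  t_out <- seq(0, 240, by = 7)
  out <- interpolate_nodes(g, f(g$times), t_out)
  expect_equal(out, f(t_out), tolerance = 1e-9)
})

test_that("collocation solves a linear decay problem spectrally", {
  # x' = -x on [0, 1], x(0) = 1: solve the square collocation system by
  # Newton iteration on the defect equations and compare x(1) with exp(-1)
  solve_decay <- function(N) {
    g <- lgl_grid(N, 0, 1)
    x <- rep(1, N + 1)
    for (it in 1:50) {
      defect <- as.numeric(g$D %*% x) + g$half_span * x
      defect[1] <- x[1] - 1   # pinned initial value
      Jm <- g$D + diag(g$half_span, N + 1)
      Jm[1, ] <- 0; Jm[1, 1] <- 1
      step <- solve(Jm, -defect)
      x <- x + step
      if (max(abs(step)) < 1e-14) break
    }
    x[N + 1]
  }
  err10 <- abs(solve_decay(10) - exp(-1))
  err20 <- abs(solve_decay(20) - exp(-1))
  expect_lt(err20, 1e-8)
  expect_lt(err20, err10)
})
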