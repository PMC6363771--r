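test_that("vector field anchor identities hold", {
  p <- toy_parameters()
  ceil <- av_ceiling(p)
  # source balances sink at the AV ceiling with full VPS34 activity
  s <- av_state(c(0.5, 0.5, 0.5, 1, ceil), params = p)
  d <- av_vector_field(s, params = p)
  expect_equal(unname(d["x5"]), 0)
  # at the ceiling the AV count can only decrease
  for (x4 in c(0, 0.3, 0.7, 1)) {
    s <- av_state(c(0.5, 0.5, 0.5, x4, ceil), params = p)
    expect_lte(av_vector_field(s, params = p)["x5"], 0)
  }
  # no drug, no input: all six concentration derivatives vanish
  s <- av_state(c(0.2, 0.4, 0.6, 0.8, 10), params = p)
  expect_equal(unname(av_vector_field(s, params = p)[6:11]), rep(0, 6))
  expect_error(av_vector_field(s, controls = c(-1, rep(0, 5)), params = p),
               "negative")
})

test_that("identity drug curves reduce to the drug-free vector field", {
  # rb = rm = 1 makes every drug multiplier exactly 1
  p <- toy_parameters()
  s <- av_state(c(0.3, 0.6, 0.2, 0.7, 12), w = c(1, 2, 0.5, 3, 0.1, 4),
                params = p)
  s0 <- s; s0[6:11] <- 0
  d_drugged <- av_vector_field(s, params = p)
  d_free <- av_vector_field(s0, params = p)
  expect_equal(d_drugged[1:5], d_free[1:5])
})

test_that("unavailable drugs never accumulate", {
  p <- toy_parameters(b = c(1, 0, 1, 1, 1, 1))
  sched <- control_schedule(c(0, 100), matrix(1, 2, 6))
  tr <- simulate_model(p, av_state(c(0.5, 0.5, 0.5, 0.5, 10), params = p),
                       sched, times = seq(0, 100, by = 1))
  expect_equal(max(tr$w2), 0)
  expect_gt(min(tr$w1[-1]), 0)
})

test_that("constant infusion approaches b*c/delta mono-exponentially", {
  p <- toy_parameters()
  const <- 0.4
  sched <- control_schedule(c(0, 2000), matrix(const, 2, 6))
  tr <- simulate_model(p, av_state(c(0.5, 0.5, 0.5, 0.5, 10), params = p),
                       sched, times = seq(0, 2000, by = 10))
  expect_equal(tr$w1[nrow(tr)], const / p$delta[1], tolerance = 1e-5)
  # the whole curve is the analytic mono-exponential approach
  expect_equal(tr$w1, const / p$delta[1] * (1 - exp(-p$delta[1] * tr$t)),
               tolerance = 1e-6)
})

test_that("a root-found fixed point stays put under integration", {
  p <- toy_parameters(C_En = 0.3, C_Nu = 0.8)
  fp <- find_fixed_point(p)
  expect_lt(max(abs(av_vector_field(fp, params = p))), 1e-10)
  tr <- simulate_model(p, fp, times = seq(0, 1000, by = 5),
                       rtol = 1e-10, atol = 1e-12)
  drift <- max(abs(as.matrix(tr[nrow(tr), 2:6]) - fp[1:5]))
  expect_lt(drift, 1e-7)
})

test_that("compiled and R vector fields integrate to the same trajectory", {
  set.seed(11)
  p <- random_parameters()
  y0 <- random_state(p)
  sched <- control_schedule(c(0, 60, 120, 240),
                            matrix(runif(24, 0, 0.3), 4, 6))
  times <- seq(0, 240, by = 2)
  tr_c <- simulate_model(p, y0, sched, times)     # compiled path
  rhs_r <- function(t, y, parms) {
    u <- as.numeric(eval_schedule(sched, t))
    list(as.numeric(av_vector_field(pmax(y, 0), u, p)))
  }
  tr_r <- deSolve::lsoda(as.numeric(y0), times, rhs_r, NULL,
                         rtol = 1e-8, atol = 1e-10)
  expect_equal(as.matrix(tr_c[, 2:12]), unname(tr_r[, 2:12]),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("trajectories respect the state box for random models", {
  set.seed(7)
  for (rep in 1:100) {
    p <- random_parameters()
    y0 <- random_state(p)
    tr <- simulate_model(p, y0, times = seq(0, 500, length.out = 51),
                         rtol = 1e-8, atol = 1e-10)
    X <- as.matrix(tr[, 2:12])
    expect_true(all(X >= 0))
    expect_true(all(X[, 1:4] <= 1))
    expect_true(all(X[, 5] <= av_ceiling(p)))
  }
})

test_that("time rescaling leaves the state sequence unchanged", {
  p <- toy_parameters()
  y0 <- av_state(c(0.9, 0.1, 0.8, 0.2, 30), params = p)
  tr1 <- simulate_model(p, y0, times = seq(0, 200, by = 2))
  p2 <- p; p2$timescale <- 4
  tr2 <- simulate_model(p2, y0, times = seq(0, 800, by = 8))
  expect_equal(as.matrix(tr1[, -1]), as.matrix(tr2[, -1]),
               tolerance = 1e-6)
})

test_that("schedules evaluate with the stated interpolation rule", {
  sc <- control_schedule(c(0, 10, 20), matrix(c(0, 2, 0), 3, 6))
  expect_equal(eval_schedule(sc, 5)[1, 1], 1)     # linear midpoint
  scc <- control_schedule(c(0, 10, 20), matrix(c(0, 2, 0), 3, 6),
                          interpolation = "constant")
  expect_equal(eval_schedule(scc, 5)[1, 1], 0)
  expect_equal(eval_schedule(scc, 15)[1, 1], 2)
  expect_error(control_schedule(c(0, 0, 10), matrix(0, 3, 6)),
               "increasing")
  expect_error(control_schedule(c(0, 10), matrix(-1, 2, 6)),
               "nonnegative")
})
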