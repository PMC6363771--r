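# A fast synthetic control problem used throughout: hold the toy model's
# drug-free fixed point shifted slightly downward, which needs only a small
# sustained dose of drug 2.
small_problem <- function(shift = 3, epsilon = 1) {
  p <- toy_parameters(C_En = 0.5, C_Nu = 0.5,
                      drugs = replicate(6, hill_curve(0.05, 1, 0.5, 2),
                                        simplify = FALSE))
  fp <- find_fixed_point(p)
  ocp_spec(p, 2, target = fp[5] - shift, epsilon = epsilon, initial = fp)
}

test_that("an in-band target needs (almost) no fuel", {
  p <- toy_parameters()
  fp <- find_fixed_point(p)
  spec <- ocp_spec(p, 1, target = fp[5], epsilon = 2, initial = fp)
  sol <- solve_ocp(spec, N = 24)
  expect_true(sol$status %in% c("solved", "feasible"))
  expect_lt(sol$J, 0.2)
  expect_equal(sol$feasibility$band_violation, 0, tolerance = 1e-8)
})

test_that("a target beyond the AV ceiling is reported infeasible", {
  p <- toy_parameters()
  spec <- ocp_spec(p, 1, target = av_ceiling(p) - 0.5, epsilon = 0.4)
  spec$target <- av_ceiling(p) + 1   # force past construction checks
  sol <- solve_ocp(spec, N = 16)
  expect_equal(sol$status, "infeasible")
})

test_that("the solver produces validated feasible downregulation schedules", {
  spec <- small_problem()
  sol <- solve_ocp(spec, N = 32)
  expect_true(sol$status %in% c("solved", "feasible"))
  expect_lte(sol$feasibility$band_violation, 0.05)
  expect_equal(max(sol$feasibility$cap_violation), 0)
  expect_gt(sol$J, 0)
  # dosage record: nondecreasing, starts at zero, total equals J
  r <- sol$dosage
  expect_equal(r$r2[1], 0)
  expect_true(all(diff(r$r2) >= -1e-12))
  expect_lt(abs(max(r$r2) - sol$J) / sol$J, 1e-6)
  # mesh independence: a refined grid gives a similar objective
  sol2 <- solve_ocp(spec, N = 40)
  expect_lt(abs(sol2$J - sol$J) / sol$J, 0.1)
})

test_that("necessary-condition diagnostics hold for solved problems", {
  spec <- small_problem()
  sol <- solve_ocp(spec, N = 32)
  skip_if_not(identical(sol$status, "solved"))
  diag <- check_necessary_conditions(sol)
  expect_s3_class(diag, "optimality_diagnostics")
  expect_gte(diag$complementarity_residual, 0)
  # control is applied only where its switching function is favorable
  expect_lt(diag$complementarity_residual, 0.05 * max(sol$J, 1))
})

test_that("collocation trajectory agrees with re-integration when solved", {
  spec <- small_problem()
  sol <- solve_ocp(spec, N = 32)
  tr <- sol$trajectory
  x5_nodes <- interpolate_nodes(sol$grid, sol$X[, 5], tr$t)
  in_hold <- tr$t >= spec$t0
  expect_lt(max(abs(tr$x5[in_hold] - x5_nodes[in_hold])), 0.5)
})
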