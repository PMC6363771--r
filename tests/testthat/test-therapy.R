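test_that("therapy enumeration covers all drug subsets in order", {
  expect_length(enumerate_therapies(1), 6)
  duals <- enumerate_therapies(2)
  expect_length(duals, 15)
  expect_equal(duals[[1]], c(1L, 2L))
  expect_equal(duals[[15]], c(5L, 6L))
  expect_false(anyDuplicated(vapply(duals, paste, "", collapse = "-")) > 0)
  expect_length(enumerate_therapies(6), 1)
  expect_error(enumerate_therapies(0), "between 1 and 6")
  expect_error(enumerate_therapies(7), "between 1 and 6")
})

test_that("minimum-fuel objective integrates the therapy drugs only", {
  z <- zero_schedule(240)
  expect_equal(schedule_objective(z, 1:6, 240), 0)
  const <- control_schedule(c(0, 240), matrix(0.25, 2, 6))
  expect_equal(schedule_objective(const, 3, 240), 0.25 * 240,
               tolerance = 1e-10)
  expect_equal(schedule_objective(const, c(2, 5), 240), 2 * 0.25 * 240,
               tolerance = 1e-10)
  # drugs outside the therapy do not contribute
  expect_equal(schedule_objective(const, 1, 240),
               schedule_objective(const, 2, 240))
})

test_that("cumulative dosage is a nondecreasing running integral", {
  const <- control_schedule(c(0, 240), matrix(0.1, 2, 6))
  r <- cumulative_dosage(const, c(1, 4), seq(0, 240, by = 10))
  expect_equal(r$r1[1], 0)
  expect_equal(r$r4, 0.1 * r$t, tolerance = 1e-10)
  expect_true(all(diff(r$r1) >= 0))
  set.seed(5)
  rnd <- control_schedule(seq(0, 240, length.out = 25),
                          matrix(runif(25 * 6), 25, 6))
  r2 <- cumulative_dosage(rnd, 1:6, seq(0, 240, by = 5))
  for (i in 1:6) expect_true(all(diff(r2[[paste0("r", i)]]) >= -1e-12))
  # summed final dosages equal the objective
  total <- sum(vapply(1:6, function(i) max(r2[[paste0("r", i)]]), 0))
  expect_equal(total, schedule_objective(rnd, 1:6, 240, n_quad = 20001),
               tolerance = 1e-5)
})

test_that("ocp_spec validates the target band and initial state", {
  p <- toy_parameters()
  expect_error(ocp_spec(p, 1, target = 50), "inside")
  expect_error(ocp_spec(p, 1, target = 10, t0 = 0), "t0")
  expect_error(ocp_spec(p, 1, target = 10, epsilon = -1), "epsilon")
  expect_error(ocp_spec(p, integer(0), target = 10), "nonempty")
  dirty <- c(rep(0.5, 4), 10, 0.5, rep(0, 5))
  expect_error(ocp_spec(p, 1, target = 10, initial = dirty), "zero")
  spec <- ocp_spec(p, c(3, 1), target = 10)
  expect_equal(spec$therapy, c(1L, 3L))
  expect_equal(spec$params$b, as.numeric(1:6 %in% c(1, 3)))
  expect_equal(unname(spec$initial[6:11]), rep(0, 6))
})

test_that("validate_solution reports violations from re-integration", {
  p <- toy_parameters()
  fp <- find_fixed_point(p)
  # a trivially feasible problem: target the drug-free fixed point itself
  spec <- ocp_spec(p, 1, target = fp[5], epsilon = 1, initial = fp)
  rep0 <- validate_solution(spec, zero_schedule(240))
  expect_equal(rep0$band_violation, 0)
  expect_equal(rep0$J, 0)
  expect_equal(max(rep0$cap_violation), 0)
  # an uncontrolled system far from the target misses the band
  spec2 <- ocp_spec(p, 1, target = max(1, fp[5] - 10), epsilon = 1,
                    initial = fp)
  rep2 <- validate_solution(spec2, zero_schedule(240))
  expect_gt(rep2$band_violation, 1)
  # band deviations before t0 never count
  expect_equal(rep2$band_violation,
               max(abs(rep2$trajectory$x5[rep2$trajectory$t >= spec2$t0] -
                         spec2$target)) - spec2$epsilon,
               tolerance = 1e-6)
})

test_that("feasible monotherapy schedules embed into superset therapies", {
  p <- toy_parameters()
  fp <- find_fixed_point(p)
  spec1 <- ocp_spec(p, 2, target = fp[5], epsilon = 2, initial = fp)
  sched <- control_schedule(c(0, 240), matrix(0.01, 2, 1), drugs = 2,
                            interpolation = "constant")
  rep1 <- validate_solution(spec1, sched)
  for (extra in list(c(2, 4), c(1, 2, 6))) {
    spec_k <- ocp_spec(p, extra, target = fp[5], epsilon = 2, initial = fp)
    rep_k <- validate_solution(spec_k, embed_schedule(sched, spec_k))
    expect_equal(rep_k$band_violation, rep1$band_violation,
                 tolerance = 1e-8)
    expect_equal(rep_k$negativity_violation, rep1$negativity_violation)
    expect_equal(rep_k$J, rep1$J, tolerance = 1e-10)
  }
  spec_no2 <- ocp_spec(p, c(3, 4), target = fp[5], epsilon = 2,
                       initial = fp)
  expect_error(embed_schedule(sched, spec_no2), "outside")
})

test_that("dosage records match the objective to high relative accuracy", {
  set.seed(9)
  times <- seq(0, 240, length.out = 49)
  vals <- matrix(0, 49, 6)
  vals[, c(2, 6)] <- runif(98, 0, 2)
  sched <- control_schedule(times, vals, interpolation = "constant")
  grid_out <- seq(0, 240, length.out = 4801)
  r <- cumulative_dosage(sched, c(2, 6), grid_out)
  J <- schedule_objective(sched, c(2, 6), 240, n_quad = 4801)
  total <- max(r$r2) + max(r$r6)
  expect_lt(abs(total - J) / J, 1e-8)
})
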