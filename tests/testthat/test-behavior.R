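test_that("long-time classification separates stationary and oscillatory", {
  p <- default_parameters(0.1, 0.1)
  s1 <- classify_long_time(p)
  expect_equal(s1$regime, "stationary")
  expect_true(s1$settled)
  expect_equal(s1$envelope[1], s1$envelope[2], tolerance = 0.01)
  p6 <- default_parameters(0.6, 0.6)
  s6 <- classify_long_time(p6)
  expect_equal(s6$regime, "oscillatory")
  expect_gt(s6$amplitude, 0.5)
  expect_false(is.na(s6$period))
  expect_gte(s6$representative_x5, s6$envelope[1])
  expect_lte(s6$representative_x5, s6$envelope[2])
  # no AV synthesis: count decays to zero
  p0 <- p; p0$k3 <- 1e-9
  s0 <- classify_long_time(p0)
  expect_equal(s0$regime, "stationary")
  expect_lt(s0$representative_x5, 0.01)
})

test_that("regime calls are stable under doubling the observation window", {
  for (C in c(0.1, 0.6, 1.0)) {
    p <- default_parameters(C, C)
    a <- classify_long_time(p, burn_in = 1500, observe = 600)
    b <- classify_long_time(p, burn_in = 1500, observe = 1200)
    expect_equal(a$regime, b$regime)
    expect_equal(a$representative_x5, b$representative_x5, tolerance = 0.5)
  }
})

test_that("phase diagram reduces to single classifications per cell", {
  p <- default_parameters()
  pd1 <- phase_diagram(p, 0.3, 0.7, burn_in = 1000, observe = 500)
  expect_equal(nrow(pd1), 1)
  ref <- local({
    q <- p; q$C_En <- 0.3; q$C_Nu <- 0.7
    classify_long_time(q, burn_in = 1000, observe = 500)
  })
  expect_equal(pd1$representative_x5, ref$representative_x5)
  expect_equal(pd1$regime, ref$regime)
  g <- seq(0.1, 1, length.out = 4)
  pd <- phase_diagram(p, g, g, burn_in = 1500, observe = 800)
  expect_equal(nrow(pd), 16)
  expect_true(any(pd$regime == "oscillatory"))
  expect_true(any(pd$regime == "stationary"))
  # high count under starvation, low under replete conditions
  expect_gt(pd$representative_x5[pd$C_En == 0.1 & pd$C_Nu == 0.1], 30)
  expect_lt(pd$representative_x5[pd$C_En == 1 & pd$C_Nu == 1], 5)
})

test_that("step responses move the AV count in the expected direction", {
  p <- default_parameters()
  up <- step_response(p, c(1, 1), c(0.2, 0.2), horizon = 400)
  expect_lt(up$x5[1], 5)
  expect_gt(up$x5[nrow(up)], 30)
  down <- step_response(p, c(0.2, 0.2), c(1, 1), horizon = 400)
  expect_gt(down$x5[1], 30)
  expect_lt(down$x5[nrow(down)], 5)
  # no perturbation: stays put
  flat <- step_response(p, c(0.4, 0.4), c(0.4, 0.4), horizon = 200)
  expect_lt(diff(range(flat$x5)), 0.1)
})

test_that("dose-response curves start at the drug-free behavior", {
  p <- default_parameters(0.6, 0.6)
  short <- list(burn_in = 1500, observe = 800)
  dr <- do.call(dose_response,
                c(list(p, drug = 4, doses = c(0, 0.2, 0.5, 1, 2, 5)), short))
  base <- do.call(classify_long_time, c(list(p), short))
  expect_identical(dr$representative_x5[1], base$representative_x5)
  expect_identical(dr$regime[1], base$regime)
  # drug 4 suppresses the AV count with increasing dose
  expect_lt(dr$representative_x5[nrow(dr)], dr$representative_x5[1] - 5)
  expect_error(dose_response(p, 7, c(0, 1)), "drug index")
  expect_error(dose_response(p, 4, c(0.1, 1)), "start at 0")
})

test_that("drugs 1 and 5 raise and drug 6 cannot quench oscillations", {
  p <- default_parameters(0.6, 0.6)
  short <- list(burn_in = 1500, observe = 800)
  for (drug in c(1, 5)) {
    dr <- do.call(dose_response,
                  c(list(p, drug = drug,
                         doses = c(0, p$drugs[[drug]]$theta * c(1, 10))),
                    short))
    expect_gt(dr$representative_x5[3], dr$representative_x5[1] + 2)
  }
  dr6 <- do.call(dose_response,
                 c(list(p, drug = 6, doses = c(0, 0.5, 1, 2, 4)), short))
  expect_true(any(dr6$regime[-1] == "oscillatory"))
})

test_that("EC50 recovers theta for an engineered linear readout", {
  # VPS34 activation made constant and weak, so at steady state
  # x5 = ceiling * c H6(w) / (c H6(w) + k2) ~ (ceiling c / k2) H6(w):
  # the AV count is (nearly) a linear readout of the drug-6 Hill factor and
  # the half-maximal effect sits at theta
  p <- toy_parameters(C_En = 0.4, C_Nu = 0.4,
                      drugs = replicate(6, hill_curve(0.05, 1, 0.8, 3),
                                        simplify = FALSE))
  p$regulation$h42 <- hill_curve(0.02, 0.02, 0.5, 2)  # constant weak drive
  p$k2 <- 1
  # independent oracle: analytic steady state scanned by brute force
  curve6 <- p$drugs[[6]]
  x5_exact <- function(w) {
    H <- hill_drug(w, curve6)
    av_ceiling(p) * 0.02 * H / (0.02 * H + p$k2)
  }
  w_scan <- exp(seq(log(1e-4), log(1e4), length.out = 20001))
  eff <- x5_exact(w_scan) - x5_exact(0)
  half <- abs(eff[length(eff)]) / 2
  ec50_oracle <- w_scan[which(abs(eff) >= half)[1]]
  expect_equal(ec50_oracle, curve6$theta, tolerance = 0.02)
  ec50 <- compute_ec50(p, 6, min_effect = 0.1, burn_in = 800,
                       observe = 300)
  expect_equal(as.numeric(ec50), ec50_oracle, tolerance = 0.02)
})

test_that("EC50 rejects flat responses and self-brackets on the scan", {
  p <- toy_parameters(drugs = replicate(6, hill_curve(1, 1, 1, 2),
                                        simplify = FALSE))
  expect_error(compute_ec50(p, 3, burn_in = 500, observe = 200),
               "no measurable effect")
  p6 <- default_parameters(0.6, 0.6)
  ec <- compute_ec50(p6, 4, burn_in = 1500, observe = 800)
  scan <- attr(ec, "scan")
  base <- attr(ec, "baseline_x5")
  sat <- scan$effect[nrow(scan)]
  below <- scan$dose[abs(scan$effect) < abs(sat) / 2 &
                       sign(scan$effect) == sign(sat) | scan$effect == 0]
  above <- scan$dose[abs(scan$effect) >= abs(sat) / 2 &
                       sign(scan$effect) == sign(sat)]
  expect_lte(as.numeric(ec), min(above))
  expect_gte(as.numeric(ec), max(c(0, below[below < min(above)])))
})
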