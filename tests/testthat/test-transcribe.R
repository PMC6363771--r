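make_toy_spec <- function() {
  p <- toy_parameters()
  fp <- find_fixed_point(p)
  ocp_spec(p, c(2, 6), target = max(1.5, fp[5] - 5), epsilon = 1,
           initial = fp)
}

test_that("transcription dimensions and node bounds are consistent", {
  spec <- make_toy_spec()
  nlp <- transcribe(spec, 16)
  m <- 17
  expect_equal(nlp$n_var, m * (11 + 2))
  expect_equal(nlp$n_con, m * 11)
  # endpoint node times map to 0 and tf
  expect_equal(nlp$grid$times[1], 0)
  expect_equal(nlp$grid$times[m], spec$tf)
  # initial state pinned: equal bounds on the first node of every state
  first_node <- seq(1, m * 11, by = m)
  expect_equal(nlp$lower[first_node], nlp$upper[first_node])
  # band bounds active exactly at nodes at or past t0 (x5 block)
  x5_cols <- 4 * m + seq_len(m)
  scaled_hi <- nlp$upper[x5_cols] * nlp$var_scale[x5_cols]
  in_band <- nlp$grid$times >= spec$t0
  expect_true(all(scaled_hi[in_band] <= spec$target + spec$epsilon + 1e-9))
  expect_true(all(scaled_hi[!in_band][-1] > spec$target + spec$epsilon))
})

test_that("zero dynamics with constant states give zero defects", {
  # all rates zero: constant node states solve x' = 0 exactly
  p <- toy_parameters()
  p$k1 <- 0; p$k2 <- 0; p$k3 <- 5e-9; p$k4 <- 1e-9
  p$C_En <- 0; p$C_Nu <- 0
  flat0 <- function() hill_curve(0, 0, 1, 2)
  p$regulation <- lapply(p$regulation, function(x) flat0())
  names(p$regulation) <- names(toy_parameters()$regulation)
  suppressWarnings(validate_parameters(p))
  fp <- c(rep(0.4, 4), 2, rep(0, 6))
  spec <- ocp_spec(p, 1, target = 2, epsilon = 3, one_sided = TRUE,
                   initial = fp)
  nlp <- transcribe(spec, 10, band_margin = 0.01)
  X <- matrix(rep(fp, each = 11), 11, 11)
  U <- matrix(0, 11, 6)
  z <- nlp$pack(X, U)
  defect <- nlp$constraints(z)
  # all defects vanish except the drug clearance rows (also zero here)
  expect_lt(max(abs(defect)), 1e-12)
})

test_that("transcribed gradient and Jacobian agree with finite differences", {
  set.seed(21)
  spec <- make_toy_spec()
  nlp <- transcribe(spec, 6)
  up <- ifelse(is.finite(nlp$upper), nlp$upper, nlp$lower + 1)
  z <- (nlp$lower + up) / 2
  lam <- rnorm(nlp$n_con, sd = 0.2)
  mu <- 3
  fn <- function(zz) {
    cc <- nlp$constraints(zz)
    nlp$objective(zz) + sum(lam * cc) + mu / 2 * sum(cc^2)
  }
  g <- nlp$gradient(z) +
    nlp$constraint_jac_t(z, lam + mu * nlp$constraints(z))
  free <- which(up - nlp$lower > 1e-9)
  idx <- sample(free, 15)
  h <- 1e-6
  for (i in idx) {
    zp <- z; zm <- z
    zp[i] <- z[i] + h; zm[i] <- z[i] - h
    fd <- (fn(zp) - fn(zm)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
  # dense Jacobian consistent with the transposed product
  v <- rnorm(nlp$n_con)
  expect_equal(drop(crossprod(nlp$constraint_jacobian(z), v)),
               nlp$constraint_jac_t(z, v), tolerance = 1e-10)
})

test_that("quadrature objective matches the trapezoid integral of controls", {
  spec <- make_toy_spec()
  nlp <- transcribe(spec, 24)
  m <- 25
  X <- matrix(rep(spec$initial, each = m), m, 11)
  U <- matrix(0, m, 6)
  U[, spec$therapy] <- 0.3
  z <- nlp$pack(X, U)
  # constant control: integral = k * c * tf exactly
  expect_equal(nlp$objective(z), 2 * 0.3 * spec$tf, tolerance = 1e-9)
  # scaling all controls up increases the objective (positive weights)
  U2 <- U * 1.001
  expect_gt(nlp$objective(nlp$pack(X, U2)), nlp$objective(z))
})
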