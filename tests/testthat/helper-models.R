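# Shared test fixtures, built in code.

# A small, fast, hand-checkable parameter set (not the calibrated defaults):
# mild regulation, identity drug curves unless overridden.
toy_parameters <- function(C_En = 0.5, C_Nu = 0.5, b = rep(1, 6),
                           drugs = NULL) {
  flat <- function() hill_curve(rb = 1, rm = 1, theta = 1, n = 2)
  if (is.null(drugs)) drugs <- replicate(6, flat(), simplify = FALSE)
  av_parameters(
    timescale = 1, C_En = C_En, C_Nu = C_Nu,
    k1 = 0.2, k2 = 0.1, k3 = 2, k4 = 0.05,
    delta = rep(0.02, 6), b = b,
    regulation = list(
      h12 = hill_curve(0.1, 2, 0.5, 2),
      h13 = hill_curve(0.1, 2, 0.5, 2),
      h23 = hill_curve(0.1, 2, 0.5, 2),
      h21 = hill_curve(0.2, 3, 0.5, 2),
      h42 = hill_curve(0.05, 1, 0.5, 2)),
    drugs = drugs)
}

# random valid parameter draw for property-style tests
random_parameters <- function() {
  rcurve <- function(rb_max = 1, rm_max = 5)
    hill_curve(rb = runif(1, 0.01, rb_max), rm = runif(1, 0.1, rm_max),
               theta = runif(1, 0.2, 1), n = runif(1, 1, 6))
  av_parameters(
    timescale = 1,
    C_En = runif(1), C_Nu = runif(1),
    k1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.02, 0.3),
    k3 = runif(1, 0.5, 4), k4 = runif(1, 0.02, 0.2),
    delta = runif(6, 0.005, 0.05), b = rep(1, 6),
    regulation = list(h12 = rcurve(), h13 = rcurve(), h23 = rcurve(),
                      h21 = rcurve(), h42 = rcurve(rm_max = 1)),
    drugs = replicate(6, {
      hill_curve(rb = runif(1, 0, 0.2), rm = 1, theta = runif(1, 0.3, 2),
                 n = runif(1, 1, 4))
    }, simplify = FALSE))
}

random_state <- function(params) {
  av_state(c(runif(4), runif(1, 0, av_ceiling(params))),
           w = runif(6, 0, 2), params = params)
}
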