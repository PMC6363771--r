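#' Hill regulation curve
#'
#' A four-parameter Hill curve used throughout the autophagy network model,
#' both for kinase-kinase regulatory influences (activating form, see
#' [hill_activating()]) and for drug effects on kinase activities (repressive
#' form, see [hill_drug()]).
#'
#' @param rb Baseline rate (the value approached by the activating form as the
#'   input goes to 0, and by the drug form as the concentration grows large).
#'   Nonnegative.
#' @param rm Maximal rate (activating form: large-input limit; drug form:
#'   zero-concentration value, so `rm = 1` means a drug-free multiplier of 1).
#'   Nonnegative.
#' @param theta Half-saturation threshold, strictly positive.
#' @param n Hill coefficient (steepness), strictly positive; need not be an
#'   integer.
#' @return An object of class `hill_curve`.
#' @examples
#' hc <- hill_curve(rb = 0.1, rm = 1, theta = 0.3, n = 2)
#' hill_activating(0.3, hc)  # half saturation: (rb + rm) / 2
#' @export
hill_curve <- function(rb, rm, theta, n) {
  stopifnot(is.numeric(rb), is.numeric(rm), is.numeric(theta), is.numeric(n),
            length(rb) == 1L, length(rm) == 1L, length(theta) == 1L,
            length(n) == 1L)
  if (!is.finite(rb) || rb < 0) stop("'rb' must be finite and nonnegative")
  if (!is.finite(rm) || rm < 0) stop("'rm' must be finite and nonnegative")
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be positive")
  if (!is.finite(n) || n <= 0) stop("'n' must be positive")
  structure(list(rb = rb, rm = rm, theta = theta, n = n),
            class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("<hill_curve rb=%g rm=%g theta=%g n=%g>\n",
              x$rb, x$rm, x$theta, x$n))
  invisible(x)
}

is_hill_curve <- function(x) inherits(x, "hill_curve")

#' Activating Hill function
#'
#' Evaluates `rb + (rm - rb) * x^n / (x^n + theta^n)`, the form used for the
#' regulatory influences h_ji among the four kinases. The output is bounded
#' between `min(rb, rm)` and `max(rb, rm)` for any nonnegative input.
#'
#' @param x Nonnegative numeric vector of regulator activities.
#' @param curve A [hill_curve()].
#' @return Numeric vector of rates, same length as `x`.
#' @export
hill_activating <- function(x, curve) {
  stopifnot(is_hill_curve(curve))
  if (any(!is.finite(x))) stop("non-finite input to hill_activating()")
  if (any(x < 0)) stop("negative input to hill_activating()")
  xn <- x^curve$n
  curve$rb + (curve$rm - curve$rb) * xn / (xn + curve$theta^curve$n)
}

#' Repressive (drug-effect) Hill function
#'
#' Evaluates `rm - (rm - rb) * w^n / (w^n + theta^n)`, the multiplier a drug at
#' dimensionless concentration `w` applies to the kinase rate it targets. The
#' multiplier decreases from `rm` at `w = 0` toward `rb` at saturating
#' concentrations (for `rm > rb`).
#'
#' @param w Nonnegative numeric vector of drug concentrations.
#' @param curve A [hill_curve()].
#' @return Numeric vector of multipliers, same length as `w`.
#' @export
hill_drug <- function(w, curve) {
  stopifnot(is_hill_curve(curve))
  if (any(!is.finite(w))) stop("non-finite input to hill_drug()")
  if (any(w < 0)) stop("negative drug concentration in hill_drug()")
  wn <- w^curve$n
  curve$rm - (curve$rm - curve$rb) * wn / (wn + curve$theta^curve$n)
}

# derivative of the activating form w.r.t. its input (used by the NLP Jacobian)
hill_activating_deriv <- function(x, curve) {
  n <- curve$n; th <- curve$theta
  xn <- x^n
  num <- (curve$rm - curve$rb) * n * th^n * ifelse(x > 0, xn / x, 0)
  num / (xn + th^n)^2
}

# derivative of the drug form w.r.t. the concentration
hill_drug_deriv <- function(w, curve) {
  n <- curve$n; th <- curve$theta
  wn <- w^n
  num <- -(curve$rm - curve$rb) * n * th^n * ifelse(w > 0, wn / w, 0)
  num / (wn + th^n)^2
}
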