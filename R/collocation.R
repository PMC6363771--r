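#' Legendre-Gauss-Lobatto collocation grid
#'
#' Computes the order-`N` LGL grid on `[-1, 1]`: the `N + 1` nodes (roots of
#' `(1 - tau^2) P'_N(tau)`, including both endpoints), the quadrature weights
#' `2 / (N (N + 1) P_N(tau_i)^2)`, the Lagrange differentiation matrix `D`
#' with `D[k, i] = dL_i/dtau (tau_k)`, and an affine map between `[-1, 1]`
#' and a physical time interval `[t0, tf]`.
#'
#' The weights integrate polynomials up to degree `2N - 1` exactly (so they
#' sum to 2), and `D` maps node values of any polynomial of degree at most
#' `N` to exact derivative values.
#'
#' @param N Polynomial order, integer `>= 1`.
#' @param t0,tf Physical time interval endpoints (`t0 < tf`), minutes.
#' @return An object of class `collocation_grid` with fields `N`, `nodes`,
#'   `weights`, `D`, `t0`, `tf`, `times` (mapped node times) and
#'   `half_span = (tf - t0) / 2`.
#' @export
lgl_grid <- function(N, t0 = 0, tf = 1) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be an integer >= 1")
  if (tf <= t0) stop("'tf' must exceed 't0'")
  N <- as.integer(N)
  # Newton iteration on the interior extrema of P_N, Chebyshev initial guess
  tau <- cos(pi * (N:0) / N)
  P <- matrix(0, N + 1, N + 1)
  for (it in 1:200) {
    P[, 1] <- 1
    P[, 2] <- tau
    if (N >= 2) for (k in 2:N)
      P[, k + 1] <- ((2 * k - 1) * tau * P[, k] - (k - 1) * P[, k - 1]) / k
    tau_old <- tau
    tau <- tau_old - (tau * P[, N + 1] - P[, N]) / ((N + 1) * P[, N + 1])
    if (max(abs(tau - tau_old)) < 1e-15) break
  }
  P[, 1] <- 1; P[, 2] <- tau
  if (N >= 2) for (k in 2:N)
    P[, k + 1] <- ((2 * k - 1) * tau * P[, k] - (k - 1) * P[, k - 1]) / k
  PN <- P[, N + 1]
  w <- 2 / (N * (N + 1) * PN^2)
  # standard closed-form LGL differentiation matrix
  D <- matrix(0, N + 1, N + 1)
  for (k in seq_len(N + 1)) for (i in seq_len(N + 1)) {
    if (k != i) D[k, i] <- PN[k] / (PN[i] * (tau[k] - tau[i]))
  }
  D[1, 1] <- -N * (N + 1) / 4
  D[N + 1, N + 1] <- N * (N + 1) / 4
  structure(list(N = N, nodes = tau, weights = w, D = D, t0 = t0, tf = tf,
                 times = (tf - t0) / 2 * tau + (tf + t0) / 2,
                 half_span = (tf - t0) / 2),
            class = "collocation_grid")
}

#' @export
print.collocation_grid <- function(x, ...) {
  cat(sprintf("<collocation_grid LGL N=%d on [%g, %g] min>\n",
              x$N, x$t0, x$tf))
  invisible(x)
}

#' Spectral differentiation at the collocation nodes
#'
#' Applies the differentiation matrix of an LGL grid to node values of a
#' function, returning node values of the derivative (with respect to the
#' normalized coordinate `tau`) of the degree-`N` interpolant.
#'
#' @param grid A [lgl_grid()].
#' @param values Numeric vector of `N + 1` node values, or a matrix with
#'   `N + 1` rows (one column per function).
#' @return Derivative values, same shape as `values`.
#' @export
apply_differentiation <- function(grid, values) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(v) != grid$N + 1)
    stop(sprintf("expected %d node values, got %d", grid$N + 1, nrow(v)))
  out <- grid$D %*% v
  if (is.matrix(values)) out else as.numeric(out)
}

# barycentric weights for the LGL nodes (stable off-node interpolation)
barycentric_weights <- function(nodes) {
  n <- length(nodes)
  bw <- numeric(n)
  for (i in seq_len(n)) bw[i] <- 1 / prod(nodes[i] - nodes[-i])
  bw / max(abs(bw))
}

#' Evaluate the collocation interpolant off the nodes
#'
#' Barycentric Lagrange evaluation of the degree-`N` interpolant through the
#' node values, at arbitrary points of the grid's physical time interval.
#'
#' @param grid A [lgl_grid()].
#' @param values `N + 1` node values (vector) or matrix with `N + 1` rows.
#' @param t_out Physical times at which to evaluate.
#' @return Interpolated values (vector or matrix with one row per `t_out`).
#' @export
interpolate_nodes <- function(grid, values, t_out) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  tau_out <- (t_out - (grid$tf + grid$t0) / 2) / grid$half_span
  bw <- barycentric_weights(grid$nodes)
  out <- matrix(0, length(tau_out), ncol(v))
  for (j in seq_along(tau_out)) {
    d <- tau_out[j] - grid$nodes
    hit <- which(abs(d) < 1e-14)
    if (length(hit)) {
      out[j, ] <- v[hit[1], ]
    } else {
      c_j <- bw / d
      out[j, ] <- colSums(v * c_j) / sum(c_j)
    }
  }
  if (is.matrix(values)) out else as.numeric(out)
}
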