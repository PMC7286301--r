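#' Jansen-Rit model parameters
#'
#' Scalar constants of the Jansen-Rit neural mass model. Each cortical node
#' comprises a pyramidal population coupled to excitatory and inhibitory
#' interneuron populations; the state is six-dimensional (three average
#' postsynaptic potentials y0, y1, y2 in mV and their derivatives y3, y4, y5
#' in mV/s) and the observable is the pyramidal potential y = y1 - y2.
#'
#' Defaults are the standard single-column values: synaptic connectivity
#' constants C = (135, 108, 33.75, 33.75), basal extracortical input
#' P = 120 Hz, rate constants a = 100/s, b = 50/s, maximum firing rate
#' nu_max = 5 Hz, half-activation potential v0 = 6 mV, sigmoid gradient
#' r = 0.56/mV, and global coupling eps = 0.1. The excitatory and inhibitory
#' PSP amplitudes A (sweep range 2-14 mV) and B (10-30 mV) are the control
#' parameters of the analyses in this package; their defaults are the
#' classical A = 3.25, B = 22.
#'
#' @param A excitatory PSP amplitude (mV).
#' @param B inhibitory PSP amplitude (mV).
#' @param a excitatory rate constant (1/s).
#' @param b inhibitory rate constant (1/s).
#' @param C1,C2,C3,C4 synaptic connectivity constants (dimensionless).
#' @param P basal extracortical input (Hz).
#' @param eps global coupling strength (dimensionless).
#' @param nu_max maximum population firing rate (Hz).
#' @param v0 potential at half-maximum firing rate (mV).
#' @param r sigmoid gradient at v0 (1/mV).
#' @return an object of class \code{jr_params}.
#' @export
jr_params <- function(A = 3.25, B = 22, a = 100, b = 50,
                      C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75,
                      P = 120, eps = 0.1, nu_max = 5, v0 = 6, r = 0.56) {
  stopifnot(a > 0, b > 0, nu_max > 0, r > 0, A >= 0, B >= 0)
  structure(list(A = A, B = B, a = a, b = b,
                 C1 = C1, C2 = C2, C3 = C3, C4 = C4,
                 P = P, eps = eps, nu_max = nu_max, v0 = v0, r = r),
            class = "jr_params")
}

#' @export
print.jr_params <- function(x, ...) {
  cat(sprintf(
    "jr_params: A=%.3g B=%.3g mV, a=%g b=%g /s, C=(%g,%g,%g,%g), P=%g Hz, eps=%g\n",
    x$A, x$B, x$a, x$b, x$C1, x$C2, x$C3, x$C4, x$P, x$eps))
  invisible(x)
}

# parameter vector in the fixed order the C++ integrator expects
.par_vec <- function(p) {
  c(p$A, p$B, p$a, p$b, p$C1, p$C2, p$C3, p$C4, p$P,
    p$nu_max, p$v0, p$r)
}

#' Sigmoidal firing-rate function
#'
#' \code{f(v) = nu_max / (1 + exp(r * (v0 - v)))}: transduction of average
#' membrane potential into a population firing rate. Strictly increasing,
#' range (0, nu_max), with f(v0) = nu_max / 2. The exponent is clamped so
#' the function saturates instead of overflowing.
#'
#' @param v membrane potential (mV), vectorised.
#' @param params a \code{jr_params}.
#' @return firing rate (Hz).
#' @export
jr_sigmoid <- function(v, params = jr_params()) {
  z <- params$r * (params$v0 - v)
  z <- pmin(pmax(z, -700), 700)
  params$nu_max / (1 + exp(z))
}

#' Derivative of the sigmoidal firing-rate function
#'
#' \code{f'(v) = r f(v) (1 - f(v)/nu_max)} (Hz/mV).
#'
#' @inheritParams jr_sigmoid
#' @export
jr_sigmoid_deriv <- function(v, params = jr_params()) {
  f <- jr_sigmoid(v, params)
  params$r * f * (1 - f / params$nu_max)
}

#' Network vector field of the coupled Jansen-Rit model
#'
#' Evaluates the deterministic right-hand side of the N-node network. Per
#' node i (dropping the node index on the right where it is the same node):
#' \preformatted{
#'   y0' = y3
#'   y1' = y4
#'   y2' = y5
#'   y3' = A a f(y1 - y2) - 2 a y3 - a^2 y0
#'   y4' = A a [P_i + eps sum_j w_ij f(y1_j - y2_j) + C2 f(C1 y0)]
#'         - 2 a y4 - a^2 y1
#'   y5' = B b C4 f(C3 y0) - 2 b y5 - b^2 y2
#' }
#' The coupling (afferent pyramidal firing rates weighted by the connectome)
#' enters only the excitatory-interneuron drive y4'.
#'
#' @param state N x 6 matrix, columns (y0, ..., y5); a length-6 vector is
#'   accepted for a single node.
#' @param params a \code{jr_params}.
#' @param sc a \code{structural_connectome}, or \code{NULL} for uncoupled
#'   nodes.
#' @param drive per-node extracortical input (Hz); defaults to
#'   \code{params$P} for every node.
#' @return N x 6 matrix of time derivatives.
#' @export
network_rhs <- function(state, params = jr_params(), sc = NULL, drive = NULL) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  n <- nrow(state)
  stopifnot(ncol(state) == 6)
  if (is.null(drive)) drive <- rep(params$P, n)
  if (length(drive) != n) stop("drive length must match the number of nodes")
  w <- if (is.null(sc)) matrix(0, n, n) else sc$weights
  if (nrow(w) != n) stop("connectome dimension does not match state")
  y0 <- state[, 1]; y1 <- state[, 2]; y2 <- state[, 3]
  y3 <- state[, 4]; y4 <- state[, 5]; y5 <- state[, 6]
  fy <- jr_sigmoid(y1 - y2, params)
  coup <- params$eps * as.vector(w %*% fy)
  cbind(
    y3, y4, y5,
    params$A * params$a * fy - 2 * params$a * y3 - params$a^2 * y0,
    params$A * params$a *
      (drive + coup + params$C2 * jr_sigmoid(params$C1 * y0, params)) -
      2 * params$a * y4 - params$a^2 * y1,
    params$B * params$b * params$C4 * jr_sigmoid(params$C3 * y0, params) -
      2 * params$b * y5 - params$b^2 * y2,
    deparse.level = 0)
}

# Scalar consistency residual for the node-homogeneous equilibrium in the
# pyramidal potential y = y1 - y2, for afferent row sum gamma:
#   y = (A/a)(P + eps*gamma*f(y) + C2 f(C1 (A/a) f(y)))
#       - (B/b) C4 f(C3 (A/a) f(y))
.fp_residual <- function(y, params, gamma) {
  f <- jr_sigmoid(y, params)
  y0 <- params$A / params$a * f
  y1 <- params$A / params$a *
    (params$P + params$eps * gamma * f +
       params$C2 * jr_sigmoid(params$C1 * y0, params))
  y2 <- params$B / params$b * params$C4 * jr_sigmoid(params$C3 * y0, params)
  (y1 - y2) - y
}

#' Homogeneous network equilibria
#'
#' For a row-normalised connectome (every row sum Gamma = 1) the network has
#' node-homogeneous equilibria obtained from a single scalar consistency
#' equation in the pyramidal potential y = y1 - y2. The equation is scanned
#' over a bracketing grid and each sign change refined by bisection; several
#' roots signal the saddle-node (multi-equilibrium) regime.
#'
#' @param params a \code{jr_params}.
#' @param sc a row-normalised \code{structural_connectome}, or \code{NULL}
#'   for a single uncoupled node (coupling term absent).
#' @param y_range scan interval for y (mV); default c(-20, 60) covers the
#'   physiological PSP range generously.
#' @param step scan step (mV).
#' @param tol bisection tolerance on the residual root.
#' @return list with \code{y} (roots, mV), \code{states} (list of length-6
#'   equilibrium vectors, derivative components zero), \code{gamma},
#'   \code{residuals}.
#' @export
find_fixed_point <- function(params = jr_params(), sc = NULL,
                             y_range = c(-20, 60), step = 0.05,
                             tol = 1e-14) {
  gamma <- if (is.null(sc)) 0 else {
    if (!sc$is_row_normalised)
      stop("connectome must be row-normalised for a homogeneous equilibrium")
    1
  }
  ys <- seq(y_range[1], y_range[2], by = step)
  res <- .fp_residual(ys, params, gamma)
  sgn <- sign(res)
  roots <- ys[res == 0]
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(.fp_residual, c(ys[i], ys[i + 1]),
                        params = params, gamma = gamma, tol = tol)
    y <- r$root
    # Newton polish to the machine-precision root so the assembled
    # 6-component state annihilates the vector field to rounding error
    for (it in 1:4) {
      h <- 1e-6
      fy <- .fp_residual(y, params, gamma)
      dfy <- (.fp_residual(y + h, params, gamma) -
                .fp_residual(y - h, params, gamma)) / (2 * h)
      if (!is.finite(dfy) || dfy == 0) break
      step <- fy / dfy
      y <- y - step
      if (abs(step) < 1e-15) break
    }
    roots <- c(roots, y)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    stop(sprintf("no equilibrium found for y in [%g, %g] mV",
                 y_range[1], y_range[2]))
  states <- lapply(roots, function(y) {
    f <- jr_sigmoid(y, params)
    y0 <- params$A / params$a * f
    y2 <- params$B / params$b * params$C4 *
      jr_sigmoid(params$C3 * y0, params)
    c(y0, y + y2, y2, 0, 0, 0)
  })
  list(y = roots, states = states, gamma = gamma,
       residuals = .fp_residual(roots, params, gamma))
}

#' Single-node Jacobian at an equilibrium
#'
#' The 6 x 6 Jacobian of the intrinsic (uncoupled) Jansen-Rit vector field
#' at a given equilibrium state.
#'
#' @param params a \code{jr_params}.
#' @param eq length-6 equilibrium state vector.
#' @return 6 x 6 numeric matrix.
#' @export
single_node_jacobian <- function(params, eq) {
  y0 <- eq[1]; y <- eq[2] - eq[3]
  fp_y <- jr_sigmoid_deriv(y, params)
  fp_c1 <- jr_sigmoid_deriv(params$C1 * y0, params)
  fp_c3 <- jr_sigmoid_deriv(params$C3 * y0, params)
  a <- params$a; b <- params$b
  J <- matrix(0, 6, 6)
  J[1, 4] <- 1; J[2, 5] <- 1; J[3, 6] <- 1
  J[4, 1] <- -a^2
  J[4, 2] <- params$A * a * fp_y
  J[4, 3] <- -params$A * a * fp_y
  J[4, 4] <- -2 * a
  J[5, 1] <- params$A * a * params$C2 * params$C1 * fp_c1
  J[5, 2] <- -a^2
  J[5, 5] <- -2 * a
  J[6, 1] <- params$B * b * params$C4 * params$C3 * fp_c3
  J[6, 3] <- -b^2
  J[6, 6] <- -2 * b
  J
}

#' Eigenmode-decoupled Jacobian block
#'
#' Linearising the network around a node-homogeneous equilibrium and
#' diagonalising in the basis of eigenvectors of the structural connectivity
#' matrix W reduces the 6N x 6N stability problem to N independent 6 x 6
#' problems, one per eigenvalue mu of W:
#' \code{J(mu) = J_intrinsic + eps * mu * E}, where E is zero except the
#' y4'-row entries for (y1, y2), which are \code{A a f'(y*) (+1, -1)}.
#'
#' @param params a \code{jr_params}.
#' @param eq length-6 homogeneous equilibrium state.
#' @param mu eigenvalue of W (may be complex).
#' @return 6 x 6 matrix (complex if \code{mu} is complex).
#' @export
local_jacobian <- function(params, eq, mu) {
  J <- single_node_jacobian(params, eq)
  fp_y <- jr_sigmoid_deriv(eq[2] - eq[3], params)
  g <- params$eps * mu * params$A * params$a * fp_y
  if (is.complex(mu)) J <- J + 0i
  J[5, 2] <- J[5, 2] + g
  J[5, 3] <- J[5, 3] - g
  J
}

#' Full network Jacobian at a homogeneous equilibrium
#'
#' Builds the 6N x 6N Jacobian directly (intrinsic blocks on the diagonal
#' plus the coupling perturbation weighted by W). Used as the brute-force
#' cross-check of the eigenmode decoupling in \code{\link{local_jacobian}}.
#'
#' @param params a \code{jr_params}.
#' @param sc a \code{structural_connectome}.
#' @param eq length-6 homogeneous equilibrium state.
#' @return 6N x 6N numeric matrix (state ordered node-major: node 1's six
#'   components, then node 2's, ...).
#' @export
network_jacobian <- function(params, sc, eq) {
  n <- sc$n_nodes
  Ji <- single_node_jacobian(params, eq)
  fp_y <- jr_sigmoid_deriv(eq[2] - eq[3], params)
  E <- matrix(0, 6, 6)
  E[5, 2] <- params$A * params$a * fp_y
  E[5, 3] <- -E[5, 2]
  kronecker(diag(n), Ji) + params$eps * kronecker(sc$weights, E)
}
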