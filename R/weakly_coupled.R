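#' Adjoint (infinitesimal phase response) of the single-node limit cycle
#'
#' Solves the adjoint variational equation \code{dQ/dt = -J(x(t))' Q} along
#' the limit cycle by backward-in-time integration (RK4 on the cycle grid)
#' until the solution is periodic to within \code{tol} per period, then
#' normalises so that \code{Q(t) . F(x(t)) = Omega} (F the vector field) at
#' every sample. Backward integration makes all non-periodic components
#' decay, leaving the unique periodic adjoint.
#'
#' @param cycle a \code{limit_cycle}.
#' @param params a \code{jr_params}; defaults to the cycle's snapshot.
#' @param tol per-period relative convergence tolerance.
#' @param max_periods maximum number of backward periods before signalling
#'   non-convergence (a near-fold cycle converges slowly).
#' @return K x 6 matrix of adjoint samples on the cycle grid, with attribute
#'   \code{"normalisation_spread"} (max relative deviation of Q.F from
#'   Omega).
#' @export
compute_adjoint <- function(cycle, params = cycle$params, tol = 1e-8,
                            max_periods = 200) {
  K <- nrow(cycle$y_samples)
  Tper <- cycle$period
  h <- Tper / K

  # periodic splines of the state, evaluated on a half-step grid so RK4
  # stages fall exactly on precomputed Jacobians
  t_knots <- Tper * (0:K) / K
  sp <- lapply(1:6, function(j)
    stats::splinefun(t_knots, c(cycle$y_samples[, j], cycle$y_samples[1, j]),
                     method = "periodic"))
  t2 <- Tper * (0:(2 * K - 1)) / (2 * K)
  J2 <- lapply(t2, function(t) {
    st <- vapply(sp, function(f) f(t), numeric(1))
    t(single_node_jacobian(params, st))  # transposed once here
  })

  # integrate Qt(s) = Q(T - s) forward in s: dQt/ds = +J(T - s)' Qt
  jt_index <- function(i2) (2 * K - i2) %% (2 * K) + 1  # s-grid -> t-grid
  Q <- rep(1, 6)
  Qhist <- matrix(0, K, 6)
  converged <- FALSE
  for (per in seq_len(max_periods)) {
    Qstart <- Q
    for (i in 0:(K - 1)) {
      Ja <- J2[[jt_index(2 * i)]]
      Jb <- J2[[jt_index(2 * i + 1)]]
      Jc <- J2[[jt_index(2 * i + 2)]]
      k1 <- Ja %*% Q
      k2 <- Jb %*% (Q + h / 2 * k1)
      k3 <- Jb %*% (Q + h / 2 * k2)
      k4 <- Jc %*% (Q + h * k3)
      Q <- Q + h / 6 * as.vector(k1 + 2 * k2 + 2 * k3 + k4)
      Qhist[i + 1, ] <- Q  # Qt at s_{i+1}
    }
    nQ <- sqrt(sum(Q^2))
    Q <- Q / nQ  # keep scale fixed between periods
    if (sqrt(sum((Q - Qstart / sqrt(sum(Qstart^2)))^2)) < tol &&
        per > 1) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("adjoint did not converge within ", max_periods,
         " periods (near-fold cycle?)")

  # map back to cycle time: Q(t_k) = Qt(s_{K-k}); s index K stored at row K
  Qmat <- matrix(0, K, 6)
  Qmat[1, ] <- Qhist[K, ]
  for (k in 1:(K - 1)) Qmat[k + 1, ] <- Qhist[K - k, ]

  Fv <- network_rhs(cycle$y_samples, params, sc = NULL,
                    drive = rep(params$P, K))
  cF <- rowSums(Qmat * Fv)
  Qmat <- Qmat * (cycle$Omega / mean(cF))
  spread <- max(abs(cF / mean(cF) - 1))
  attr(Qmat, "normalisation_spread") <- spread
  Qmat
}

# Fourier spectral derivative of samples of a smooth periodic function on a
# uniform grid over [0, 2*pi)
.spectral_deriv <- function(v) {
  K <- length(v)
  kk <- c(0:(K / 2), -(ceiling(K / 2) - 1):-1)
  if (K %% 2 == 0) kk[K / 2 + 1] <- 0  # Nyquist mode has no odd derivative
  Re(stats::fft(stats::fft(v) * 1i * kk, inverse = TRUE)) / K
}

#' Build the phase interaction function H
#'
#' \code{H(phi) = (1/T) int_0^T Q4(t) * A*a*f(y(t + phi/Omega)) dt}, where
#' Q4 is the adjoint component of the perturbed equation (the excitatory
#' drive y4'), y = y1 - y2 on the cycle, and \code{A*a*f(.)} is exactly the
#' coupling term's contribution per unit connection weight. Evaluated on the
#' cycle grid the integral is a circular average, exact for the trapezoidal
#' rule on periodic data. The derivative samples come from the Fourier
#' spectral derivative.
#'
#' @param cycle a \code{limit_cycle}.
#' @param Q adjoint samples from \code{\link{compute_adjoint}}.
#' @param params a \code{jr_params}.
#' @return an object of class \code{phase_reduction}: fields \code{H}
#'   (K samples over [0, 2 pi)), \code{Hd} (derivative samples), \code{H0},
#'   \code{H_prime0}, \code{Omega}, \code{cycle}, \code{Q}.
#' @export
build_H <- function(cycle, Q, params = cycle$params) {
  K <- nrow(cycle$y_samples)
  if (nrow(Q) != K) stop("adjoint and cycle grids differ")
  yobs <- cycle$y_samples[, 2] - cycle$y_samples[, 3]
  u <- params$A * params$a * jr_sigmoid(yobs, params)
  q4 <- Q[, 5]
  # H[m+1] = mean_k q4[k] * u[k + m]  (circular): via FFT cross-correlation
  H <- Re(stats::fft(Conj(stats::fft(q4)) * stats::fft(u),
                     inverse = TRUE)) / K^2
  Hd <- .spectral_deriv(H)
  structure(list(H = H, Hd = Hd, H0 = H[1], H_prime0 = Hd[1],
                 Omega = cycle$Omega, K = K, cycle = cycle, Q = Q,
                 params = params),
            class = "phase_reduction")
}

#' Full phase reduction of a Jansen-Rit node
#'
#' Convenience wrapper: limit cycle, adjoint, and phase interaction function
#' in one call.
#'
#' @param params a \code{jr_params} with (A, B) in the oscillatory region.
#' @param ... passed to \code{\link{compute_limit_cycle}}.
#' @return a \code{phase_reduction}.
#' @export
phase_reduction <- function(params, ...) {
  cycle <- compute_limit_cycle(params, ...)
  Q <- compute_adjoint(cycle, params)
  build_H(cycle, Q, params)
}

#' @export
print.phase_reduction <- function(x, ...) {
  cat(sprintf(
    "phase_reduction: Omega = %.4f rad/s (T = %.5f s), H(0) = %.5g, H'(0) = %.5g\n",
    x$Omega, 2 * pi / x$Omega, x$H0, x$H_prime0))
  invisible(x)
}

#' Evaluate the phase interaction function (or its derivative)
#'
#' Periodic cubic interpolation of the stored H samples.
#'
#' @param red a \code{phase_reduction}.
#' @param phi phase argument(s), radians (any real; interpreted mod 2 pi).
#' @param deriv 0 for H, 1 for H'.
#' @return numeric vector.
#' @export
eval_H <- function(red, phi, deriv = 0) {
  v <- if (deriv == 0) red$H else red$Hd
  K <- red$K
  grid <- 2 * pi * (0:K) / K
  sp <- stats::splinefun(grid, c(v, v[1]), method = "periodic")
  sp(phi %% (2 * pi))
}

#' Stability of the globally synchronous state
#'
#' For a connectome with constant row sum Gamma the synchronous solution
#' exists and its weakly-coupled Jacobian is \code{-eps H'(0) L} (L the
#' graph Laplacian), so with the Laplacian spectrum in the right half plane
#' synchrony is stable iff \code{eps * H'(0) > 0}. The synchronous state
#' oscillates at the emergent frequency \code{Omega + eps * Gamma * H(0)}.
#'
#' @param red a \code{phase_reduction}.
#' @param eps global coupling strength.
#' @param gamma common row sum of the connectome (1 after row
#'   normalisation).
#' @return list: \code{stable}, \code{indicator} (eps * H'(0)),
#'   \code{emergent_frequency} (rad/s).
#' @export
synchrony_stability <- function(red, eps, gamma = 1) {
  ind <- eps * red$H_prime0
  list(stable = ind > 0, indicator = ind,
       emergent_frequency = red$Omega + eps * gamma * red$H0)
}

#' Simulate the reduced phase model
#'
#' Integrates \code{theta_i' = Omega + eps sum_j w_ij H(theta_j - theta_i)}
#' with RK4 and periodic cubic Hermite evaluation of H. Convergence to a
#' phase-locked state is detected by comparing relative phases one period
#' apart at the end of the run.
#'
#' @param red a \code{phase_reduction}.
#' @param sc a \code{structural_connectome}.
#' @param eps global coupling strength.
#' @param theta0 initial phases (radians); default all zero.
#' @param t_total integration time (s).
#' @param dt step (s); 1e-3 is ample for RK4 at ~10 Hz rhythms.
#' @param sample_rate output sampling rate (Hz).
#' @param lock_tol stationarity tolerance (radians over one period) for
#'   declaring a locked state.
#' @return list: \code{theta} (N x M phase trajectories), \code{dt_sample},
#'   \code{locked} (flag), \code{Phi} (final relative phases, gauge
#'   phi_N = 0).
#' @export
simulate_phase_model <- function(red, sc, eps, theta0 = NULL, t_total = 10,
                                 dt = 1e-3, sample_rate = 200,
                                 lock_tol = 1e-8) {
  n <- sc$n_nodes
  if (is.null(theta0)) theta0 <- rep(0, n)
  stopifnot(length(theta0) == n, red$K >= 512)
  keep_every <- max(1L, as.integer(round(1 / (sample_rate * dt))))
  n_steps <- as.integer(round(t_total / dt))
  th <- phase_integrate_cpp(theta0, sc$weights, eps, red$Omega,
                            red$H, red$Hd, dt, n_steps, keep_every)
  dts <- keep_every * dt
  M <- ncol(th)
  Tper <- 2 * pi / red$Omega
  lag <- max(1L, round(Tper / dts))
  locked <- FALSE
  if (M > lag) {
    rel_now <- th[, M] - th[n, M]
    rel_then <- th[, M - lag] - th[n, M - lag]
    locked <- max(abs(rel_now - rel_then)) < lock_tol
  }
  Phi <- (th[, M] - th[n, M]) %% (2 * pi)
  list(theta = th, dt_sample = dts, locked = locked, Phi = Phi)
}

#' Jacobian of the phase model at a phase-locked state
#'
#' Builds
#' \code{M_ij = eps [H'(phi_j - phi_i) w_ij - delta_ij sum_k H'(phi_k - phi_i) w_ik]},
#' whose row sums vanish (the uniform vector spans the kernel from the
#' global phase-shift symmetry). The state is first checked to be stationary
#' for the relative-phase dynamics.
#'
#' @param Phi phases of the locked state (radians), any gauge.
#' @param sc a \code{structural_connectome}.
#' @param red a \code{phase_reduction}.
#' @param eps global coupling strength.
#' @param check_tol relative stationarity tolerance (set \code{NULL} to
#'   skip the check).
#' @return list: \code{jacobian} (N x N), \code{eigenvalues} (sorted by
#'   decreasing real part), \code{largest_nonzero} (leading eigenvalue after
#'   removing the symmetry zero mode).
#' @export
phase_locked_jacobian <- function(Phi, sc, red, eps, check_tol = 1e-4) {
  n <- sc$n_nodes
  stopifnot(length(Phi) == n)
  w <- sc$weights
  D <- outer(Phi, Phi, function(a, b) b - a)  # D[i, j] = phi_j - phi_i
  if (!is.null(check_tol)) {
    v <- red$Omega + eps * rowSums(w * matrix(eval_H(red, D), n, n))
    resid <- max(abs(v - mean(v)))
    scale <- abs(eps) * max(abs(red$H)) + 1e-300
    if (resid > check_tol * scale)
      stop(sprintf(
        "Phi is not a phase-locked state: frequency spread %.3g rad/s", resid))
  }
  Hp <- matrix(eval_H(red, D, deriv = 1), n, n)
  M <- eps * (Hp * w)
  diag(M) <- diag(M) - rowSums(eps * Hp * w)
  ev <- eigen(M, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  zero_idx <- which.min(abs(ev))
  list(jacobian = M, eigenvalues = ev,
       largest_nonzero = ev[-zero_idx][which.max(Re(ev[-zero_idx]))])
}

#' Eigenmode prediction of functional connectivity
#'
#' At synchrony the phase-model Jacobian reduces to \code{-eps H'(0) L}; the
#' phase-locked pattern emerging beyond an instability of synchrony is a
#' linear combination of its eigenmodes. The predictor is the tensor-product
#' sum \code{sum_k lambda_k v_k v_k'} over the \code{n_modes} eigenmodes
#' with largest real part (all N by default), taken as a real matrix
#' (conjugate eigenpairs are both included so their contributions combine to
#' \code{2 Re(lambda v v')}), symmetrised, and min-max rescaled to [0, 1]
#' over the off-diagonal entries.
#'
#' @param sc a row-normalised \code{structural_connectome}.
#' @param red a \code{phase_reduction}.
#' @param eps global coupling strength.
#' @param n_modes number of eigenmodes to sum (default all N).
#' @return an \code{fc_matrix} with metric "predicted".
#' @export
eigenmode_fc_prediction <- function(sc, red, eps, n_modes = NULL) {
  n <- sc$n_nodes
  if (is.null(n_modes)) n_modes <- n
  stopifnot(n_modes >= 1, n_modes <= n)
  J <- phase_locked_jacobian(rep(0, n), sc, red, eps,
                             check_tol = NULL)$jacobian
  eg <- eigen(J)
  # the non-symmetric eigensolver returns non-orthogonal bases of
  # degenerate eigenspaces; orthonormalise each real degenerate cluster so
  # the tensor-product sum over all modes equals the spectral reconstruction
  if (!is.complex(eg$values) ||
      max(abs(Im(eg$values))) < 1e-10 * max(abs(eg$values), 1)) {
    vals <- Re(eg$values)
    vecs <- Re(eg$vectors)
    scale <- max(abs(vals), 1)
    cl <- cumsum(c(TRUE, abs(diff(sort(vals))) > 1e-8 * scale))
    ordv <- order(vals)
    for (g in unique(cl)) {
      idx <- ordv[cl == g]
      if (length(idx) > 1)
        vecs[, idx] <- qr.Q(qr(vecs[, idx, drop = FALSE]))
    }
    eg <- list(values = vals, vectors = vecs)
  }
  ord <- order(-Re(eg$values))
  sel <- ord[seq_len(n_modes)]
  # complete any conjugate pair cut by the selection boundary
  vals <- eg$values
  if (is.complex(vals)) {
    for (k in sel) {
      if (abs(Im(vals[k])) > 1e-12) {
        mate <- which(abs(vals - Conj(vals[k])) < 1e-10 & seq_len(n) != k)
        sel <- union(sel, mate[1])
      }
    }
  }
  S <- matrix(0 + 0i, n, n)
  for (k in sel) {
    v <- eg$vectors[, k]
    S <- S + vals[k] * (v %o% v)
  }
  M <- Re(S)
  M <- (M + t(M)) / 2
  off <- upper.tri(M) | lower.tri(M)
  rng <- range(M[off])
  # a numerically constant pattern (e.g. all-to-all coupling) must not have
  # its rounding dust amplified by the rescale
  M[off] <- if (diff(rng) <= 1e-12 * max(abs(rng), 1)) 0 else
    (M[off] - rng[1]) / diff(rng)
  fc_matrix(M, metric = "predicted")
}
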