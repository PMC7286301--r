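#' Extract the single-node limit cycle
#'
#' Integrates a single (uncoupled, noise-free) node past its transient,
#' estimates the orbit period from the autocorrelation of the observable
#' y = y1 - y2 with full-state closure used to reject subharmonic
#' candidates, refines the period by minimising the state-space closure
#' distance on a spline-interpolated trajectory, and resamples one period at
#' K uniform points.
#'
#' @param params a \code{jr_params} with (A, B) inside the oscillatory
#'   region.
#' @param dt integration step (s).
#' @param t_transient discarded settle time (s).
#' @param t_record recorded window used for period detection (s).
#' @param K samples per period in the returned cycle (>= 200).
#' @return an object of class \code{limit_cycle}: \code{y_samples} (K x 6
#'   matrix over one period), \code{period} (s), \code{Omega} (rad/s),
#'   \code{closure} (relative endpoint mismatch), \code{params}.
#' @export
compute_limit_cycle <- function(params, dt = 1e-4, t_transient = 5,
                                t_record = 1.5, K = 1024) {
  stopifnot(K >= 200)
  eq <- find_fixed_point(params)$states[[1]]
  y0 <- eq + c(1, 1, 0, 0, 0, 0)  # kick off the equilibrium
  n_steps <- round((t_transient + t_record) / dt)
  X <- jr_single_states_cpp(y0, .par_vec(params), dt, n_steps,
                            round(t_transient / dt), 1L)
  yobs <- X[, 2] - X[, 3]
  amp <- diff(range(yobs))
  if (amp < 1e-6)
    stop("no oscillation detected: observable amplitude below 1e-6 mV ",
         "(parameters outside the oscillatory regime?)")

  # candidate periods: local maxima of the autocorrelation, smallest lag
  # whose full-state closure is small wins (rejects T/2 for two-loop orbits)
  yc <- yobs - mean(yobs)
  max_lag <- min(length(yc) - 1, round(0.5 / dt))
  ac <- stats::acf(yc, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  is_max <- c(FALSE, diff(sign(diff(ac))) < 0, FALSE) & lags > round(0.01 / dt)
  cand <- lags[is_max & ac > 0.2]
  if (!length(cand))
    stop("no periodicity detected in the recorded window")
  scale0 <- apply(X, 2, function(c) diff(range(c)))
  scale0[scale0 == 0] <- 1
  closure_at <- function(lag) {
    m <- nrow(X) - lag
    sqrt(mean(((X[1:m, ] - X[(lag + 1):nrow(X), ]) %*%
                 diag(1 / scale0))^2))
  }
  cl <- vapply(cand, closure_at, numeric(1))
  T0_lag <- cand[which(cl < 0.02)][1]
  if (is.na(T0_lag)) T0_lag <- cand[which.min(cl)]

  # spline interpolants of each state component for sub-step refinement
  tt <- (seq_len(nrow(X)) - 1) * dt
  sp <- lapply(1:6, function(j) stats::splinefun(tt, X[, j]))
  state_at <- function(t) vapply(sp, function(f) f(t), numeric(1))
  t0 <- 0.2 * t_record  # anchor point well inside the window
  obj <- function(Tc) {
    d <- (state_at(t0 + Tc) - state_at(t0)) / scale0
    sqrt(mean(d^2))
  }
  Tlag <- T0_lag * dt
  opt <- stats::optimize(obj, c(Tlag - 5 * dt, Tlag + 5 * dt), tol = 1e-12)
  Tper <- opt$minimum

  ts_cycle <- t0 + Tper * (0:(K - 1)) / K
  y_samples <- t(vapply(ts_cycle, state_at, numeric(6)))
  structure(list(y_samples = y_samples, period = Tper,
                 Omega = 2 * pi / Tper,
                 closure = opt$objective, params = params),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf(
    "limit_cycle: T = %.5f s (%.2f Hz), %d samples, closure %.2e\n",
    x$period, 1 / x$period, nrow(x$y_samples), x$closure))
  invisible(x)
}

# time derivative of the observable on the cycle: y' = y4 - y5 (exact)
.cycle_ydot <- function(cycle) cycle$y_samples[, 5] - cycle$y_samples[, 6]

# second derivative y'' = y4' - y5' from the vector field
.cycle_yddot <- function(cycle) {
  d <- network_rhs(cycle$y_samples, cycle$params, sc = NULL,
                   drive = rep(cycle$params$P, nrow(cycle$y_samples)))
  d[, 5] - d[, 6]
}

#' Waveform shape of a limit cycle
#'
#' Counts the extrema of the observable over one period (sign changes of
#' y' = y4 - y5 with a hysteresis threshold that ignores sub-tolerance
#' wiggles) and flags an inflection plateau: a point where both y' and y''
#' are simultaneously near zero relative to their amplitude scales, the
#' signature of the smooth single- to double-peak transition.
#'
#' @param cycle a \code{limit_cycle}.
#' @param hysteresis fraction of max |y'| below which sign changes are
#'   ignored.
#' @param plateau_tol threshold on the scaled indicator
#'   \code{(y'/s1)^2 + (y''/s2)^2} below which a plateau is declared.
#' @return list: \code{n_extrema} (2 for sinusoidal-like, 4 for
#'   double-peaked), \code{has_inflection_plateau}, \code{plateau_indicator}
#'   (the minimum of the scaled indicator).
#' @export
waveform_shape <- function(cycle, hysteresis = 1e-3, plateau_tol = 1e-3) {
  ydot <- .cycle_ydot(cycle)
  K <- length(ydot)
  if (K < 200) stop("undersampled cycle")
  thr <- hysteresis * max(abs(ydot))
  # hysteresis sign-change counter around the periodic loop
  s <- 0
  n_changes <- 0
  for (v in c(ydot, ydot)[seq_len(2 * K)]) {  # two loops: settle, then count
    if (abs(v) <= thr) next
    sv <- sign(v)
    if (s != 0 && sv != s) {
      n_changes <- n_changes + 1
    }
    s <- sv
  }
  n_extrema <- n_changes / 2  # counted over two periods
  yddot <- .cycle_yddot(cycle)
  s1 <- max(abs(ydot)); s2 <- max(abs(yddot))
  ind <- (ydot / s1)^2 + (yddot / s2)^2
  list(n_extrema = as.integer(round(n_extrema)),
       has_inflection_plateau = min(ind) < plateau_tol,
       plateau_indicator = min(ind))
}

#' Locate a false bifurcation by bisection on the waveform shape
#'
#' A false bifurcation is a smooth transition between a sinusoidal-like
#' (2 extrema per period) and a double-peaked (4 extrema) waveform that
#' happens without any change of orbit stability, via the development of an
#' inflection point. Requires the two ends of \code{A_range} to show
#' different shapes; bisection on the extrema count then brackets the
#' transition to tolerance \code{tol}.
#'
#' @param params a \code{jr_params} (A overridden during the search).
#' @param B inhibitory amplitude (mV) at which to search.
#' @param A_range interval of A (mV) straddling the transition.
#' @param tol bisection tolerance in A (mV).
#' @param ... further arguments to \code{\link{compute_limit_cycle}}.
#' @return list: \code{A_star}, \code{direction} ("up" if the extrema count
#'   increases with A), \code{n_extrema_lo}, \code{n_extrema_hi}.
#' @export
locate_false_bifurcation <- function(params, B = 22, A_range = c(7, 9),
                                     tol = 0.01, ...) {
  shape_at <- function(A) {
    p <- params; p$A <- A; p$B <- B
    waveform_shape(compute_limit_cycle(p, ...))$n_extrema
  }
  lo <- A_range[1]; hi <- A_range[2]
  n_lo <- shape_at(lo); n_hi <- shape_at(hi)
  if (n_lo == n_hi)
    stop(sprintf("same waveform shape (%d extrema) at both ends of A_range",
                 n_lo))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (shape_at(mid) == n_lo) lo <- mid else hi <- mid
  }
  list(A_star = (lo + hi) / 2,
       direction = if (n_hi > n_lo) "up" else "down",
       n_extrema_lo = n_lo, n_extrema_hi = n_hi)
}
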