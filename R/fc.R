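#' Analytic signal via the FFT
#'
#' One-sided-spectrum construction of the analytic signal: the FFT of the
#' (real) input has its positive frequencies doubled, negative frequencies
#' zeroed, and DC/Nyquist kept, before inverse transformation.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
.analytic_signal <- function(x) {
  m <- length(x)
  X <- stats::fft(x)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1, m / 2 + 1)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / m
}

#' Instantaneous phases by Hilbert transform
#'
#' Per node: subtract the temporal mean, form the analytic signal, and take
#' its complex argument as the instantaneous phase. An edge-guard window
#' (default 5% of the samples at each end, where the analytic signal is
#' distorted by the implicit periodic extension) is dropped before the
#' phases are returned, so all subsequent averaging excludes it.
#'
#' @param ts a \code{node_time_series} (or plain matrix, rows = nodes).
#' @param edge_frac fraction of samples trimmed from each end.
#' @param demean subtract each node's temporal mean first (default TRUE).
#' @return an object of class \code{phase_series} with fields \code{phi}
#'   (N x M' matrix of phases, radians) and \code{dt}.
#' @export
extract_phases <- function(ts, edge_frac = 0.05, demean = TRUE) {
  y <- if (inherits(ts, "node_time_series")) ts$y else ts
  dt <- if (inherits(ts, "node_time_series")) ts$dt else NA_real_
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  m <- ncol(y)
  if (m < 16) stop("need at least 16 samples to estimate phases")
  rng <- apply(y, 1, function(r) diff(range(r)))
  if (any(rng == 0))
    stop("constant time series (undefined phase) for node(s) ",
         paste(which(rng == 0), collapse = ", "))
  phi <- t(apply(y, 1, function(r) {
    if (demean) r <- r - mean(r)
    Arg(.analytic_signal(r))
  }))
  guard <- floor(edge_frac * m)
  keep <- (guard + 1):(m - guard)
  structure(list(phi = phi[, keep, drop = FALSE], dt = dt),
            class = "phase_series")
}

#' Phase series container
#'
#' @param phi N x M matrix of instantaneous phases (radians, modulo 2 pi).
#' @param dt sampling step (s).
#' @export
phase_series <- function(phi, dt = NA_real_) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1)
  stopifnot(all(is.finite(phi)))
  structure(list(phi = phi, dt = dt), class = "phase_series")
}

#' Functional connectivity matrix container
#'
#' @param values N x N symmetric matrix in [0, 1]; diagonal fixed to 1
#'   (self-synchrony) and excluded from all comparisons.
#' @param metric one of "mpc", "mpa", "predicted".
#' @param is_binarised logical.
#' @export
fc_matrix <- function(values, metric = c("mpc", "mpa", "predicted"),
                      is_binarised = FALSE) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(values = values, metric = metric,
                 is_binarised = is_binarised),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("fc_matrix (%s%s): %d nodes, off-diagonal mean %.3f\n",
              x$metric, if (x$is_binarised) ", binarised" else "",
              nrow(x$values), mean(off)))
  invisible(x)
}

# pairwise apply over unordered node pairs of a phase matrix
.pairwise_phase_stat <- function(phi, stat) {
  n <- nrow(phi)
  R <- diag(1, n)
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        v <- stat(phi[j, ] - phi[k, ])
        R[j, k] <- v
        R[k, j] <- v
      }
    }
  }
  R
}

#' Mean phase coherence
#'
#' For each node pair, the modulus of the circular mean of the instantaneous
#' phase difference: \code{R_jk = | mean_l exp(i (phi_j - phi_k)(t_l)) |}.
#' 1 means phase locking, 0 complete desynchronisation.
#'
#' @param ph a \code{phase_series}.
#' @return an \code{fc_matrix} with metric "mpc".
#' @export
mean_phase_coherence <- function(ph) {
  stopifnot(inherits(ph, "phase_series"))
  R <- .pairwise_phase_stat(ph$phi, function(d) Mod(mean(exp(1i * d))))
  fc_matrix(R, metric = "mpc")
}

#' Mean phase agreement
#'
#' Temporal average of \code{(1 + cos(delta phi)) / 2}. Unlike mean phase
#' coherence it distinguishes in-phase locking (1) from locking at a fixed
#' lag (below 1, down to 0 at antiphase).
#'
#' @param ph a \code{phase_series}.
#' @return an \code{fc_matrix} with metric "mpa".
#' @export
mean_phase_agreement <- function(ph) {
  stopifnot(inherits(ph, "phase_series"))
  R <- .pairwise_phase_stat(ph$phi, function(d) mean((1 + cos(d)) / 2))
  fc_matrix(R, metric = "mpa")
}

#' Binarise a functional connectivity matrix at a target edge density
#'
#' Applies the same ranking and deterministic tie rule as structural
#' thresholding (\code{\link{threshold_binarise}}), so binarised FC and SC
#' are directly comparable. The default density 0.23 matches the structural
#' preprocessing.
#'
#' @param fc a non-binarised \code{fc_matrix}.
#' @param density fraction in (0, 1] of node pairs to retain.
#' @return a binarised \code{fc_matrix}.
#' @export
binarise_fc <- function(fc, density = 0.23) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (fc$is_binarised) stop("FC matrix is already binarised")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  v <- fc$values
  n <- nrow(v)
  n_keep <- if (density == 1) n * (n - 1) / 2 else
    floor(density * n * (n - 1) / 2)
  b <- matrix(0, n, n)
  if (n_keep > 0) {
    idx <- .top_pairs(v, n_keep)
    b[idx] <- 1
    b[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  fc_matrix(b, metric = fc$metric, is_binarised = TRUE)
}

.binary_offdiag <- function(x) {
  v <- if (inherits(x, "fc_matrix")) x$values else
    if (inherits(x, "structural_connectome")) x$weights else x
  v <- (v != 0)
  v[upper.tri(v)]
}

#' Jaccard similarity of binary edge sets
#'
#' Ratio of shared to total edges over the unordered off-diagonal pairs of
#' two binarised matrices: |intersection| / |union|. 1 for identical edge
#' sets, 0 for disjoint nonempty ones.
#'
#' @param x,y binarised \code{fc_matrix} / \code{structural_connectome} /
#'   0-1 matrices of equal size.
#' @return similarity in [0, 1].
#' @export
jaccard_binary <- function(x, y) {
  ex <- .binary_offdiag(x)
  ey <- .binary_offdiag(y)
  if (length(ex) != length(ey)) stop("matrices differ in size")
  uni <- sum(ex | ey)
  if (uni == 0) stop("both edge sets are empty: Jaccard undefined")
  sum(ex & ey) / uni
}

.binaryless_offdiag <- function(x) {
  v <- if (inherits(x, "fc_matrix")) x$values else
    if (inherits(x, "structural_connectome")) x$weights else x
  v[upper.tri(v)]
}

.rescaled_offdiag <- function(x) {
  v <- if (inherits(x, "fc_matrix")) x$values else
    if (inherits(x, "structural_connectome")) x$weights else x
  u <- v[upper.tri(v)]
  rng <- range(u)
  if (diff(rng) == 0) return(rep(0, length(u)))
  (u - rng[1]) / diff(rng)
}

#' Weighted Jaccard similarity of two matrices
#'
#' Ratio of elementwise-minimum to elementwise-maximum sums over the
#' unordered off-diagonal pairs. By default both matrices are first min-max
#' rescaled to [0, 1] over their off-diagonal entries so matrices on
#' different scales (e.g. a spectral prediction versus a synchrony metric)
#' are comparable; set \code{rescale = FALSE} to compare raw values already
#' on a common [0, 1] scale.
#'
#' @param x,y \code{fc_matrix} / matrices of equal size.
#' @param rescale min-max rescale the off-diagonal entries first.
#' @return similarity in [0, 1].
#' @export
jaccard_weighted <- function(x, y, rescale = TRUE) {
  grab <- if (rescale) .rescaled_offdiag else .binaryless_offdiag
  ux <- grab(x)
  uy <- grab(y)
  if (length(ux) != length(uy)) stop("matrices differ in size")
  denom <- sum(pmax(ux, uy))
  if (denom == 0) stop("both matrices are constant: weighted Jaccard undefined")
  sum(pmin(ux, uy)) / denom
}

#' Average a list of FC matrices entrywise
#'
#' @param fcs list of \code{fc_matrix} objects sharing size and metric.
#' @return an \code{fc_matrix}.
#' @export
average_fc <- function(fcs) {
  stopifnot(length(fcs) >= 1)
  vals <- Reduce(`+`, lapply(fcs, function(f) f$values)) / length(fcs)
  fc_matrix(vals, metric = fcs[[1]]$metric)
}
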