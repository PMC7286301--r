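#' Classify a point of the (A, B) parameter plane by equilibrium stability
#'
#' Finds all node-homogeneous network equilibria, then solves the N
#' eigenmode-decoupled 6 x 6 spectral problems (one per eigenvalue of the
#' connectivity matrix, see \code{\link{local_jacobian}}) for each
#' equilibrium. The leading eigenvalue (largest real part over all modes and
#' equilibria) determines the label:
#' \describe{
#'   \item{hopf_unstable}{leading eigenvalue has positive real part and a
#'     nonzero imaginary part (oscillatory instability of the equilibrium
#'     set: the regime supporting limit cycles).}
#'   \item{multi_equilibria}{more than one equilibrium root (saddle-node
#'     regime) without an oscillatory instability.}
#'   \item{stable_focus_or_node}{all eigenvalues in the left half plane.}
#' }
#'
#' @param params a \code{jr_params} (with the A, B of interest).
#' @param sc a row-normalised \code{structural_connectome}, or \code{NULL}
#'   for a single uncoupled node.
#' @return an object of class \code{stability_classification}: fields
#'   \code{A}, \code{B}, \code{n_equilibria}, \code{leading_eigenvalue}
#'   (overall spectral abscissa), \code{leading_complex} (leading eigenvalue
#'   among complex pairs, the Hopf indicator), \code{label},
#'   \code{critical_mode_index}, \code{equilibria}.
#' @export
classify_point <- function(params, sc = NULL) {
  mus <- if (is.null(sc)) 0 else eigen(sc$weights, only.values = TRUE)$values
  fp <- find_fixed_point(params, sc)
  leading <- -Inf + 0i          # overall spectral abscissa
  leading_cplx <- -Inf + 0i     # over complex-pair eigenvalues (Hopf modes)
  crit_mode <- NA_integer_
  for (st in fp$states) {
    for (k in seq_along(mus)) {
      ev <- eigen(local_jacobian(params, st, mus[k]), only.values = TRUE)$values
      top <- ev[which.max(Re(ev))]
      if (Re(top) > Re(leading)) leading <- top
      cp <- ev[abs(Im(ev)) > 1e-8]
      if (length(cp)) {
        topc <- cp[which.max(Re(cp))]
        if (Re(topc) > Re(leading_cplx)) {
          leading_cplx <- topc
          crit_mode <- k
        }
      }
    }
  }
  # in the saddle-node regime a real positive eigenvalue always exists, so
  # the oscillatory instability is read off the complex pairs only
  label <- if (Re(leading_cplx) > 0) "hopf_unstable"
    else if (length(fp$y) > 1) "multi_equilibria"
    else "stable_focus_or_node"
  structure(list(A = params$A, B = params$B,
                 n_equilibria = length(fp$y),
                 leading_eigenvalue = leading,
                 leading_complex = leading_cplx,
                 label = label,
                 critical_mode_index = crit_mode,
                 equilibria = fp$y),
            class = "stability_classification")
}

#' @export
print.stability_classification <- function(x, ...) {
  cat(sprintf(
    "(A=%.3g, B=%.3g): %s; %d equilibria; leading eigenvalue %.4g %+.4gi\n",
    x$A, x$B, x$label, x$n_equilibria,
    Re(x$leading_eigenvalue), Im(x$leading_eigenvalue)))
  invisible(x)
}

# scalar indicator whose sign change marks the requested boundary
.boundary_indicator <- function(A, params, sc, boundary) {
  params$A <- A
  cl <- classify_point(params, sc)
  if (boundary == "hopf") Re(cl$leading_complex) else
    as.numeric(cl$n_equilibria > 1) - 0.5
}

#' Trace a bifurcation boundary in the (A, B) plane
#'
#' For each requested B, scans A over \code{A_range} for a change of the
#' boundary indicator (Hopf: sign of the leading eigenvalue's real part;
#' saddle-node: change in the number of equilibria) and refines the crossing
#' by bisection to tolerance \code{tol}. B values where no change is found
#' in the interval are skipped with a warning.
#'
#' @param params a \code{jr_params} (its A is overridden during the scan).
#' @param sc a row-normalised \code{structural_connectome} or \code{NULL}.
#' @param B_values numeric vector of B values (mV).
#' @param boundary "hopf" or "saddle_node".
#' @param A_range scan interval for A (mV); default the sweep range (2, 14).
#' @param tol bisection tolerance in A (mV).
#' @param n_scan number of initial scan points across \code{A_range}.
#' @return data frame with columns A, B (one row per located crossing).
#' @export
trace_boundary <- function(params, sc = NULL, B_values,
                           boundary = c("hopf", "saddle_node"),
                           A_range = c(2, 14), tol = 1e-3, n_scan = 25) {
  boundary <- match.arg(boundary)
  out <- list()
  for (B in B_values) {
    p <- params
    p$B <- B
    As <- seq(A_range[1], A_range[2], length.out = n_scan)
    ind <- vapply(As, .boundary_indicator, numeric(1),
                  params = p, sc = sc, boundary = boundary)
    cross <- which(ind[-1] * ind[-length(ind)] < 0)
    if (!length(cross)) {
      warning(sprintf("no %s boundary found in A = [%g, %g] at B = %g",
                      boundary, A_range[1], A_range[2], B))
      next
    }
    for (i in cross) {
      lo <- As[i]; hi <- As[i + 1]
      flo <- ind[i]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- .boundary_indicator(mid, p, sc, boundary)
        if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      out[[length(out) + 1]] <- data.frame(A = (lo + hi) / 2, B = B)
    }
  }
  if (!length(out)) return(data.frame(A = numeric(0), B = numeric(0)))
  do.call(rbind, out)
}
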