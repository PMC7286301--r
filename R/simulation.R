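#' Simulation configuration
#'
#' Settings for integrating the stochastic network model. The stochastic
#' forcing perturbs the extracortical input P of every node independently;
#' under the default \code{noise_mode = "sde"} the Euler-Maruyama per-step
#' increment is \code{noise_std * sqrt(dt) * xi} with standard normal xi
#' (so \code{noise_std} is a Wiener intensity in Hz). The alternative
#' \code{"per_step"} reading adds a value with standard deviation
#' \code{noise_std} at every step regardless of dt.
#'
#' @param dt integration time step (s); default 1e-4.
#' @param t_total simulated duration (s); default 20 s (over 100 cycles of
#'   ~10 Hz activity, enough for stable phase statistics).
#' @param t_transient initial window discarded before analysis (s).
#' @param noise_std standard deviation of the extracortical input noise
#'   (Hz); default 0.1.
#' @param n_realisations number of independent realisations for ensembles.
#' @param seed RNG seed; realisation r uses a sub-seed drawn reproducibly
#'   from this seed.
#' @param ic_law initial-condition law: \code{"uniform"} draws each PSP
#'   component uniformly within \code{ic_width} mV of the equilibrium
#'   (derivative components zero); \code{"equilibrium"} starts exactly at
#'   the equilibrium.
#' @param ic_width half-width of the uniform initial-condition box (mV).
#' @param sample_rate output sampling rate (Hz); the raw integration grid is
#'   needed for accuracy, not for phase estimation of sub-50 Hz rhythms, so
#'   output is downsampled (default 1000 Hz).
#' @param noise_mode \code{"sde"} or \code{"per_step"} (see above).
#' @param method \code{"euler"} (Euler-Maruyama; required when noise is on)
#'   or \code{"rk4"} (deterministic runs).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(dt = 1e-4, t_total = 20, t_transient = 5,
                       noise_std = 0.1, n_realisations = 1, seed = 1,
                       ic_law = c("uniform", "equilibrium"), ic_width = 2,
                       sample_rate = 1000,
                       noise_mode = c("sde", "per_step"),
                       method = c("euler", "rk4")) {
  ic_law <- match.arg(ic_law)
  noise_mode <- match.arg(noise_mode)
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  if (t_transient >= t_total) stop("t_transient must be less than t_total")
  if (noise_std < 0) stop("noise_std must be nonnegative")
  if (noise_std > 0 && method == "rk4")
    stop("stochastic runs require method = 'euler' (Euler-Maruyama)")
  keep_every <- max(1L, as.integer(round(1 / (sample_rate * dt))))
  structure(list(dt = dt, t_total = t_total, t_transient = t_transient,
                 noise_std = noise_std,
                 n_realisations = as.integer(n_realisations),
                 seed = seed, ic_law = ic_law, ic_width = ic_width,
                 sample_rate = 1 / (keep_every * dt),
                 keep_every = keep_every,
                 noise_mode = noise_mode, method = method),
            class = "sim_config")
}

#' Node time series container
#'
#' @param y N x M matrix of pyramidal potentials y = y1 - y2 (mV), one row
#'   per node, uniformly sampled.
#' @param dt sampling step (s).
#' @param t0 time of the first retained sample (s).
#' @return an object of class \code{node_time_series}.
#' @export
node_time_series <- function(y, dt, t0 = 0) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  stopifnot(ncol(y) >= 2, all(is.finite(y)), dt > 0)
  structure(list(y = y, dt = dt, t0 = t0), class = "node_time_series")
}

#' @export
print.node_time_series <- function(x, ...) {
  cat(sprintf("node_time_series: %d nodes x %d samples at %.6g s (%.4g s)\n",
              nrow(x$y), ncol(x$y), x$dt, ncol(x$y) * x$dt))
  invisible(x)
}

# draw an initial N x 6 state per the configured law, around equilibrium eq
.draw_ic <- function(n, eq, config) {
  st <- matrix(rep(eq, each = n), n, 6)
  if (config$ic_law == "uniform") {
    st[, 1:3] <- st[, 1:3] +
      matrix(stats::runif(3 * n, -config$ic_width, config$ic_width), n, 3)
  }
  st
}

#' Integrate one realisation of the network model
#'
#' Euler-Maruyama (or RK4 when deterministic) integration of the coupled
#' Jansen-Rit network, discarding the transient and returning the
#' downsampled observable y = y1 - y2 for every node. The run is fully
#' reproducible from \code{config$seed}.
#'
#' @param params a \code{jr_params}.
#' @param sc a row-normalised \code{structural_connectome} (or \code{NULL}
#'   for uncoupled nodes, in which case \code{n_nodes} gives the count).
#' @param config a \code{sim_config}.
#' @param state0 optional N x 6 initial state; overrides the configured
#'   initial-condition law.
#' @param n_nodes number of nodes when \code{sc} is \code{NULL}.
#' @return a \code{node_time_series}; the final N x 6 state is attached as
#'   attribute \code{"final_state"}.
#' @export
jr_simulate <- function(params, sc, config = sim_config(), state0 = NULL,
                        n_nodes = 1) {
  n <- if (is.null(sc)) n_nodes else sc$n_nodes
  w <- if (is.null(sc)) matrix(0, n, n) else sc$weights
  if (!is.null(sc) && !sc$is_row_normalised && params$eps != 0)
    warning("connectome is not row-normalised; homogeneous-equilibrium ",
            "analyses assume unit row sums")
  n_steps <- as.integer(round(config$t_total / config$dt))
  n_discard <- as.integer(round(config$t_transient / config$dt))
  withr::with_seed(config$seed, {
    if (is.null(state0)) {
      eqs <- find_fixed_point(params, sc = if (is.null(sc)) NULL else sc)
      state0 <- .draw_ic(n, eqs$states[[1]], config)
    }
    res <- jr_integrate_cpp(state0, w, .par_vec(params), params$eps,
                            config$dt, n_steps, n_discard,
                            config$keep_every, config$noise_std,
                            if (config$noise_mode == "sde") 1L else 2L,
                            if (config$method == "euler") 0L else 1L)
    ts <- node_time_series(res$y, dt = config$keep_every * config$dt,
                           t0 = config$t_transient)
    attr(ts, "final_state") <- res$state
    ts
  })
}

#' Run an ensemble of independent realisations
#'
#' Repeats \code{\link{jr_simulate}} with initial conditions (and noise)
#' drawn independently per realisation. Realisation r uses a sub-seed drawn
#' once from \code{config$seed} via \code{sample.int}, so the ensemble is
#' reproducible as a set and each member individually.
#'
#' @inheritParams jr_simulate
#' @return list of \code{node_time_series}, one per realisation.
#' @export
run_ensemble <- function(params, sc, config = sim_config(), n_nodes = 1) {
  stopifnot(config$n_realisations >= 1)
  sub_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, config$n_realisations))
  lapply(seq_len(config$n_realisations), function(r) {
    cfg <- config
    cfg$seed <- sub_seeds[r]
    jr_simulate(params, sc, cfg, n_nodes = n_nodes)
  })
}
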