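#' Sweep the (A, B) plane: SC-FC similarity and stability diagnostics
#'
#' For every grid cell: classifies the network equilibrium (eigenmode
#' spectra); where the equilibrium is oscillatory-unstable, simulates an
#' ensemble of noisy realisations, estimates mean-phase-coherence FC,
#' averages over realisations, binarises at the structural edge density, and
#' records the Jaccard similarity against the binarised SC; additionally
#' records the weakly-coupled synchrony indicator H'(0) where the phase
#' reduction is available. Cells without oscillations carry NA similarity.
#'
#' @param params a \code{jr_params} (A, B overridden per cell).
#' @param sc row-normalised \code{structural_connectome} driving the
#'   dynamics.
#' @param sc_binary binarised \code{structural_connectome} used as the
#'   Jaccard reference.
#' @param A_values,B_values grid vectors (mV).
#' @param config a \code{sim_config} (its \code{n_realisations} and seed
#'   govern the per-cell ensembles; per-cell seeds are derived from it).
#' @param density edge density for FC binarisation (default: the binarised
#'   SC's density).
#' @param with_wco also compute H'(0) per oscillatory cell (slower).
#' @return data frame with one row per cell: A, B, label, n_equilibria,
#'   leading_re, jaccard, hprime0.
#' @export
sweep_ab <- function(params, sc, sc_binary, A_values, B_values,
                     config = sim_config(), density = NULL,
                     with_wco = FALSE) {
  if (is.null(density)) density <- sc_binary$edge_density
  grid <- expand.grid(A = A_values, B = B_values)
  cell_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$A <- grid$A[i]
    p$B <- grid$B[i]
    out <- data.frame(A = p$A, B = p$B, label = NA_character_,
                      n_equilibria = NA_integer_, leading_re = NA_real_,
                      jaccard = NA_real_, hprime0 = NA_real_)
    tryCatch({
      cl <- classify_point(p, sc)
      out$label <- cl$label
      out$n_equilibria <- cl$n_equilibria
      out$leading_re <- Re(cl$leading_eigenvalue)
      if (cl$label == "hopf_unstable") {
        cfg <- config
        cfg$seed <- cell_seeds[i]
        ens <- run_ensemble(p, sc, cfg)
        fcs <- lapply(ens, function(ts)
          mean_phase_coherence(extract_phases(ts)))
        fc_bin <- binarise_fc(average_fc(fcs), density)
        out$jaccard <- jaccard_binary(fc_bin, sc_binary)
        if (with_wco) {
          red <- phase_reduction(p)
          out$hprime0 <- red$H_prime0
        }
      }
      out
    }, error = function(e) {
      warning(sprintf("cell (A=%g, B=%g) failed: %s", p$A, p$B,
                      conditionMessage(e)))
      out
    })
  })
  do.call(rbind, rows)
}

# initial full-model state with every node placed on the single-node limit
# cycle at a prescribed phase
.cycle_state_at_phases <- function(cycle, phases) {
  K <- nrow(cycle$y_samples)
  idx <- (round((phases %% (2 * pi)) / (2 * pi) * K) %% K) + 1
  cycle$y_samples[idx, , drop = FALSE]
}

#' Compare weakly-coupled and full-model functional connectivity
#'
#' For each coupling strength: draws random initial phases, runs the full
#' Jansen-Rit network (noise-free, nodes initialised on the limit cycle at
#' those phases) and the reduced phase model from the same phases, averages
#' mean-phase-agreement FC over realisations for both, binarises both at a
#' matched density, and returns the Jaccard similarity. Pairing the initial
#' conditions isolates the reduction error from initial-condition sampling
#' error.
#'
#' @param params a \code{jr_params} with (A, B) in the oscillatory region.
#' @param sc row-normalised \code{structural_connectome}.
#' @param eps_list coupling strengths to compare.
#' @param config a \code{sim_config}; \code{noise_std} must be 0.
#' @param density binarisation edge density.
#' @param red optional precomputed \code{phase_reduction}.
#' @return data frame: eps, jaccard, plus the two average FC matrices in
#'   attribute \code{"fc"} (a list per eps with entries full, wco).
#' @export
compare_wco_full <- function(params, sc, eps_list = c(0.01, 0.1, 1),
                             config = sim_config(noise_std = 0,
                                                 t_total = 6,
                                                 t_transient = 0.5,
                                                 n_realisations = 6),
                             density = 0.23, red = NULL) {
  if (config$noise_std != 0)
    stop("weakly coupled comparison is defined for noise-free dynamics")
  if (is.null(red)) red <- phase_reduction(params)
  n <- sc$n_nodes
  theta_sets <- withr::with_seed(config$seed,
    replicate(config$n_realisations,
              stats::runif(n, 0, 2 * pi), simplify = FALSE))
  t_post <- config$t_total - config$t_transient
  fc_store <- list()
  res <- lapply(eps_list, function(eps) {
    p <- params
    p$eps <- eps
    full_fcs <- list()
    wco_fcs <- list()
    for (r in seq_along(theta_sets)) {
      th0 <- theta_sets[[r]]
      st0 <- .cycle_state_at_phases(red$cycle, th0)
      ts <- jr_simulate(p, sc, config, state0 = st0)
      full_fcs[[r]] <- mean_phase_agreement(extract_phases(ts))
      ph <- simulate_phase_model(red, sc, eps, theta0 = th0,
                                 t_total = config$t_total,
                                 sample_rate = config$sample_rate)
      keep <- which((seq_len(ncol(ph$theta)) - 1) * ph$dt_sample >=
                      config$t_transient)
      wco_fcs[[r]] <- mean_phase_agreement(
        phase_series(ph$theta[, keep, drop = FALSE], ph$dt_sample))
    }
    full_avg <- average_fc(full_fcs)
    wco_avg <- average_fc(wco_fcs)
    fc_store[[as.character(eps)]] <<- list(full = full_avg, wco = wco_avg)
    data.frame(eps = eps,
               jaccard = jaccard_binary(binarise_fc(full_avg, density),
                                        binarise_fc(wco_avg, density)))
  })
  out <- do.call(rbind, res)
  attr(out, "fc") <- fc_store
  out
}

#' Eigenmode FC prediction versus direct simulation
#'
#' Computes the eigenmode predictor of FC at synchrony (all N modes) and a
#' noise-free full-model mean-phase-agreement FC averaged over random
#' initial phase realisations, both min-max scaled to [0, 1], and returns
#' their weighted Jaccard similarity.
#'
#' @inheritParams compare_wco_full
#' @param eps coupling strength.
#' @return list: \code{jaccard_weighted}, \code{predicted}
#'   (\code{fc_matrix}), \code{simulated} (\code{fc_matrix}).
#' @export
predict_vs_simulate <- function(params, sc, eps = 0.1,
                                config = sim_config(noise_std = 0,
                                                    t_total = 6,
                                                    t_transient = 0.5,
                                                    n_realisations = 6),
                                red = NULL) {
  if (config$noise_std != 0)
    stop("prediction comparison is defined for noise-free dynamics")
  if (is.null(red)) red <- phase_reduction(params)
  pred <- eigenmode_fc_prediction(sc, red, eps)
  p <- params
  p$eps <- eps
  theta_sets <- withr::with_seed(config$seed,
    replicate(config$n_realisations,
              stats::runif(sc$n_nodes, 0, 2 * pi), simplify = FALSE))
  fcs <- lapply(theta_sets, function(th0) {
    st0 <- .cycle_state_at_phases(red$cycle, th0)
    ts <- jr_simulate(p, sc, config, state0 = st0)
    mean_phase_agreement(extract_phases(ts))
  })
  sim <- average_fc(fcs)
  list(jaccard_weighted = jaccard_weighted(pred, sim),
       predicted = pred, simulated = sim)
}
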