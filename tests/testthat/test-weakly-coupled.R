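test_that("the adjoint is periodic and normalised against the vector field", {
  red <- red_9_22()
  cyc <- red$cycle
  Q <- red$Q
  # Q . F = Omega at every sample
  Fv <- network_rhs(cyc$y_samples, cyc$params, sc = NULL,
                    drive = rep(cyc$params$P, nrow(cyc$y_samples)))
  cF <- rowSums(Q * Fv)
  expect_lt(max(abs(cF / cyc$Omega - 1)), 1e-6)
  expect_lt(attr(Q, "normalisation_spread"), 1e-6)
})

test_that("the adjoint predicts phase shifts from small impulses", {
  red <- red_9_22()
  cyc <- red$cycle
  p <- cyc$params
  K <- nrow(cyc$y_samples)
  delta <- 1  # mV/s, small against the ~1e3 mV/s swing of y4 on the cycle
  mean_level <- mean(cyc$y_samples[, 2] - cyc$y_samples[, 3])
  # mean fractional crossing position over several cycles, 3 s after impulse
  run <- function(s0) {
    X <- jrconnect:::jr_single_states_cpp(s0, jrconnect:::.par_vec(p),
                                          1e-4, 40000, 30000, 1L)
    yc <- (X[, 2] - X[, 3]) - mean_level
    s <- sign(yc)
    i <- which(s[-1] > 0 & s[-length(s)] <= 0)[1:8]
    mean((i - 1) + (-yc[i]) / (yc[i + 1] - yc[i]) -
           (seq_along(i) - 1) * cyc$period / 1e-4)
  }
  for (frac in c(0.15, 0.6)) {
    k <- round(frac * K) + 1
    st <- cyc$y_samples[k, ]
    stp <- st
    stp[5] <- stp[5] + delta          # impulse on the y4 component
    predicted <- red$Q[k, 5] * delta  # Q is the phase gradient (rad)
    dt_shift <- (run(st) - run(stp)) * 1e-4
    measured <- wrap_pi(dt_shift * cyc$Omega)
    expect_lt(abs(measured - predicted) / abs(predicted), 0.05)
  }
})

test_that("H is periodic, nonvanishing at the origin, and spectrally differentiated", {
  red <- red_9_22()
  expect_equal(eval_H(red, 0), eval_H(red, 2 * pi), tolerance = 1e-10)
  expect_gt(abs(red$H0), 0.01)   # H(0) does not vanish for this coupling
  # spectral derivative agrees with centered differences
  K <- red$K
  h <- 2 * pi / K
  cd <- (red$H[c(2:K, 1)] - red$H[c(K, 1:(K - 1))]) / (2 * h)
  expect_lt(max(abs(red$Hd - cd)), 1e-4 * max(abs(red$Hd)))
})

test_that("synchrony analysis: frequency offset, stability flag, phase-model confirmation", {
  red <- red_9_22()
  ss0 <- synchrony_stability(red, eps = 0)
  expect_equal(ss0$emergent_frequency, red$Omega)

  ss <- synchrony_stability(red, eps = 0.1)
  expect_true(ss$stable)   # eps H'(0) > 0 at A=9, B=22
  expect_equal(ss$indicator, 0.1 * red$H_prime0)

  # phase model from near-uniform phases converges to synchrony
  g6 <- fixture_network("global", 6)
  th0 <- withr::with_seed(3, runif(6, 0, 0.1))
  ph <- simulate_phase_model(red, g6, eps = 0.5, theta0 = th0, t_total = 150)
  expect_true(ph$locked)
  expect_lt(max(abs(wrap_pi(outer(ph$Phi, ph$Phi, "-")))), 1e-3)

  # where eps H'(0) < 0, a tiny perturbation off synchrony grows
  red5 <- red_5_19()
  expect_false(synchrony_stability(red5, eps = 0.5)$stable)
  th0 <- withr::with_seed(4, runif(6, 0, 1e-3))
  ph5 <- simulate_phase_model(red5, g6, eps = 0.5, theta0 = th0, t_total = 40)
  spread0 <- max(abs(wrap_pi(outer(th0, th0, "-"))))
  spread1 <- max(abs(wrap_pi(outer(ph5$Phi, ph5$Phi, "-"))))
  expect_gt(spread1, 10 * spread0)
})

test_that("phase model decouples at eps = 0 and preserves exact synchrony", {
  red <- red_9_22()
  sc <- fixture_network("ring", 5)
  th0 <- withr::with_seed(5, runif(5, 0, 2 * pi))
  ph <- simulate_phase_model(red, sc, eps = 0, theta0 = th0, t_total = 1)
  M <- ncol(ph$theta)
  t_end <- (M - 1) * ph$dt_sample
  expect_equal(ph$theta[, M], th0 + red$Omega * t_end, tolerance = 1e-9)

  # identical initial phases on a unit-row-sum network stay identical
  ph2 <- simulate_phase_model(red, sc, eps = 0.3,
                              theta0 = rep(1.1, 5), t_total = 2)
  expect_lt(max(abs(ph2$theta[, ncol(ph2$theta)] -
                      ph2$theta[1, ncol(ph2$theta)])), 1e-10)
})

test_that("two-node phase-model lock matches the root of the antisymmetric H equation", {
  red <- red_9_22()
  tn <- fixture_network("two_node")
  ph <- simulate_phase_model(red, tn, eps = 0.2, theta0 = c(0.7, 0),
                             t_total = 200)
  chi_sim <- wrap_pi(ph$Phi[1] - ph$Phi[2])
  g <- function(chi) eval_H(red, -chi) - eval_H(red, chi)
  # nearest root of g to the simulated lock
  root <- stats::uniroot(g, c(chi_sim - 0.3, chi_sim + 0.3),
                         extendInt = "yes")$root
  expect_lt(abs(chi_sim - root), 1e-4)
})

test_that("the phase-locked Jacobian matches structure, Laplacian limit, and finite differences", {
  red <- red_9_22()
  sc <- sc_mod10()$norm
  n <- sc$n_nodes

  # at synchrony the Jacobian is exactly -eps H'(0) L
  eps <- 0.1
  pj <- phase_locked_jacobian(rep(0, n), sc, red, eps)
  L <- graph_laplacian(sc)
  expect_equal(pj$jacobian, -eps * red$H_prime0 * L, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(pj$jacobian))), 1e-10)
  expect_equal(sum(Mod(pj$eigenvalues) < 1e-10), 1)  # one symmetry zero

  # generic locked state (a twisted/antiphase ring pattern): eigenvalues
  # match a centered-difference Jacobian of the phase vector field
  ring6 <- fixture_network("ring", 6)
  nr <- 6
  ph <- simulate_phase_model(red_5_19(), ring6, eps = 0.2,
                             theta0 = withr::with_seed(6, runif(nr, 0, 2 * pi)),
                             t_total = 300)
  expect_true(ph$locked)
  expect_gt(max(abs(wrap_pi(outer(ph$Phi, ph$Phi, "-")))), 0.5)  # non-uniform
  pj2 <- phase_locked_jacobian(ph$Phi, ring6, red_5_19(), 0.2)
  rhs <- function(th) {
    D <- outer(th, th, function(a, b) b - a)
    red_5_19()$Omega + 0.2 * rowSums(ring6$weights *
                                       matrix(eval_H(red_5_19(), D), nr, nr))
  }
  h <- 1e-6
  Jfd <- matrix(0, nr, nr)
  for (j in seq_len(nr)) {
    e <- rep(0, nr); e[j] <- h
    Jfd[, j] <- (rhs(ph$Phi + e) - rhs(ph$Phi - e)) / (2 * h)
  }
  ev_fd <- sort(Re(eigen(Jfd, only.values = TRUE)$values))
  ev_an <- sort(Re(pj2$eigenvalues))
  expect_lt(max(abs(ev_fd - ev_an)), 1e-5)

  # a non-stationary state is rejected
  expect_error(phase_locked_jacobian(withr::with_seed(8, runif(n, 0, 2 * pi)),
                                     sc, red, eps), "not a phase-locked")
})

test_that("eigenmode FC prediction respects symmetry and planted modules", {
  red <- red_5_19()
  g5 <- fixture_network("global", 5)
  pred_g <- eigenmode_fc_prediction(g5, red, eps = 0.1)
  off <- pred_g$values[row(pred_g$values) != col(pred_g$values)]
  expect_lt(diff(range(off)), 1e-8)   # complete permutation symmetry

  # module contrast needs the synchrony-stable side (eps H'(0) > 0), where
  # the reconstruction weights connected pairs positively
  sc <- sc_mod10()
  pred <- eigenmode_fc_prediction(sc$norm, red_9_22(), eps = 0.2)
  v <- pred$values
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_true(all(v[row(v) != col(v)] >= 0 & v[row(v) != col(v)] <= 1))
  same <- outer(sc$modules, sc$modules, "==") & (row(v) != col(v))
  expect_gt(mean(v[same]), mean(v[!outer(sc$modules, sc$modules, "==")]))

  # restricting to fewer modes still returns a valid matrix
  pred2 <- eigenmode_fc_prediction(sc$norm, red, eps = 0.2, n_modes = 3)
  expect_true(all(is.finite(pred2$values)))
})
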