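test_that("phase extraction recovers the analytic phases of sinusoids", {
  dt <- 1e-3
  t <- seq(0, 2 - dt, by = dt)
  y <- rbind(cos(2 * pi * 10 * t),
             cos(2 * pi * 10 * t),                 # identical copy
             cos(2 * pi * 10 * (t - 0.025)))       # quarter period later
  ph <- extract_phases(node_time_series(y, dt))
  # unwrapped slope of a 10 Hz cosine is 2*pi*10 rad/s
  phi <- ph$phi[1, ]
  un <- cumsum(c(phi[1], wrap_pi(diff(phi))))
  slope <- stats::coef(stats::lm(un ~ seq_along(un)))[[2]] / dt
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # identical series: zero phase difference at every retained sample
  expect_lt(max(abs(ph$phi[1, ] - ph$phi[2, ])), 1e-10)
  # quarter-period shift: constant difference of pi/2
  d13 <- wrap_pi(ph$phi[1, ] - ph$phi[3, ])
  expect_lt(max(abs(d13 - pi / 2)), 0.05)

  expect_error(extract_phases(matrix(1, 2, 100)), "constant")
  expect_error(extract_phases(matrix(rnorm(10), 1, 10)), "16 samples")
})

test_that("MPC and MPA reproduce their closed-form values", {
  mk <- function(d) phase_series(rbind(d, rep(0, length(d))))
  # constant difference (any value): MPC = 1
  expect_equal(mean_phase_coherence(mk(rep(1.3, 50)))$values[1, 2], 1,
               tolerance = 1e-12)
  # antipodal samples {0, pi}: MPC = 0
  expect_equal(mean_phase_coherence(mk(rep(c(0, pi), 25)))$values[1, 2], 0,
               tolerance = 1e-12)
  # {0, pi/2}: MPC = |(1 + i)/2| = sqrt(2)/2
  expect_equal(mean_phase_coherence(mk(rep(c(0, pi / 2), 25)))$values[1, 2],
               sqrt(2) / 2, tolerance = 1e-12)
  # MPA: synchrony 1, antiphase 0, mixed {0, pi} -> 1/2
  expect_equal(mean_phase_agreement(mk(rep(0, 50)))$values[1, 2], 1,
               tolerance = 1e-12)
  expect_equal(mean_phase_agreement(mk(rep(pi, 50)))$values[1, 2], 0,
               tolerance = 1e-12)
  expect_equal(mean_phase_agreement(mk(rep(c(0, pi), 24)))$values[1, 2], 0.5,
               tolerance = 1e-12)
  # locked at difference c: MPC = 1 and MPA = (1 + cos c)/2
  for (cc in c(0.4, 1.9, 3.0)) {
    expect_equal(mean_phase_coherence(mk(rep(cc, 40)))$values[1, 2], 1,
                 tolerance = 1e-12)
    expect_equal(mean_phase_agreement(mk(rep(cc, 40)))$values[1, 2],
                 (1 + cos(cc)) / 2, tolerance = 1e-12)
  }
})

test_that("both synchrony metrics are invariant to a global phase shift", {
  phi <- withr::with_seed(4, matrix(runif(3 * 200, 0, 2 * pi), 3, 200))
  shift <- matrix(rep(runif(200, 0, 2 * pi), each = 3), 3, 200)
  a <- mean_phase_coherence(phase_series(phi))$values
  b <- mean_phase_coherence(phase_series(phi + shift))$values
  expect_equal(a, b, tolerance = 1e-12)
  am <- mean_phase_agreement(phase_series(phi))$values
  bm <- mean_phase_agreement(phase_series(phi + shift))$values
  expect_equal(am, bm, tolerance = 1e-12)
})

test_that("binarise_fc matches the requested edge count and separates values", {
  n <- 10
  vals <- withr::with_seed(9, matrix(runif(n * n), n, n))
  vals <- (vals + t(vals)) / 2
  fc <- fc_matrix(vals)
  b <- binarise_fc(fc, 0.23)
  expect_equal(sum(b$values[row(b$values) != col(b$values)]),
               2 * floor(0.23 * n * (n - 1) / 2))
  expect_true(b$is_binarised)
  expect_equal(b$values, t(b$values))

  # density 1: all off-diagonal entries retained
  ball <- binarise_fc(fc, 1)
  expect_true(all(ball$values == 1))

  # two distinct values with the cutoff between their counts
  v2 <- matrix(0.2, 4, 4); v2[1, 2] <- v2[2, 1] <- 0.9; diag(v2) <- 1
  b2 <- binarise_fc(fc_matrix(v2), 1 / 6)   # keep exactly 1 of 6 pairs
  expect_equal(b2$values[1, 2], 1)
  expect_equal(sum(b2$values[upper.tri(b2$values)]), 1)
})

test_that("binary and weighted Jaccard reproduce counting examples", {
  m <- function(pairs, n = 3) {
    x <- matrix(0, n, n)
    for (p in pairs) { x[p[1], p[2]] <- 1; x[p[2], p[1]] <- 1 }
    x
  }
  expect_equal(jaccard_binary(m(list(c(1, 2), c(1, 3))),
                              m(list(c(1, 2), c(1, 3)))), 1)
  expect_equal(jaccard_binary(m(list(c(1, 2))), m(list(c(1, 3)))), 0)
  # {ab, ac} vs {ab, bc}: intersection 1, union 3
  expect_equal(jaccard_binary(m(list(c(1, 2), c(1, 3))),
                              m(list(c(1, 2), c(2, 3)))), 1 / 3)
  expect_error(jaccard_binary(m(list()), m(list())), "empty")

  # weighted: x = y gives 1; pairwise (0.2, 0.8) vs (0.4, 0.4) on a common
  # scale gives (0.2 + 0.4) / (0.4 + 0.8) = 0.5
  x <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0, 0.8, 0, 0), 3, 3)
  expect_equal(jaccard_weighted(x, x), 1)
  y <- matrix(c(0, 0.4, 0.4, 0.4, 0, 0, 0.4, 0, 0), 3, 3)
  expect_equal(jaccard_weighted(x, y, rescale = FALSE),
               (0.2 + 0.4 + 0) / (0.4 + 0.8 + 0))
  # y identically zero against nonzero x gives 0
  expect_equal(jaccard_weighted(x, matrix(0, 3, 3), rescale = FALSE), 0)
})

test_that("MPC and MPA agree where locking carries nontrivial structure", {
  # in a regime of structured (non-synchronous) locking both metrics rank
  # node pairs consistently; at uniformly high coherence MPC saturates while
  # MPA still resolves lag magnitudes, which is exactly why MPA exists
  p <- jr_params(A = 5, B = 19)
  sc <- fixture_network("ring", 10)
  cfg <- sim_config(t_total = 20, t_transient = 5, seed = 21)
  ts <- jr_simulate(p, sc, cfg)
  ph <- extract_phases(ts)
  dens <- 0.3
  bc <- binarise_fc(mean_phase_coherence(ph), dens)
  ba <- binarise_fc(mean_phase_agreement(ph), dens)
  expect_gte(jaccard_binary(bc, ba), 0.9)
})
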