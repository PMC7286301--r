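test_that("load_connectome reads matrices back and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 0"), f)
  sc <- load_connectome(f)
  expect_equal(sc$n_nodes, 2)
  expect_equal(sc$weights, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sc$edge_density, 1)

  writeLines(c("0 -1", "-1 0"), f)
  expect_error(load_connectome(f), "negative weight")

  writeLines(c("0 1 2 3", "1 0 1 2", "2 1 0 1"), f)
  expect_error(load_connectome(f), "non-square")

  writeLines(c("0 NaN", "1 0"), f)
  expect_error(load_connectome(f), "NaN")

  # round trip through write_connectome
  sc2 <- generate_modular_sc(connectome_recipe(n_nodes = 8, n_modules = 2,
                                               seed = 3))
  write_connectome(sc2, f)
  expect_equal(load_connectome(f)$weights, sc2$weights, tolerance = 1e-12)
})

test_that("threshold_binarise keeps the strongest pairs with the stable tie rule", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 4
  w[1, 4] <- w[4, 1] <- 3
  w[2, 3] <- w[3, 2] <- 2
  w[2, 4] <- w[4, 2] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  sc <- structural_connectome(w)
  b <- suppressWarnings(threshold_binarise(sc, 1 / 3))  # sparse: disconnects
  expect_equal(sum(b$weights) / 2, 2)  # floor(6/3) = 2 edges
  expect_equal(b$weights[1, 2], 1)
  expect_equal(b$weights[1, 3], 1)
  expect_equal(b$weights[1, 4], 0)

  # density = 1 keeps every nonzero pair
  ball <- suppressWarnings(threshold_binarise(sc, 1))
  expect_equal(ball$weights != 0, w != 0)

  # tie straddling the cutoff: brute-force ordered pair list as oracle
  wt <- matrix(0, 4, 4)
  vals <- c(5, 3, 3, 3, 2, 1)  # pairs (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  ut <- which(upper.tri(wt), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), ]
  wt[ut] <- vals
  wt <- wt + t(wt)
  sct <- structural_connectome(wt)
  bt <- suppressWarnings(threshold_binarise(sct, 0.5))  # keep floor(3) = 3
  ord <- order(-vals, ut[, 1], ut[, 2])                 # documented tie rule
  expected <- matrix(0, 4, 4)
  expected[ut[ord[1:3], , drop = FALSE]] <- 1
  expected <- expected + t(expected)
  expect_equal(bt$weights, expected)
  expect_error(threshold_binarise(sct, 0), "density")
  expect_error(threshold_binarise(structural_connectome(matrix(0, 3, 3)),
                                  0.5), "all-zero")
})

test_that("row_normalise yields unit rows, is idempotent, flags zero rows", {
  w <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3)
  sc <- row_normalise(structural_connectome(w))
  expect_true(all(abs(rowSums(sc$weights) - 1) < 1e-12))
  expect_equal(sc$weights[1, ], c(0, 0.5, 0.5))
  sc2 <- row_normalise(sc)
  expect_equal(sc2$weights, sc$weights, tolerance = 1e-12)

  w0 <- matrix(0, 3, 3); w0[1, 2] <- w0[2, 1] <- 1
  expect_error(row_normalise(structural_connectome(w0)), "node.*3")
})

test_that("graph_laplacian has zero row sums and the expected spectrum", {
  sc2 <- fixture_network("two_node")
  L2 <- graph_laplacian(sc2)
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(L2, only.values = TRUE)$values), c(0, 2))

  # idealised global coupling w_ij = 1/N including the diagonal:
  # L = I - J/N with eigenvalues {0, 1 x (N-1)}
  n <- 6
  Lg <- graph_laplacian(matrix(1 / n, n, n))
  expect_equal(sort(Re(eigen(Lg, only.values = TRUE)$values)),
               c(0, rep(1, n - 1)), tolerance = 1e-12)

  for (seed in 1:5) {
    sc <- random_sc(6, seed)
    L <- graph_laplacian(sc)
    expect_lt(max(abs(rowSums(L))), 1e-12)
    ev <- eigen(L, only.values = TRUE)$values
    expect_lt(max(abs(Im(ev))), 1e-8)           # real spectrum
    expect_equal(sum(abs(ev) < 1e-10), 1)       # single zero mode
    expect_true(all(Re(ev[abs(ev) > 1e-10]) > 0))
  }
})

test_that("threshold + normalise pipeline is permutation-equivariant", {
  raw <- generate_modular_sc(connectome_recipe(n_nodes = 12, n_modules = 3,
                                               p_in = 0.9, p_out = 0.5,
                                               seed = 5))
  proc <- function(sc)
    row_normalise(suppressWarnings(threshold_binarise(sc, 0.5)))$weights
  base <- proc(raw)
  perm <- withr::with_seed(8, sample(12))
  permuted <- structural_connectome(raw$weights[perm, perm])
  expect_equal(proc(permuted), base[perm, perm], tolerance = 1e-12)
})
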