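# Shared fixtures. Heavy objects (phase reductions, limit cycles) are
# memoised so several test files can reuse them without recomputation.

.jrc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.jrc_cache[[key]])) assign(key, force(expr), envir = .jrc_cache)
  .jrc_cache[[key]]
}

red_9_22 <- function() cached("red922",
  phase_reduction(jr_params(A = 9, B = 22)))

red_5_19 <- function() cached("red519",
  phase_reduction(jr_params(A = 5, B = 19)))

cycle_9_22 <- function() red_9_22()$cycle

# fixed-seed 10-node two-module surrogate connectome, processed like the
# empirical pipeline (threshold, binarise, row-normalise)
sc_mod10 <- function() cached("scmod10", {
  raw <- generate_modular_sc(connectome_recipe(
    n_nodes = 10, n_modules = 2, p_in = 0.9, p_out = 0.3, seed = 11))
  bin <- threshold_binarise(raw, 0.4)
  list(raw = raw, bin = bin, norm = row_normalise(bin),
       modules = attr(raw, "modules"))
})

# random symmetric nonnegative SC with zero diagonal, row-normalised
random_sc <- function(n, seed) {
  withr::with_seed(seed, {
    w <- matrix(stats::runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    row_normalise(structural_connectome(w))
  })
}

# oscillation period from upward mean-level crossings of a sampled series
est_period <- function(y, dt) {
  yc <- y - mean(y)
  s <- sign(yc)
  idx <- which(s[-1] > 0 & s[-length(s)] <= 0)
  stopifnot(length(idx) >= 3)
  tc <- (idx - 1) * dt + dt * (-yc[idx]) / (yc[idx + 1] - yc[idx])
  mean(diff(tc))
}

wrap_pi <- function(x) atan2(sin(x), cos(x))
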