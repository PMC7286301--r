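#' Recipe for a surrogate modular structural connectome
#'
#' Describes a weighted stochastic-block-model surrogate of a
#' tractography-derived connectome: nodes are split into modules, edges are
#' drawn with probability \code{p_in} within and \code{p_out} between
#' modules, and present edges receive heavy-tailed weights (lognormal by
#' default, emulating streamline-count distributions). The default scale
#' (78 nodes, matching the AAL parcellation used for the empirical
#' connectome) and the default probabilities leave the raw density above the
#' 0.23 retention fraction used at the thresholding stage.
#'
#' @param n_nodes number of nodes (default 78).
#' @param n_modules number of modules (default 4).
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability; must not exceed \code{p_in}.
#' @param weight_law list: \code{name} ("lognormal" or "uniform") plus its
#'   parameters (\code{meanlog}, \code{sdlog} or \code{min}, \code{max}).
#' @param seed RNG seed making the generated matrix reproducible.
#' @return an object of class \code{connectome_recipe}.
#' @export
connectome_recipe <- function(n_nodes = 78, n_modules = 4,
                              p_in = 0.6, p_out = 0.15,
                              weight_law = list(name = "lognormal",
                                                meanlog = 0, sdlog = 1),
                              seed = 1) {
  stopifnot(n_nodes >= 2, n_modules >= 1, n_modules <= n_nodes)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_modules = as.integer(n_modules),
                 p_in = p_in, p_out = p_out,
                 weight_law = weight_law, seed = seed),
            class = "connectome_recipe")
}

#' Generate a modular surrogate structural connectome
#'
#' Draws a symmetric, nonnegative, zero-diagonal weighted matrix from the
#' recipe's stochastic block model. Module labels are assigned contiguously
#' (as balanced as possible). The same seed always yields the same matrix.
#'
#' @param recipe a \code{connectome_recipe}.
#' @return a \code{structural_connectome} with attribute \code{"modules"}
#'   giving the planted module label of each node.
#' @export
generate_modular_sc <- function(recipe) {
  stopifnot(inherits(recipe, "connectome_recipe"))
  n <- recipe$n_nodes
  labels <- sort(rep_len(seq_len(recipe$n_modules), n))
  w <- withr::with_seed(recipe$seed, {
    m <- matrix(0, n, n)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    same <- labels[ut[, 1L]] == labels[ut[, 2L]]
    p <- ifelse(same, recipe$p_in, recipe$p_out)
    present <- stats::runif(nrow(ut)) < p
    wl <- recipe$weight_law
    vals <- switch(wl$name,
      lognormal = stats::rlnorm(sum(present), wl$meanlog, wl$sdlog),
      uniform = stats::runif(sum(present), wl$min, wl$max),
      stop("unknown weight law: ", wl$name))
    m[ut[present, , drop = FALSE]] <- vals
    m + t(m)
  })
  if (all(w == 0))
    stop("recipe parameters produced an empty graph")
  sc <- structural_connectome(w)
  attr(sc, "modules") <- labels
  sc
}

#' Small analytic fixture networks
#'
#' Named connectomes with closed-form structure, used for exact checks of
#' downstream analyses:
#' \describe{
#'   \item{global}{all-to-all coupling with equal weights and unit row sums
#'     (off-diagonal entries 1/(N-1)).}
#'   \item{two_node}{the symmetric pair, w12 = w21 = 1.}
#'   \item{ring}{binary cycle graph, row-normalised (each neighbour 1/2).}
#'   \item{path}{binary path graph, row-normalised.}
#' }
#'
#' @param name one of "global", "two_node", "ring", "path".
#' @param n number of nodes (ignored for "two_node").
#' @return a row-normalised \code{structural_connectome}.
#' @export
fixture_network <- function(name, n = 2) {
  w <- switch(name,
    global = {
      stopifnot(n >= 2)
      m <- matrix(1 / (n - 1), n, n); diag(m) <- 0; m
    },
    two_node = matrix(c(0, 1, 1, 0), 2, 2),
    ring = {
      stopifnot(n >= 3)
      m <- matrix(0, n, n)
      for (i in seq_len(n)) {
        m[i, i %% n + 1] <- 1
        m[i %% n + 1, i] <- 1
      }
      m
    },
    path = {
      stopifnot(n >= 2)
      m <- matrix(0, n, n)
      for (i in seq_len(n - 1)) { m[i, i + 1] <- 1; m[i + 1, i] <- 1 }
      m
    },
    stop("unknown fixture network: ", name))
  row_normalise(structural_connectome(w, is_binarised = all(w %in% c(0, 1))))
}
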