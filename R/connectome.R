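#' Construct a structural connectome object
#'
#' A structural connectome holds the weighted coupling matrix of a brain
#' network: entry \code{weights[i, j]} is the coupling strength from node
#' \code{j} to node \code{i}. The diagonal (self-coupling) is forced to zero.
#' Processing provenance (binarisation, row normalisation) is tracked in
#' flags so downstream analyses can assert the preprocessing they require.
#'
#' @param weights numeric N x N matrix, nonnegative, N >= 2.
#' @param is_binarised logical; have the weights been thresholded to 0/1?
#' @param is_row_normalised logical; does every row sum to one?
#' @param check_symmetry logical; require the raw matrix to be symmetric
#'   (within tolerance). Row normalisation of a binary symmetric matrix with
#'   unequal degrees breaks symmetry, so the check is skipped once the
#'   normalised flag is set.
#' @return an object of class \code{structural_connectome} with fields
#'   \code{weights}, \code{n_nodes}, \code{is_binarised},
#'   \code{is_row_normalised}, \code{edge_density}.
#' @export
structural_connectome <- function(weights, is_binarised = FALSE,
                                  is_row_normalised = FALSE,
                                  check_symmetry = !is_row_normalised) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop("non-square connectivity matrix: ", nrow(weights), " x ", ncol(weights))
  if (nrow(weights) < 1) stop("connectome needs at least one node")
  if (anyNA(weights)) stop("NaN or missing entries in connectivity matrix")
  if (any(weights < 0)) stop("negative weight in connectivity matrix")
  diag(weights) <- 0
  if (check_symmetry && !isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)))
    stop("connectivity matrix is not symmetric")
  n <- nrow(weights)
  structure(
    list(weights = unname(weights),
         n_nodes = n,
         is_binarised = is_binarised,
         is_row_normalised = is_row_normalised,
         edge_density = edge_density(weights)),
    class = "structural_connectome")
}

#' Fraction of retained off-diagonal entries
#'
#' @param w square matrix or \code{structural_connectome}.
#' @return fraction in [0, 1] of nonzero off-diagonal entries.
#' @export
edge_density <- function(w) {
  if (inherits(w, "structural_connectome")) w <- w$weights
  n <- nrow(w)
  if (n < 2) return(0)
  off <- w[row(w) != col(w)]
  mean(off != 0)
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("structural_connectome: %d nodes, density %.3f%s%s\n",
              x$n_nodes, x$edge_density,
              if (x$is_binarised) ", binarised" else "",
              if (x$is_row_normalised) ", row-normalised" else ""))
  invisible(x)
}

#' Read a structural connectivity matrix from a delimited text file
#'
#' Reads an N x N numeric matrix (CSV or whitespace-delimited), zeroes the
#' diagonal, and validates it as a connectome. Distinct errors are raised for
#' non-square input, negative weights, and NaN entries.
#'
#' @param path file path to a delimited numeric matrix without header.
#' @param delimiter field separator; \code{""} (default) means any
#'   whitespace, use \code{","} for CSV.
#' @return a \code{structural_connectome}.
#' @export
load_connectome <- function(path, delimiter = "") {
  tab <- utils::read.table(path, header = FALSE, sep = delimiter,
                           colClasses = "numeric")
  w <- as.matrix(tab)
  dimnames(w) <- NULL
  structural_connectome(w)
}

#' Write a connectome weight matrix to a delimited text file
#'
#' @param sc a \code{structural_connectome}.
#' @param path output file path.
#' @param delimiter field separator (default single space).
#' @export
write_connectome <- function(sc, path, delimiter = " ") {
  utils::write.table(sc$weights, path, sep = delimiter,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Rank unordered off-diagonal pairs of a symmetric matrix by weight and
# return the row/column indices of the top `n_keep`. Tie rule: stable sort by
# (weight descending, smaller node index, larger node index) so retention is
# reproducible across platforms.
.top_pairs <- function(w, n_keep) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[ut]
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(n_keep)]
  ut[keep, , drop = FALSE]
}

#' Threshold and binarise a connectome
#'
#' Ranks the undirected edges (unordered node pairs) by weight and retains
#' the strongest fraction \code{density} of all possible pairs, setting them
#' to 1 and the rest to 0. The number of retained edges is
#' \code{floor(density * N(N-1)/2)}. Ties at the cutoff are broken
#' deterministically by (weight desc, smaller index, larger index). The
#' output is symmetric. A warning is emitted if the thresholded graph is
#' disconnected.
#'
#' @param sc a non-binarised \code{structural_connectome}.
#' @param density fraction in (0, 1] of node pairs to retain.
#' @return a binarised \code{structural_connectome}.
#' @export
threshold_binarise <- function(sc, density = 0.23) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (sc$is_binarised) stop("connectome is already binarised")
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1)
    stop("density must be a single value in (0, 1]")
  w <- sc$weights
  if (all(w == 0)) stop("all-zero connectivity matrix cannot be thresholded")
  # symmetrise tiny asymmetries before ranking (raw SC is symmetric)
  w <- (w + t(w)) / 2
  n <- nrow(w)
  n_pairs <- n * (n - 1) / 2
  n_keep <- if (density == 1) sum(w[upper.tri(w)] != 0) else
    floor(density * n_pairs)
  # zero-weight pairs are non-edges, never retained
  n_keep <- min(n_keep, sum(w[upper.tri(w)] != 0))
  b <- matrix(0, n, n)
  if (n_keep > 0) {
    idx <- .top_pairs(w, n_keep)
    b[idx] <- 1
    b[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  out <- structural_connectome(b, is_binarised = TRUE)
  if (!.is_connected(b))
    warning("thresholded connectome is disconnected")
  out
}

# Connectivity of the binary graph via breadth-first search.
.is_connected <- function(b) {
  n <- nrow(b)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(b[v, ] != 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Row-normalise a connectome
#'
#' Divides each row by its sum so that afferent connection strengths for
#' every node sum to unity (row sum Gamma = 1). An isolated node (zero row)
#' is an error because its inputs cannot be normalised.
#'
#' @param sc a \code{structural_connectome}.
#' @return a row-normalised \code{structural_connectome}.
#' @export
row_normalise <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  w <- sc$weights
  rs <- rowSums(w)
  bad <- which(rs == 0)
  if (length(bad))
    stop("cannot row-normalise: zero row for node(s) ",
         paste(bad, collapse = ", "))
  structural_connectome(w / rs, is_binarised = sc$is_binarised,
                        is_row_normalised = TRUE, check_symmetry = FALSE)
}

#' Graph Laplacian of a connectome
#'
#' Returns \code{L = D - W} with \code{L[i, j] = -w[i, j]} off-diagonal and
#' \code{L[i, i] = sum_k w[i, k]}. Row sums are zero, so the all-ones vector
#' is an eigenvector with eigenvalue 0. For a row-normalised connectome
#' derived from a symmetric binary graph the spectrum is real and lies in
#' [0, 2].
#'
#' @param sc a \code{structural_connectome} or square matrix.
#' @return an N x N numeric matrix.
#' @export
graph_laplacian <- function(sc) {
  w <- if (inherits(sc, "structural_connectome")) sc$weights else sc
  diag(rowSums(w)) - w
}
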