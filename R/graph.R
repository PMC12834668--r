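#' RBF guidance matrix
#'
#' Pairwise Gaussian-kernel similarities `P[i,j] = exp(-||z_i - z_j||^2 /
#' (2 sigma^2))` used to guide the adaptive probability graph. When `sigma`
#' is not supplied it is set by the median heuristic over the positive
#' pairwise Euclidean distances; if all rows coincide (median distance 0) it
#' falls back to 1 with a warning.
#'
#' @param Z numeric matrix, cells x dims, N >= 2.
#' @param sigma optional positive bandwidth.
#' @return list with `P` (N x N symmetric, unit diagonal) and `sigma` (the
#'   bandwidth actually used).
#' @export
rbf_guidance <- function(Z, sigma = NULL) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2) stop("need at least 2 cells")
  d2 <- sq_dist_matrix(Z)
  if (is.null(sigma)) {
    dist_pos <- sqrt(d2[upper.tri(d2)])
    sigma <- stats::median(dist_pos)
    if (!is.finite(sigma) || sigma <= 0) {
      warning("median pairwise distance is zero; falling back to sigma = 1")
      sigma <- 1
    }
  } else if (sigma <= 0) stop("sigma must be positive")
  P <- exp(-d2 / (2 * sigma^2))
  list(P = P, sigma = sigma)
}

# squared Euclidean distance matrix, clipped at 0 against rounding
sq_dist_matrix <- function(Z) {
  sq <- rowSums(Z^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Z)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Euclidean projection onto the probability simplex
#'
#' Returns the closest point (in L2) to `v` in `{a : a >= 0, sum(a) = 1}`,
#' by the sort-and-threshold algorithm.
#'
#' @param v finite numeric vector.
#' @return non-negative vector of the same length summing to 1.
#' @export
project_to_simplex <- function(v) {
  n <- length(v)
  if (n == 0) stop("empty vector")
  if (!all(is.finite(v))) stop("v must be finite")
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_len(n) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' Solve the adaptive probability graph
#'
#' For each cell i the row of the soft-neighbour matrix solves
#' `min_{a in simplex} sum_j ||z_i - z_j||^2 a_j + ||a - p_i||^2` over the
#' other cells j != i, which up to a constant is the simplex projection of
#' `p_i - d_i / 2`. Rows are probability distributions; the diagonal is zero.
#'
#' @param Z numeric matrix, cells x dims (N >= 2).
#' @param P guidance matrix (e.g. from [rbf_guidance()]); defaults to the
#'   RBF guidance with the median-heuristic bandwidth.
#' @param sigma optional bandwidth forwarded to [rbf_guidance()] when `P`
#'   is not given.
#' @return An object of class `probability_graph`: list with `A` (row-
#'   stochastic, zero diagonal), `P`, `degrees` (symmetrized degrees, see
#'   [node_degrees()]) and `sigma` (NA when `P` was supplied directly).
#' @export
solve_adaptive_graph <- function(Z, P = NULL, sigma = NULL) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (N < 2) stop("need at least 2 cells to build a graph")
  if (N > 50000)
    warning("dense N x N graph for ", N, " cells: the solver is O(N^2) ",
            "in time and memory")
  sig <- NA_real_
  if (is.null(P)) {
    g <- rbf_guidance(Z, sigma)
    P <- g$P
    sig <- g$sigma
  }
  if (!all(dim(P) == c(N, N))) stop("P must be N x N")
  d2 <- sq_dist_matrix(Z)
  A <- matrix(0, N, N)
  idx <- seq_len(N)
  for (i in idx) {
    j <- idx[-i]
    A[i, j] <- project_to_simplex(P[i, j] - d2[i, j] / 2)
  }
  structure(list(A = A, P = P, degrees = node_degrees(A), sigma = sig),
            class = "probability_graph")
}

#' @export
print.probability_graph <- function(x, ...) {
  cat("probability_graph:", nrow(x$A), "cells, mean row support",
      round(mean(rowSums(x$A > 0)), 1), "neighbours\n")
  invisible(x)
}

#' Export a probability graph to disk
#'
#' Writes the adjacency as a MatrixMarket sparse matrix (`graph.mtx`) and
#' the node degrees as TSV (`degrees.tsv`).
#'
#' @param graph a [solve_adaptive_graph()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the two paths written.
#' @export
export_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "probability_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "graph.mtx")
  tsv <- file.path(dir, "degrees.tsv")
  Matrix::writeMM(Matrix::Matrix(graph$A, sparse = TRUE), mtx)
  utils::write.table(data.frame(node = seq_along(graph$degrees),
                                degree = graph$degrees),
                     tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(mtx, tsv))
}

#' Node degrees of a soft neighbour graph
#'
#' Row sums of the symmetrized matrix `(A + t(A)) / 2`. Literal row sums of
#' a row-stochastic matrix are identically 1; symmetrizing first lets cells
#' that many others choose as neighbours receive degree above 1, so the
#' degree carries centrality information.
#'
#' @param A square non-negative matrix.
#' @return numeric vector of N non-negative degrees (summing to N for a
#'   row-stochastic A).
#' @export
node_degrees <- function(A) {
  A <- as.matrix(A)
  rowSums((A + t(A)) / 2)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Symmetrizes `A_f`, adds the identity (self-loops) to obtain `A*`, and
#' returns `D^{-1/2} A* D^{-1/2}` where `D` is the diagonal of row sums of
#' `A*`. The result is symmetric with spectral radius 1 -- the propagation
#' operator of Laplacian-smoothing graph convolution.
#'
#' @param A_f square non-negative matrix with zero diagonal.
#' @return An object of class `normalized_adjacency`: list with `A_tilde`
#'   and `self_loops = TRUE`.
#' @export
normalized_adjacency <- function(A_f) {
  A_f <- as.matrix(A_f)
  if (nrow(A_f) != ncol(A_f)) stop("A_f must be square")
  if (any(A_f < 0)) stop("A_f must be non-negative")
  A_sym <- (A_f + t(A_f)) / 2
  diag(A_sym) <- 0
  A_star <- A_sym + diag(nrow(A_sym))
  d <- rowSums(A_star)
  d_inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)  # self-loops keep d > 0
  A_tilde <- A_star * outer(d_inv_sqrt, d_inv_sqrt)
  structure(list(A_tilde = A_tilde, self_loops = TRUE),
            class = "normalized_adjacency")
}
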