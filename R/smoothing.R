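#' One graph-convolution propagation step
#'
#' Default parameter-free mode multiplies by the normalized adjacency
#' (`X_next = A_tilde %*% X`): pure Laplacian smoothing with identity
#' weights and activation. Supplying `W` switches to a trainable layer
#' `ReLU(A_tilde %*% X %*% W)`.
#'
#' @param X feature matrix N x d.
#' @param adj a [normalized_adjacency()] object (or a plain N x N matrix).
#' @param W optional d x d weight matrix for the trainable mode.
#' @return matrix N x d.
#' @export
gcn_propagate <- function(X, adj, W = NULL) {
  A <- if (inherits(adj, "normalized_adjacency")) adj$A_tilde else as.matrix(adj)
  X <- as.matrix(X)
  if (ncol(A) != nrow(X)) stop("adjacency and feature shapes do not match")
  out <- A %*% X
  if (!is.null(W)) {
    if (nrow(W) != ncol(X)) stop("W must be d x d")
    out <- pmax(out %*% W, 0)
  }
  out
}

#' Mean squared error
#'
#' @param pred,target matrices of the same shape.
#' @return mean over all entries of the squared difference.
#' @export
mse_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target))) stop("shapes differ")
  mean((pred - target)^2)
}

#' Intra-cluster compactness
#'
#' The smoothing-feedback signal: for each cluster, the sum of squared
#' Euclidean distances over all ordered pairs of its members divided by the
#' squared cluster size, averaged over clusters. Zero iff every cluster's
#' points coincide. Equivalently, per cluster, twice the mean squared
#' distance to the cluster centroid.
#'
#' @param X matrix N x d.
#' @param labels cluster assignment of length N (every label non-empty by
#'   construction).
#' @return scalar >= 0.
#' @export
intra_cluster_measure <- function(X, labels) {
  X <- as.matrix(X)
  if (length(labels) != nrow(X)) stop("labels length must equal nrow(X)")
  labs <- unique(labels)
  if (length(labs) == 0) stop("no clusters")
  vals <- vapply(labs, function(l) {
    Xi <- X[labels == l, , drop = FALSE]
    m <- nrow(Xi)
    # ordered-pair sum: sum_{i,j} ||x_i - x_j||^2 = 2m * sum ||x_i - mean||^2
    cen <- colMeans(Xi)
    2 * sum(sweep(Xi, 2, cen)^2) / m
  }, numeric(1))
  mean(vals)
}

#' Seeded k-means clustering of an embedding
#'
#' @param X matrix N x d.
#' @param K number of clusters (`<= N`).
#' @param seed integer seed; with `nstart = 20` restarts the result is
#'   deterministic given the seed.
#' @return integer labels in `1..K`.
#' @export
cluster_cells <- function(X, K, seed = 1L) {
  X <- as.matrix(X)
  if (K > nrow(X)) stop("K exceeds the number of cells")
  if (K == nrow(X)) return(seq_len(nrow(X)))  # every point its own cluster
  withr::with_seed(as.integer(seed), {
    stats::kmeans(X, centers = K, nstart = 20, iter.max = 100)$cluster
  })
}

#' Adaptive-depth Laplacian smoothing
#'
#' Repeatedly propagates the embedding through the normalized adjacency,
#' after each step re-clustering with seeded k-means and computing the
#' intra-cluster compactness `xi`. Iteration stops at the first `t` where
#' `xi(t+1) > xi(t)` (a strict increase; ties continue), returning the
#' embedding at depth `t` -- stopping at the first local minimum of `xi`
#' guards against over-smoothing. Without an increase, the embedding at
#' `max_layers` is returned.
#'
#' @param Z input embedding N x d.
#' @param adj a [normalized_adjacency()] object.
#' @param K cluster count used for the feedback clustering.
#' @param max_layers maximum propagation depth (>= 1).
#' @param seed seed for the k-means feedback at every depth.
#' @return list with `embedding` (N x d at the selected depth) and `trace`
#'   (class `smoothing_trace`: `xi_values` for depths 0..t_last,
#'   `selected_t`, `max_layers`, `stopped_early`).
#' @export
adaptive_smooth <- function(Z, adj, K, max_layers = 10, seed = 1L) {
  stopifnot(max_layers >= 1)
  X <- as.matrix(Z)
  xi <- intra_cluster_measure(X, cluster_cells(X, K, seed))
  xi_values <- xi
  best <- X
  selected_t <- 0L
  stopped_early <- FALSE
  for (t in seq_len(max_layers)) {
    X_next <- gcn_propagate(X, adj)
    if (!all(is.finite(X_next))) stop("non-finite values during propagation")
    xi_next <- intra_cluster_measure(X_next, cluster_cells(X_next, K, seed))
    xi_values <- c(xi_values, xi_next)
    if (xi_next > xi) {
      stopped_early <- TRUE
      break
    }
    X <- X_next
    xi <- xi_next
    best <- X
    selected_t <- t
  }
  trace <- structure(list(xi_values = xi_values, selected_t = selected_t,
                          max_layers = as.integer(max_layers),
                          stopped_early = stopped_early),
                     class = "smoothing_trace")
  list(embedding = best, trace = trace)
}

#' @export
print.smoothing_trace <- function(x, ...) {
  cat("smoothing_trace: selected depth t =", x$selected_t,
      if (x$stopped_early) "(stopped early)" else "(ran to max_layers)", "\n")
  cat("  xi:", paste(signif(x$xi_values, 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Clustering agreement scores
#'
#' Normalized mutual information (arithmetic normalization of the entropies)
#' and the adjusted Rand index between a clustering and reference labels.
#' Both are invariant to relabelling. Degenerate single-cluster cases where
#' an entropy is zero return NMI 1 if the partitions are identical up to
#' relabelling and 0 otherwise.
#'
#' @param labels,truth equal-length assignment vectors.
#' @return list with `nmi` and `ari`.
#' @export
evaluate_clustering <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("labels and truth must have equal length")
  li <- as.integer(factor(labels))
  ti <- as.integer(factor(truth))
  ari <- mclust::adjustedRandIndex(li, ti)
  if (length(unique(li)) == 1 && length(unique(ti)) == 1) {
    nmi <- 1
  } else if (length(unique(li)) == 1 || length(unique(ti)) == 1) {
    nmi <- 0
  } else {
    nmi <- igraph::compare(li, ti, method = "nmi")
  }
  list(nmi = nmi, ari = ari)
}
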