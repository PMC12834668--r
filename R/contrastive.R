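#' Initialise multi-subspace encoder parameters
#'
#' The multi-subspace encoder (MSEncoder) maps a view's embedding `Z`
#' (N x d) into `p` subspace embeddings of dimension `d_sub = d / (2p)` each,
#' so that the concatenation of both views' flattened subspaces has width
#' exactly `d`. It projects `Z` to keys `K = Z W_K` and values `V = Z W_V`,
#' scores each subspace with a query (`K Q`) plus a degree term
#' (`alpha * D W_S`, `D` the diagonal degree matrix), softmaxes the `p`
#' scores per cell, and scales a per-subspace linear projection of the value
#' by the attention weight.
#'
#' @param d embedding dimension (must be divisible by `2 * p`).
#' @param n_cells number of cells N (the degree projection `W_S` is N x p).
#' @param p number of subspaces.
#' @param d_key key dimension.
#' @param alpha non-negative weight of the structural (degree) score.
#' @param seed integer seed.
#' @return list of class `msencoder_params`.
#' @export
init_msencoder <- function(d, n_cells, p = 3, d_key = 32, alpha = 1,
                           seed = 1L) {
  if (d %% (2 * p) != 0)
    stop("d (", d, ") must be divisible by 2 * p (", 2 * p, ")")
  if (alpha < 0) stop("alpha must be non-negative")
  d_sub <- d %/% (2L * p)
  withr::with_seed(as.integer(seed), {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr)
    }
    structure(list(W_K = glorot(d, d_key), W_V = glorot(d, d),
                   Q = glorot(d_key, p), W_S = glorot(n_cells, p),
                   proj = lapply(seq_len(p), function(k) glorot(d, d_sub)),
                   alpha = alpha, p = as.integer(p), d_sub = as.integer(d_sub)),
              class = "msencoder_params")
  })
}

#' Multi-subspace encoder forward pass
#'
#' @param Z view embedding, N x d.
#' @param degrees node degrees from the view's adaptive graph: either a
#'   length-N vector or the N x N diagonal degree matrix.
#' @param params an [init_msencoder()] object.
#' @return An object of class `subspace_set`: list with `embeddings`
#'   (array N x p x d_sub), `att` (N x p, rows sum to 1) and `d_sub`.
#' @export
msencoder_forward <- function(Z, degrees, params) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (is.matrix(degrees)) {
    if (!all(dim(degrees) == c(N, N))) stop("degree matrix must be N x N")
    degrees <- diag(degrees)
  }
  if (length(degrees) != N) stop("degrees length must equal nrow(Z)")
  if (nrow(params$W_S) != N)
    stop("params were initialised for ", nrow(params$W_S), " cells, got ", N)
  K <- Z %*% params$W_K
  V <- Z %*% params$W_V
  S <- as.numeric(degrees) * params$W_S          # diag(degrees) %*% W_S
  att <- row_softmax(K %*% params$Q + params$alpha * S)
  emb <- array(0, dim = c(N, params$p, params$d_sub))
  for (k in seq_len(params$p))
    emb[, k, ] <- att[, k] * (V %*% params$proj[[k]])
  structure(list(embeddings = emb, att = att, d_sub = params$d_sub),
            class = "subspace_set")
}

subspace_k <- function(set, k) {
  matrix(set$embeddings[, k, ], nrow = dim(set$embeddings)[1])
}

#' Seeded random derangement
#'
#' A uniform permutation of `1..n` with no fixed points, used to form
#' product-of-marginals (negative) pairs for the mutual-information
#' estimator.
#'
#' @param n length (>= 2).
#' @param seed integer seed.
#' @return integer vector of length `n`.
#' @export
random_derangement <- function(n, seed = 1L) {
  if (n < 2) stop("a derangement needs n >= 2")
  withr::with_seed(as.integer(seed), {
    repeat {
      perm <- sample.int(n)
      if (!any(perm == seq_len(n))) return(perm)
    }
  })
}

#' Jensen-Shannon mutual-information lower bound
#'
#' Softplus-based estimator of the mutual information between two paired
#' views, with the discriminator fixed to the dot product:
#' `E_pos[-SP(-<u_i, r_i>)] - E_neg[SP(<u_i, r_pi(i)>)]` with
#' `SP(x) = log(1 + exp(x))` and negatives formed by a derangement `pi` of
#' the rows (a sample from the product of marginals). Both terms are
#' non-positive, so the estimate is always `<= 0`; it approaches 0 only when
#' positives score arbitrarily high and negatives arbitrarily low.
#'
#' @param pos_u,pos_r paired embeddings, N x d_sub each.
#' @param neg_pairing a derangement of `1..N` (default: seeded via
#'   [random_derangement()]).
#' @param seed seed used when `neg_pairing` is not supplied.
#' @return scalar estimate (`<= 0`).
#' @export
js_mi <- function(pos_u, pos_r, neg_pairing = NULL, seed = 1L) {
  pos_u <- as.matrix(pos_u); pos_r <- as.matrix(pos_r)
  stopifnot(all(dim(pos_u) == dim(pos_r)))
  N <- nrow(pos_u)
  if (N < 2) stop("need N >= 2 for negative pairs")
  if (is.null(neg_pairing)) neg_pairing <- random_derangement(N, seed)
  if (any(neg_pairing == seq_len(N)))
    stop("neg_pairing must be a derangement (no fixed points)")
  s_pos <- rowSums(pos_u * pos_r)
  s_neg <- rowSums(pos_u * pos_r[neg_pairing, , drop = FALSE])
  mean(-softplus(-s_pos)) - mean(softplus(s_neg))
}

#' CLUB upper bound on mutual information
#'
#' Contrastive log-ratio upper bound between two subspace embeddings of the
#' same view, under the Gaussian conditional
#' `P(u_l | u_k) = N(u_l; u_k, beta^{-1} I)`:
#' `(beta / 2) * (E_{i != j} ||u_l[j] - u_k[i]||^2 - E_i ||u_l[i] - u_k[i]||^2)`
#' with the first expectation over all ordered pairs `i != j`. The Gaussian
#' normalising constants cancel between the two terms.
#'
#' @param u_k,u_l matrices N x d_sub.
#' @param beta positive precision of the Gaussian conditional.
#' @return scalar upper-bound estimate (0 when `u_k` and `u_l` have all rows
#'   identical).
#' @export
club_upper_bound <- function(u_k, u_l, beta = 1) {
  u_k <- as.matrix(u_k); u_l <- as.matrix(u_l)
  stopifnot(all(dim(u_k) == dim(u_l)))
  if (beta <= 0) stop("beta must be positive")
  N <- nrow(u_k)
  diag_sum <- sum((u_l - u_k)^2)
  total <- N * sum(u_l^2) + N * sum(u_k^2) -
    2 * sum(colSums(u_l) * colSums(u_k))
  e_neg <- (total - diag_sum) / (N * (N - 1))
  e_pos <- diag_sum / N
  (beta / 2) * (e_neg - e_pos)
}

#' Multi-subspace contrastive loss
#'
#' To be minimised:
#' `-sum_k JS(u_k, r_k) + gamma * sum_{k<l} max(0, CLUB(u_k, u_l))`.
#' Gradient descent therefore maximises the cross-view mutual-information
#' lower bound within matching subspaces and minimises the within-view upper
#' bound between different subspaces of the u-view. Each CLUB term is
#' floored at zero: mutual information is non-negative, so a negative
#' estimate means the bound is already vacuous, and continuing to push it
#' down only inflates the embedding scale without reducing redundancy
#' (with the fixed-variance Gaussian conditional the raw estimator is
#' unbounded below, which otherwise destabilises joint training).
#'
#' @param U,R [msencoder_forward()] outputs for the two views (same N, p,
#'   d_sub).
#' @param gamma non-negative weight of the redundancy (CLUB) penalty.
#' @param beta CLUB precision.
#' @param neg_pairing optional shared derangement; defaults to a seeded one.
#' @param seed seed for the derangement.
#' @return scalar loss.
#' @export
contrastive_loss <- function(U, R, gamma = 1, beta = 1, neg_pairing = NULL,
                             seed = 1L) {
  stopifnot(inherits(U, "subspace_set"), inherits(R, "subspace_set"))
  if (!all(dim(U$embeddings) == dim(R$embeddings)))
    stop("U and R must share N, p and d_sub")
  p <- dim(U$embeddings)[2]
  N <- dim(U$embeddings)[1]
  if (is.null(neg_pairing)) neg_pairing <- random_derangement(N, seed)
  js_sum <- 0
  for (k in seq_len(p))
    js_sum <- js_sum + js_mi(subspace_k(U, k), subspace_k(R, k), neg_pairing)
  club_sum <- 0
  if (p >= 2) {
    for (k in seq_len(p - 1)) for (l in seq.int(k + 1, p))
      club_sum <- club_sum + max(0, club_upper_bound(subspace_k(U, k),
                                                     subspace_k(U, l), beta))
  }
  -js_sum + gamma * club_sum
}

#' Concatenate the two views' subspace embeddings
#'
#' Flattens each view (subspaces in order, each subspace's `d_sub`
#' coordinates contiguous) and binds them column-wise: u-view subspaces
#' 1..p, then r-view subspaces 1..p. The result has width
#' `2 * p * d_sub = d`.
#'
#' @param U,R [msencoder_forward()] outputs.
#' @return matrix N x d.
#' @export
concat_views <- function(U, R) {
  stopifnot(inherits(U, "subspace_set"), inherits(R, "subspace_set"))
  if (!all(dim(U$embeddings) == dim(R$embeddings)))
    stop("U and R must share N, p and d_sub")
  flat <- function(S) do.call(cbind, lapply(seq_len(dim(S$embeddings)[2]),
                                            function(k) subspace_k(S, k)))
  cbind(flat(U), flat(R))
}
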