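#' Initialise encoder parameters
#'
#' A fully connected encoder `D -> widths[1] -> ... -> d` with Glorot-uniform
#' weight initialisation and zero biases. Both modalities must share the
#' output dimension `d` so their embeddings can be compared and fused.
#'
#' @param widths integer vector of layer widths starting at the input
#'   dimension and ending at the embedding dimension d, e.g. `c(500, 256, 60)`.
#' @param activation `"elu"` or `"relu"`, applied between hidden layers (the
#'   output layer is linear).
#' @param seed integer seed for the weight draw.
#' @return list of class `encoder_params` with per-layer `W`/`b` and the
#'   activation name.
#' @export
init_encoder <- function(widths, activation = c("elu", "relu"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(length(widths) >= 2, all(widths >= 1))
  withr::with_seed(as.integer(seed), {
    layers <- lapply(seq_len(length(widths) - 1), function(i) {
      fan_in <- widths[i]; fan_out <- widths[i + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in),
           b = matrix(0, 1, fan_out))
    })
    structure(list(layers = layers, widths = widths, activation = activation),
              class = "encoder_params")
  })
}

activation_fun <- function(name) {
  switch(name,
         elu = function(x) ifelse(x > 0, x, expm1(x)),
         relu = function(x) pmax(x, 0),
         identity = identity,
         stop("unknown activation: ", name))
}

#' Encoder forward pass
#'
#' Deterministic forward pass through the fully connected encoder; hidden
#' layers use the configured activation, the final layer is linear.
#'
#' @param X input matrix, cells x D (D must match `params$widths[1]`).
#' @param params an [init_encoder()] object.
#' @return embedding matrix, cells x d.
#' @export
encode <- function(X, params) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("encoder input must be finite")
  if (ncol(X) != params$widths[1])
    stop("input width ", ncol(X), " does not match encoder width ",
         params$widths[1])
  act <- activation_fun(params$activation)
  h <- X
  nl <- length(params$layers)
  for (i in seq_len(nl)) {
    h <- sweep(h %*% params$layers[[i]]$W, 2,
               as.vector(params$layers[[i]]$b), `+`)
    if (i < nl) h <- act(h)
  }
  h
}

#' Degree-centrality encoding
#'
#' Adds a degree-scaled structural feature to every cell's embedding:
#' `z_i + log(1 + softplus(c_raw) * deg_i)` elementwise, where `c_raw` is a
#' learnable length-d vector per modality. The softplus keeps the effective
#' vector positive so the logarithm is defined for any non-negative degree,
#' and a cell of degree 0 is passed through unchanged.
#'
#' @param Z embedding matrix, cells x d.
#' @param degrees non-negative degree vector of length N (from
#'   [node_degrees()]).
#' @param c_raw unconstrained numeric vector of length d (default zeros,
#'   i.e. effective vector `softplus(0) = log 2`).
#' @return matrix of the same shape as `Z`.
#' @export
centrality_encode <- function(Z, degrees, c_raw = rep(0, ncol(Z))) {
  Z <- as.matrix(Z)
  if (length(degrees) != nrow(Z)) stop("degrees length must equal nrow(Z)")
  if (any(degrees < 0)) stop("degrees must be non-negative")
  if (length(c_raw) != ncol(Z)) stop("c_raw length must equal ncol(Z)")
  Z + log1p(outer(as.numeric(degrees), softplus(as.numeric(c_raw))))
}

#' Self-attention semantic fusion
#'
#' Scaled dot-product self-attention over cells:
#' `Att = softmax(Z_hat %*% t(Z_hat) / sqrt(d))` row-wise, and the fused
#' embedding `Z_tilde = Att %*% Z_hat`. Every row of `Att` is a probability
#' distribution, so rows of `Z_tilde` are convex combinations of rows of
#' `Z_hat`.
#'
#' @param Z_hat matrix, cells x d.
#' @return list with `Att` (N x N, rows sum to 1) and `Z_tilde` (N x d).
#' @export
self_attention_enhance <- function(Z_hat) {
  Z_hat <- as.matrix(Z_hat)
  if (!all(is.finite(Z_hat))) stop("Z_hat must be finite")
  if (ncol(Z_hat) < 1) stop("need at least one embedding dimension")
  Att <- row_softmax(tcrossprod(Z_hat) / sqrt(ncol(Z_hat)))
  list(Att = Att, Z_tilde = Att %*% Z_hat)
}
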