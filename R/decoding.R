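#' Fuse common and omics-specific embeddings
#'
#' Element-wise weighted sum `Z = Z_ra + lambda_r * Z_tilde_r +
#' lambda_a * Z_tilde_a` combining the shared contrastive embedding with the
#' two attention-enhanced per-omics embeddings.
#'
#' @param Z_ra,Z_tilde_r,Z_tilde_a matrices N x d.
#' @param lambda_r,lambda_a non-negative scaling weights.
#' @return matrix N x d.
#' @export
fuse <- function(Z_ra, Z_tilde_r, Z_tilde_a, lambda_r = 0.1, lambda_a = 0.1) {
  if (!all(dim(Z_ra) == dim(Z_tilde_r)) || !all(dim(Z_ra) == dim(Z_tilde_a)))
    stop("all three matrices must share the same shape")
  if (lambda_r < 0 || lambda_a < 0) stop("fusion weights must be non-negative")
  Z_ra + lambda_r * Z_tilde_r + lambda_a * Z_tilde_a
}

# entrywise ZINB log-likelihood in log space:
#   x = 0: log(pi + (1 - pi) * NB(0)), via log-sum-exp
#   x > 0: log(1 - pi) + log NB(x), with the 1/x! normalisation restored
# branches are evaluated only where they apply (counts are mostly zeros)
zinb_loglik_matrix <- function(x, pi_, mu, theta) {
  rec <- function(m, idx) if (length(m) == 1) m else m[idx]
  zero <- x == 0
  pos <- !zero
  out <- x
  if (any(zero)) {
    th <- rec(theta, zero); m_ <- rec(mu, zero); p_ <- rec(pi_, zero)
    logp0 <- th * (log(th) - log(th + m_))
    a <- log(p_)
    b <- log1p(-p_) + logp0
    mx <- pmax(a, b)
    out[zero] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  if (any(pos)) {
    th <- rec(theta, pos); m_ <- rec(mu, pos); p_ <- rec(pi_, pos)
    xp <- x[pos]
    out[pos] <- log1p(-p_) +
      lgamma(xp + th) - lgamma(th) - lgamma(xp + 1) +
      th * (log(th) - log(th + m_)) + xp * (log(m_) - log(th + m_))
  }
  out
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Mean over entries of `-log ZINB(x; pi, mu, theta)` where the ZINB mixes a
#' point mass at zero (weight `pi`) with a negative binomial of mean `mu`
#' and dispersion `theta` (variance `mu + mu^2 / theta`). Computed in log
#' space via log-gamma; the zero branch uses a log-sum-exp of the two
#' mixture components.
#'
#' @param X_r non-negative count matrix N x Dr.
#' @param Pi dropout probability matrix, entries strictly in (0, 1).
#' @param M_r mean matrix, entries strictly positive.
#' @param Theta dispersion matrix (or scalar, recycled), strictly positive.
#' @return scalar mean NLL.
#' @export
zinb_nll <- function(X_r, Pi, M_r, Theta) {
  X_r <- as.matrix(X_r)
  if (any(X_r < 0)) stop("counts must be non-negative")
  if (length(Theta) == 1) Theta <- matrix(Theta, nrow(X_r), ncol(X_r))
  if (length(Pi) == 1) Pi <- matrix(Pi, nrow(X_r), ncol(X_r))
  Pi <- as.matrix(Pi); M_r <- as.matrix(M_r); Theta <- as.matrix(Theta)
  if (any(Pi <= 0) || any(Pi >= 1)) stop("Pi must be strictly in (0, 1)")
  if (any(M_r <= 0)) stop("M_r must be strictly positive")
  if (any(Theta <= 0)) stop("Theta must be strictly positive")
  -mean(zinb_loglik_matrix(X_r, Pi, M_r, Theta))
}

#' Initialise the generative decoders
#'
#' Two independent decoders sharing only the embedding: the RNA decoder has
#' a hidden layer (`d -> hidden`, ELU) feeding three linear heads -- dropout
#' logits (sigmoid -> `Pi`), log-means (exp -> `M_r`), log-dispersions
#' (exp -> `Theta`); the ATAC decoder has its own hidden layer feeding one
#' accessibility-logit head (sigmoid -> `M_a`).
#'
#' @param d embedding (input) dimension.
#' @param d_rna,d_atac output widths for the RNA and ATAC heads.
#' @param hidden hidden width of each trunk.
#' @param seed integer seed.
#' @return list of class `decoder_params`.
#' @export
init_decoder <- function(d, d_rna, d_atac, hidden = 256, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr)
    }
    structure(list(
      W_h = glorot(d, hidden), b_h = matrix(0, 1, hidden),
      W_pi = glorot(hidden, d_rna), b_pi = matrix(0, 1, d_rna),
      W_mu = glorot(hidden, d_rna), b_mu = matrix(0, 1, d_rna),
      W_theta = glorot(hidden, d_rna), b_theta = matrix(0, 1, d_rna),
      W_ha = glorot(d, hidden), b_ha = matrix(0, 1, hidden),
      W_a = glorot(hidden, d_atac), b_a = matrix(0, 1, d_atac),
      hidden = hidden), class = "decoder_params")
  })
}

decoder_trunk <- function(Z, params, which = c("rna", "atac")) {
  which <- match.arg(which)
  W <- if (which == "rna") params$W_h else params$W_ha
  b <- if (which == "rna") params$b_h else params$b_ha
  h <- sweep(as.matrix(Z) %*% W, 2, as.vector(b), `+`)
  ifelse(h > 0, h, expm1(h))
}

clamp_exp <- function(x, lo = 1e-5, hi = 1e6) exp(pmin(pmax(x, log(lo)), log(hi)))

#' Decode an embedding to ZINB parameters
#'
#' @param Z embedding matrix N x d.
#' @param params an [init_decoder()] object.
#' @return list of class `zinb_params` with `Pi` in (0,1), `M_r` > 0 and
#'   `Theta` > 0 (exp outputs clamped to `[1e-5, 1e6]`).
#' @export
zinb_decode <- function(Z, params) {
  if (!all(is.finite(as.matrix(Z)))) stop("Z must be finite")
  h <- decoder_trunk(Z, params, "rna")
  out <- list(
    Pi = stats::plogis(sweep(h %*% params$W_pi, 2, as.vector(params$b_pi), `+`)),
    M_r = clamp_exp(sweep(h %*% params$W_mu, 2, as.vector(params$b_mu), `+`)),
    Theta = clamp_exp(sweep(h %*% params$W_theta, 2, as.vector(params$b_theta), `+`)))
  for (nm in names(out)) if (!all(is.finite(out[[nm]])))
    stop("non-finite activations in decoder head ", nm)
  structure(out, class = "zinb_params")
}

#' Decode an embedding to Bernoulli means
#'
#' @param Z embedding matrix N x d.
#' @param params an [init_decoder()] object.
#' @return matrix N x d_atac with entries strictly in (0, 1).
#' @export
bernoulli_decode <- function(Z, params) {
  if (!all(is.finite(as.matrix(Z)))) stop("Z must be finite")
  h <- decoder_trunk(Z, params, "atac")
  M_a <- stats::plogis(sweep(h %*% params$W_a, 2, as.vector(params$b_a), `+`))
  if (!all(is.finite(M_a))) stop("non-finite activations in decoder head M_a")
  M_a
}

#' Bernoulli cross-entropy
#'
#' Mean over entries of `-(x log u + (1 - x) log(1 - u))`, the negative
#' Bernoulli log-likelihood of a binary matrix under mean matrix `M_a`.
#'
#' @param X_a binary matrix.
#' @param M_a mean matrix with entries in (0, 1).
#' @return scalar (>= 0).
#' @export
bernoulli_ce <- function(X_a, M_a) {
  X_a <- as.matrix(X_a); M_a <- as.matrix(M_a)
  if (!all(X_a %in% c(0, 1))) stop("X_a must be binary")
  if (any(M_a <= 0) || any(M_a >= 1)) stop("M_a must be strictly in (0, 1)")
  -mean(X_a * log(M_a) + (1 - X_a) * log(1 - M_a))
}

#' Overall training loss
#'
#' `L1 = zinb_nll + alpha_1 * bernoulli_ce + alpha_2 * contrastive`, linear
#' in each weight.
#'
#' @param X_r count matrix; `zp` its [zinb_decode()] parameters.
#' @param X_a binary matrix; `M_a` its [bernoulli_decode()] means.
#' @param contrastive precomputed [contrastive_loss()] value.
#' @param alpha_1,alpha_2 non-negative weights.
#' @return scalar loss.
#' @export
total_loss <- function(X_r, zp, X_a, M_a, contrastive, alpha_1 = 0.1,
                       alpha_2 = 1) {
  if (alpha_1 < 0 || alpha_2 < 0) stop("loss weights must be non-negative")
  zinb_nll(X_r, zp$Pi, zp$M_r, zp$Theta) +
    alpha_1 * bernoulli_ce(X_a, M_a) +
    alpha_2 * contrastive
}
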