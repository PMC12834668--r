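#' Specification for a synthetic paired dataset
#'
#' Describes a paired RNA/ATAC dataset with `K` shared latent clusters. RNA
#' counts are zero-inflated negative binomial: per-cluster gene means are a
#' gene-level baseline perturbed by a cluster-specific log-normal effect
#' whose spread is `separation`; a structural-zero (dropout) mask with
#' probability `dropout_pi` is applied on top of NB sampling. ATAC peaks are
#' Bernoulli: the peaks are split into `K` disjoint signature blocks, open
#' with probability `peak_on_prob` in the matching cluster and
#' `peak_off_prob` elsewhere.
#'
#' @param n_cells,n_genes,n_peaks dataset dimensions.
#' @param n_clusters number of latent clusters K (`<= n_cells`).
#' @param cluster_props K mixing proportions summing to 1 (default uniform).
#' @param rna_mean_scale median scale of gene baseline means (counts).
#' @param rna_dispersion NB dispersion theta shared across genes.
#' @param dropout_pi structural-zero probability in `[0, 1)`.
#' @param peak_on_prob,peak_off_prob Bernoulli means for signature /
#'   background peaks, `0 < off < on < 1`.
#' @param separation standard deviation of per-cluster log-mean shifts;
#'   larger values separate clusters more.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_cells = 300, n_genes = 500, n_peaks = 800,
                           n_clusters = 3, cluster_props = NULL,
                           rna_mean_scale = 5, rna_dispersion = 2,
                           dropout_pi = 0.3,
                           peak_on_prob = 0.35, peak_off_prob = 0.02,
                           separation = 1, seed = 1L) {
  if (is.null(cluster_props))
    cluster_props <- rep(1 / n_clusters, n_clusters)
  stopifnot(n_cells >= 2, n_genes >= 1, n_peaks >= 1, n_clusters >= 1,
            rna_mean_scale > 0, rna_dispersion > 0, separation > 0)
  if (n_clusters > n_cells) stop("n_clusters exceeds n_cells")
  if (length(cluster_props) != n_clusters || any(cluster_props < 0))
    stop("cluster_props must be ", n_clusters, " non-negative values")
  if (abs(sum(cluster_props) - 1) > 1e-9) stop("cluster_props must sum to 1")
  if (dropout_pi < 0 || dropout_pi >= 1) stop("dropout_pi must be in [0, 1)")
  if (!(peak_off_prob > 0 && peak_off_prob < peak_on_prob && peak_on_prob < 1))
    stop("need 0 < peak_off_prob < peak_on_prob < 1")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks),
                 n_clusters = as.integer(n_clusters),
                 cluster_props = cluster_props,
                 rna_mean_scale = rna_mean_scale,
                 rna_dispersion = rna_dispersion, dropout_pi = dropout_pi,
                 peak_on_prob = peak_on_prob, peak_off_prob = peak_off_prob,
                 separation = separation, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic paired dataset with known clusters
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a [paired_omics] whose `labels` are the truth)
#'   and `true_means` (the K x genes matrix of ZINB means, useful for
#'   imputation benchmarks) and `signature_blocks` (peak index list per
#'   cluster).
#' @export
generate_paired_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    K <- spec$n_clusters
    n <- spec$n_cells
    z <- sample.int(K, n, replace = TRUE, prob = spec$cluster_props)
    # guarantee every cluster is populated (small-n draws may miss one)
    for (k in seq_len(K)) if (!any(z == k)) z[sample.int(n, 1)] <- k

    base_log_mean <- stats::rnorm(spec$n_genes, log(spec$rna_mean_scale), 0.5)
    shift <- matrix(stats::rnorm(K * spec$n_genes, 0, spec$separation),
                    nrow = K)
    mu_k <- exp(sweep(shift, 2, base_log_mean, `+`))  # K x genes

    mu_cell <- mu_k[z, , drop = FALSE]
    rna <- matrix(stats::rnbinom(n * spec$n_genes, size = spec$rna_dispersion,
                                 mu = as.vector(mu_cell)),
                  nrow = n)
    if (spec$dropout_pi > 0) {
      drop <- matrix(stats::runif(n * spec$n_genes) < spec$dropout_pi, nrow = n)
      rna[drop] <- 0
    }

    block <- floor(spec$n_peaks / K)
    blocks <- lapply(seq_len(K), function(k) seq.int((k - 1) * block + 1, k * block))
    prob <- matrix(spec$peak_off_prob, n, spec$n_peaks)
    for (k in seq_len(K)) prob[z == k, blocks[[k]]] <- spec$peak_on_prob
    atac <- matrix(stats::rbinom(n * spec$n_peaks, 1, as.vector(prob)), nrow = n)

    data <- paired_omics(rna, atac, labels = z)
    list(data = data, true_means = mu_k, signature_blocks = blocks)
  })
}

#' Add clipped Gaussian noise to a matrix
#'
#' Perturbation protocol for robustness experiments: adds i.i.d.
#' Normal(0, sd^2) noise and clips at zero from below so count-like inputs
#' stay non-negative. `sd = 0` returns the input unchanged.
#'
#' @param m numeric matrix.
#' @param sd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return matrix of the same shape.
#' @export
add_gaussian_noise <- function(m, sd, seed = 1L) {
  if (sd < 0) stop("sd must be non-negative")
  m <- as.matrix(m)
  if (sd == 0) return(m)
  withr::with_seed(as.integer(seed), {
    pmax(m + matrix(stats::rnorm(length(m), 0, sd), nrow = nrow(m)), 0)
  })
}
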