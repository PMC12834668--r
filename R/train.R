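# Joint training of the full model. Forward passes here are built from the
# autodiff primitives in autograd.R and mirror the exported pure functions
# (encode, centrality_encode, self_attention_enhance, msencoder_forward,
# zinb_decode, ...); tests pin the two routes against each other.

#' Default run configuration
#'
#' All tunable parameters of the model and training loop, overridable by
#' name. `d` must be divisible by `2 * p` so that the two views' flattened
#' subspaces concatenate back to width `d`.
#'
#' @param ... name-value overrides of the defaults.
#' @return list of class `scduet_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    d = 60L, p = 3L, d_key = 32L, hidden_enc = 256L, hidden_dec = 256L,
    activation = "elu",
    alpha = 1,          # structural-score weight in the MSEncoder attention
    beta = 1,           # CLUB Gaussian precision
    gamma = 1,          # within-view redundancy weight
    alpha_1 = 0.1,      # Bernoulli CE weight in the overall loss
    alpha_2 = 1,        # contrastive weight in the overall loss
    lambda_r = 0.1, lambda_a = 0.1,   # fusion weights
    lr = 1e-3,
    epochs_pretrain = 30L, epochs_joint = 60L,
    max_layers = 10L,
    K = NULL,           # cluster count; defaults to the number of label groups
    n_top_genes = NULL, n_top_peaks = NULL,  # optional variance filtering
    sigma = NULL,       # RBF bandwidth (NULL = median heuristic)
    use_centrality = TRUE, use_mscl = TRUE, use_adagcn = TRUE,
    noise_sd = 0, noise_stage = "normalized",
    seed = 1L, verbose = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$d %% (2 * cfg$p) != 0)
    stop("d must be divisible by 2 * p")
  for (w in c("alpha", "beta", "gamma", "alpha_1", "alpha_2",
              "lambda_r", "lambda_a"))
    if (cfg[[w]] < 0) stop(w, " must be non-negative")
  structure(cfg, class = c("scduet_config", "list"))
}

# derive a reproducible sub-seed (kept below 2^31)
sub_seed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2000000011L

# preprocess raw paired data into model inputs, optionally perturbed
prepare_inputs <- function(data, cfg) {
  counts <- data$rna_counts
  atac <- data$atac_counts
  if (!is.null(cfg$n_top_genes) && cfg$n_top_genes < ncol(counts))
    counts <- select_features(counts, cfg$n_top_genes)$matrix
  if (!is.null(cfg$n_top_peaks) && cfg$n_top_peaks < ncol(atac))
    atac <- select_features(atac, cfg$n_top_peaks)$matrix
  if (cfg$noise_sd > 0 && cfg$noise_stage == "counts") {
    counts <- add_gaussian_noise(counts, cfg$noise_sd, sub_seed(cfg$seed, 11L))
    atac <- add_gaussian_noise(atac, cfg$noise_sd, sub_seed(cfg$seed, 12L))
  }
  X_r_norm <- normalize_rna(counts)
  X_a_bin <- binarize_atac(atac)
  X_r_in <- X_r_norm
  X_a_in <- X_a_bin
  if (cfg$noise_sd > 0 && cfg$noise_stage == "normalized") {
    X_r_in <- add_gaussian_noise(X_r_norm, cfg$noise_sd, sub_seed(cfg$seed, 13L))
    X_a_in <- add_gaussian_noise(X_a_bin, cfg$noise_sd, sub_seed(cfg$seed, 14L))
  }
  list(counts = counts, atac_bin = X_a_bin, X_r_in = X_r_in, X_a_in = X_a_in)
}

# wrap numeric parameter lists into autodiff parameter nodes
params_to_nodes <- function(x) {
  if (is.matrix(x)) return(ag_param(x))
  if (is.list(x)) return(lapply(x, params_to_nodes))
  x
}

flatten_nodes <- function(x) {
  if (inherits(x, "ag_node")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, flatten_nodes)))
  list()
}

node_values <- function(x) {
  if (inherits(x, "ag_node")) return(x$value)
  if (is.list(x)) return(lapply(x, node_values))
  x
}

ag_encode <- function(Xc, layers, activation) {
  h <- Xc
  nl <- length(layers)
  for (i in seq_len(nl)) {
    h <- ag_add_bias(ag_mm(h, layers[[i]]$W), layers[[i]]$b)
    if (i < nl) h <- if (activation == "elu") ag_elu(h) else ag_relu(h)
  }
  h
}

ag_centrality <- function(Z, degrees, c_raw) {
  ag_add(Z, ag_log1p(ag_outer_const(as.numeric(degrees), ag_softplus(c_raw))))
}

ag_attention <- function(Z_hat) {
  d <- ncol(Z_hat$value)
  att <- ag_row_softmax(ag_scale(ag_mm(Z_hat, ag_t(Z_hat)), 1 / sqrt(d)))
  list(att = att, Z_tilde = ag_mm(att, Z_hat))
}

ag_msencoder <- function(Z, degrees, ms, alpha) {
  K <- ag_mm(Z, ms$W_K)
  V <- ag_mm(Z, ms$W_V)
  S <- ag_rowscale(ms$W_S, ag_const(matrix(as.numeric(degrees), ncol = 1)))
  att <- ag_row_softmax(ag_add(ag_mm(K, ms$Q), ag_scale(S, alpha)))
  subspaces <- lapply(seq_along(ms$proj), function(k)
    ag_rowscale(ag_mm(V, ms$proj[[k]]), ag_col(att, k)))
  list(subspaces = subspaces, att = att)
}

ag_js <- function(u, r, perm) {
  s_pos <- ag_rowdot(u, r)
  s_neg <- ag_rowdot(u, ag_permute_rows(r, perm))
  ag_sub(ag_scale(ag_mean_all(ag_softplus(ag_scale(s_pos, -1))), -1),
         ag_mean_all(ag_softplus(s_neg)))
}

ag_club <- function(u_k, u_l, beta) {
  N <- nrow(u_k$value)
  diff <- ag_sub(u_l, u_k)
  diag_sum <- ag_sum_all(ag_emul(diff, diff))
  total <- ag_scale(ag_add(ag_sum_all(ag_emul(u_l, u_l)),
                           ag_sum_all(ag_emul(u_k, u_k))), N)
  cross <- ag_scale(ag_sum_all(ag_emul(ag_colsums(u_l), ag_colsums(u_k))), -2)
  e_neg <- ag_scale(ag_sub(ag_add(total, cross), diag_sum), 1 / (N * (N - 1)))
  e_pos <- ag_scale(diag_sum, 1 / N)
  ag_scale(ag_sub(e_neg, e_pos), beta / 2)
}

ag_contrastive <- function(Us, Rs, gamma, beta, perm) {
  js_sum <- NULL
  for (k in seq_along(Us)) {
    term <- ag_js(Us[[k]], Rs[[k]], perm)
    js_sum <- if (is.null(js_sum)) term else ag_add(js_sum, term)
  }
  loss <- ag_scale(js_sum, -1)
  p <- length(Us)
  if (gamma > 0 && p >= 2) {
    club_sum <- NULL
    for (k in seq_len(p - 1)) for (l in seq.int(k + 1, p)) {
      term <- ag_relu(ag_club(Us[[k]], Us[[l]], beta))  # MI >= 0: floor the bound
      club_sum <- if (is.null(club_sum)) term else ag_add(club_sum, term)
    }
    loss <- ag_add(loss, ag_scale(club_sum, gamma))
  }
  loss
}

ag_zinb_heads <- function(Z, dec) {
  h <- ag_elu(ag_add_bias(ag_mm(Z, dec$W_h), dec$b_h))
  list(Pi = ag_sigmoid(ag_add_bias(ag_mm(h, dec$W_pi), dec$b_pi)),
       M_r = ag_exp_clamp(ag_add_bias(ag_mm(h, dec$W_mu), dec$b_mu)),
       Theta = ag_exp_clamp(ag_add_bias(ag_mm(h, dec$W_theta), dec$b_theta)))
}

ag_bernoulli_head <- function(Z, dec) {
  h <- ag_elu(ag_add_bias(ag_mm(Z, dec$W_ha), dec$b_ha))
  ag_sigmoid(ag_add_bias(ag_mm(h, dec$W_a), dec$b_a))
}

# full joint forward pass; returns the loss node plus the fused embedding
joint_forward <- function(nodes, inputs, graphs, cfg, perm) {
  Xr <- ag_const(inputs$X_r_in)
  Xa <- ag_const(inputs$X_a_in)
  Zr <- ag_encode(Xr, nodes$enc_r$layers, cfg$activation)
  Za <- ag_encode(Xa, nodes$enc_a$layers, cfg$activation)
  Zr_hat <- if (cfg$use_centrality)
    ag_centrality(Zr, graphs$rna$degrees, nodes$cen_r) else Zr
  Za_hat <- if (cfg$use_centrality)
    ag_centrality(Za, graphs$atac$degrees, nodes$cen_a) else Za
  att_r <- ag_attention(Zr_hat)
  att_a <- ag_attention(Za_hat)
  contra <- NULL
  if (cfg$use_mscl) {
    U <- ag_msencoder(Zr, graphs$rna$degrees, nodes$ms_u, cfg$alpha)
    R <- ag_msencoder(Za, graphs$atac$degrees, nodes$ms_r, cfg$alpha)
    Z_ra <- ag_cbind(c(U$subspaces, R$subspaces))
    contra <- ag_contrastive(U$subspaces, R$subspaces, cfg$gamma, cfg$beta, perm)
  } else {
    half <- cfg$d %/% 2L
    Z_ra <- ag_cbind(list(ag_cols(Zr, seq_len(half)),
                          ag_cols(Za, seq_len(half))))
  }
  Z <- ag_add(Z_ra, ag_add(ag_scale(att_r$Z_tilde, cfg$lambda_r),
                           ag_scale(att_a$Z_tilde, cfg$lambda_a)))
  heads <- ag_zinb_heads(Z, nodes$dec)
  M_a <- ag_bernoulli_head(Z, nodes$dec)
  loss <- ag_add(ag_zinb_nll(inputs$counts, heads$Pi, heads$M_r, heads$Theta),
                 ag_scale(ag_bernoulli_ce(inputs$atac_bin, M_a), cfg$alpha_1))
  if (!is.null(contra)) loss <- ag_add(loss, ag_scale(contra, cfg$alpha_2))
  list(loss = loss, Z = Z, heads = heads, M_a = M_a)
}

#' Train the joint multi-omics model
#'
#' Two stages. Stage 1 pretrains each modality's autoencoder on its own
#' generative objective (RNA: ZINB negative log-likelihood on counts; ATAC:
#' Bernoulli cross-entropy on the binarized matrix). The per-omics adaptive
#' probability graphs are then solved once from the pretrained embeddings.
#' Stage 2 jointly optimises the overall loss (reconstruction + weighted
#' Bernoulli term + weighted multi-subspace contrastive term) over encoders,
#' centrality vectors, MSEncoders and decoders with Adam, full batch.
#'
#' @param data a [paired_omics] object.
#' @param config a [run_config()].
#' @return An object of class `scduet_model`: parameter values, the fused
#'   embedding `Z`, decoder outputs (`zinb`, `M_a`), the per-omics graphs,
#'   per-epoch loss traces, and the prepared inputs' dimensions.
#' @export
train <- function(data, config = run_config()) {
  stopifnot(inherits(data, "paired_omics"))
  cfg <- config
  inputs <- prepare_inputs(data, cfg)
  N <- nrow(inputs$counts)
  Dr <- ncol(inputs$counts)
  Da <- ncol(inputs$atac_bin)

  nodes <- list(
    enc_r = params_to_nodes(init_encoder(c(Dr, cfg$hidden_enc, cfg$d),
                                         cfg$activation, sub_seed(cfg$seed, 1L))),
    enc_a = params_to_nodes(init_encoder(c(Da, cfg$hidden_enc, cfg$d),
                                         cfg$activation, sub_seed(cfg$seed, 2L))),
    cen_r = ag_param(matrix(0, 1, cfg$d)),
    cen_a = ag_param(matrix(0, 1, cfg$d)),
    ms_u = params_to_nodes(init_msencoder(cfg$d, N, cfg$p, cfg$d_key,
                                          cfg$alpha, sub_seed(cfg$seed, 3L))),
    ms_r = params_to_nodes(init_msencoder(cfg$d, N, cfg$p, cfg$d_key,
                                          cfg$alpha, sub_seed(cfg$seed, 4L))),
    dec = params_to_nodes(init_decoder(cfg$d, Dr, Da, cfg$hidden_dec,
                                       sub_seed(cfg$seed, 5L))))

  # ---- stage 1: per-modality pretraining --------------------------------
  rna_params <- c(flatten_nodes(nodes$enc_r),
                  flatten_nodes(nodes$dec[c("W_h", "b_h", "W_pi", "b_pi",
                                            "W_mu", "b_mu", "W_theta", "b_theta")]))
  atac_params <- c(flatten_nodes(nodes$enc_a),
                   flatten_nodes(nodes$dec[c("W_ha", "b_ha", "W_a", "b_a")]))
  opt_r <- adam_new(rna_params, lr = cfg$lr)
  opt_a <- adam_new(atac_params, lr = cfg$lr)
  pre_loss <- matrix(NA_real_, cfg$epochs_pretrain, 2,
                     dimnames = list(NULL, c("rna", "atac")))
  Xr_c <- ag_const(inputs$X_r_in)
  Xa_c <- ag_const(inputs$X_a_in)
  for (ep in seq_len(cfg$epochs_pretrain)) {
    Zr <- ag_encode(Xr_c, nodes$enc_r$layers, cfg$activation)
    heads <- ag_zinb_heads(Zr, nodes$dec)
    l_r <- ag_zinb_nll(inputs$counts, heads$Pi, heads$M_r, heads$Theta)
    ag_backward(l_r)
    adam_step(opt_r, rna_params)

    Za <- ag_encode(Xa_c, nodes$enc_a$layers, cfg$activation)
    l_a <- ag_bernoulli_ce(inputs$atac_bin, ag_bernoulli_head(Za, nodes$dec))
    ag_backward(l_a)
    adam_step(opt_a, atac_params)
    pre_loss[ep, ] <- c(l_r$value[1], l_a$value[1])
    if (!all(is.finite(pre_loss[ep, ])))
      stop("pretraining diverged at epoch ", ep,
           "; last finite losses: ", paste(pre_loss[max(ep - 1, 1), ], collapse = ", "))
    if (cfg$verbose && ep %% 10 == 0)
      message(sprintf("pretrain %d: zinb %.4f ce %.4f", ep,
                      pre_loss[ep, 1], pre_loss[ep, 2]))
  }

  # ---- per-omics adaptive graphs from pretrained embeddings -------------
  Zr0 <- ag_value(ag_encode(Xr_c, nodes$enc_r$layers, cfg$activation))
  Za0 <- ag_value(ag_encode(Xa_c, nodes$enc_a$layers, cfg$activation))
  graphs <- list(rna = solve_adaptive_graph(Zr0, sigma = cfg$sigma),
                 atac = solve_adaptive_graph(Za0, sigma = cfg$sigma))

  # ---- stage 2: joint optimisation --------------------------------------
  joint_params <- flatten_nodes(nodes)
  opt <- adam_new(joint_params, lr = cfg$lr)
  joint_loss <- rep(NA_real_, cfg$epochs_joint)
  fwd <- NULL
  for (ep in seq_len(cfg$epochs_joint)) {
    perm <- random_derangement(N, sub_seed(cfg$seed, 100L + ep))
    fwd <- joint_forward(nodes, inputs, graphs, cfg, perm)
    joint_loss[ep] <- fwd$loss$value[1]
    if (!is.finite(joint_loss[ep]))
      stop("joint training diverged at epoch ", ep, "; last finite loss: ",
           if (ep > 1) joint_loss[ep - 1] else NA)
    ag_backward(fwd$loss)
    adam_step(opt, joint_params)
    if (cfg$verbose && ep %% 10 == 0)
      message(sprintf("joint %d: loss %.4f", ep, joint_loss[ep]))
  }

  # final forward with the trained parameters
  perm <- random_derangement(N, sub_seed(cfg$seed, 99L))
  fwd <- joint_forward(nodes, inputs, graphs, cfg, perm)
  zinb <- structure(list(Pi = ag_value(fwd$heads$Pi),
                         M_r = ag_value(fwd$heads$M_r),
                         Theta = ag_value(fwd$heads$Theta)),
                    class = "zinb_params")
  structure(list(
    params = node_values(nodes), config = cfg,
    Z = ag_value(fwd$Z), zinb = zinb, M_a = ag_value(fwd$M_a),
    graphs = graphs,
    losses = list(pretrain = pre_loss, joint = joint_loss),
    dims = c(n_cells = N, n_genes = Dr, n_peaks = Da),
    trained = TRUE), class = "scduet_model")
}

#' @export
print.scduet_model <- function(x, ...) {
  cat("scduet_model:", x$dims["n_cells"], "cells, embedding d =",
      ncol(x$Z), "\n  final joint loss:",
      signif(utils::tail(x$losses$joint, 1), 6), "\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' The model state (parameter arrays, config, traces, embeddings) is a
#' plain list of numeric arrays and is serialised with R's native format.
#'
#' @param model a trained [train()] result.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `scduet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scduet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "scduet_model")) stop("not a saved scduet model")
  model
}

#' Imputed (denoised) matrices from a trained model
#'
#' Returns the generative decoder means: `M_r`, the ZINB mean of the RNA
#' counts, and `M_a`, the Bernoulli mean of peak accessibility. These serve
#' as imputations of dropout-affected entries.
#'
#' @param model a trained [train()] result.
#' @return list with `M_r` (N x Dr, positive) and `M_a` (N x Da, in (0,1)).
#' @export
impute <- function(model) {
  if (!inherits(model, "scduet_model") || !isTRUE(model$trained))
    stop("impute() needs a trained scduet_model")
  list(M_r = model$zinb$M_r, M_a = model$M_a)
}
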