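# The training loop differentiates the full model graph (encoders,
# centrality, attention, MSEncoder, JS/CLUB estimators, ZINB/Bernoulli
# likelihoods) with the package's reverse-mode engine; these tests pin the
# engine against finite differences and against the pure forward functions.

make_tiny_setup <- function() {
  spec <- synthetic_spec(n_cells = 12, n_genes = 8, n_peaks = 6,
                         n_clusters = 2, seed = 2)
  gen <- generate_paired_dataset(spec)
  cfg <- run_config(d = 8, p = 2, d_key = 4, hidden_enc = 6, hidden_dec = 6,
                    epochs_pretrain = 1, epochs_joint = 1, seed = 7)
  inputs <- scduet:::prepare_inputs(gen$data, cfg)
  N <- nrow(inputs$counts)
  nodes <- list(
    enc_r = scduet:::params_to_nodes(init_encoder(c(8, 6, 8), "elu", 1)),
    enc_a = scduet:::params_to_nodes(init_encoder(c(6, 6, 8), "elu", 2)),
    cen_r = scduet:::ag_param(matrix(0.1, 1, 8)),
    cen_a = scduet:::ag_param(matrix(-0.2, 1, 8)),
    ms_u = scduet:::params_to_nodes(init_msencoder(8, N, 2, 4, 1, 3)),
    ms_r = scduet:::params_to_nodes(init_msencoder(8, N, 2, 4, 1, 4)),
    dec = scduet:::params_to_nodes(init_decoder(8, 8, 6, 6, 5)))
  set.seed(11)
  graphs <- list(rna = solve_adaptive_graph(matrix(rnorm(N * 3), N)),
                 atac = solve_adaptive_graph(matrix(rnorm(N * 3), N)))
  list(cfg = cfg, inputs = inputs, nodes = nodes, graphs = graphs,
       perm = random_derangement(N, 9))
}

test_that("autodiff gradients of the joint loss match finite differences", {
  s <- make_tiny_setup()
  loss_at <- function() {
    scduet:::joint_forward(s$nodes, s$inputs, s$graphs, s$cfg, s$perm)$loss$value[1]
  }
  fwd <- scduet:::joint_forward(s$nodes, s$inputs, s$graphs, s$cfg, s$perm)
  scduet:::ag_backward(fwd$loss)
  probes <- list(list(s$nodes$enc_r$layers[[1]]$W, c(1L, 5L)),
                 list(s$nodes$cen_r, c(1L, 3L)),
                 list(s$nodes$ms_u$W_K, 2L),
                 list(s$nodes$ms_u$W_S, 3L),
                 list(s$nodes$ms_u$proj[[1]], 2L),
                 list(s$nodes$dec$W_pi, 1L),
                 list(s$nodes$dec$W_theta, 1L),
                 list(s$nodes$dec$W_a, 1L))
  eps <- 1e-6
  for (pr in probes) {
    node <- pr[[1]]
    for (i in pr[[2]]) {
      old <- node$value[i]
      node$value[i] <- old + eps; up <- loss_at()
      node$value[i] <- old - eps; dn <- loss_at()
      node$value[i] <- old
      num <- (up - dn) / (2 * eps)
      expect_equal(node$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the autodiff forward agrees with the pure-function forward", {
  s <- make_tiny_setup()
  fwd <- scduet:::joint_forward(s$nodes, s$inputs, s$graphs, s$cfg, s$perm)
  vals <- scduet:::node_values(s$nodes)

  Zr <- encode(s$inputs$X_r_in, structure(list(layers = vals$enc_r$layers,
                                               widths = c(8, 6, 8),
                                               activation = "elu"),
                                          class = "encoder_params"))
  Zr_hat <- centrality_encode(Zr, s$graphs$rna$degrees,
                              as.vector(vals$cen_r))
  att <- self_attention_enhance(Zr_hat)
  Za <- encode(s$inputs$X_a_in, structure(list(layers = vals$enc_a$layers,
                                               widths = c(6, 6, 8),
                                               activation = "elu"),
                                          class = "encoder_params"))
  Za_hat <- centrality_encode(Za, s$graphs$atac$degrees,
                              as.vector(vals$cen_a))
  att_a <- self_attention_enhance(Za_hat)
  ms_u <- structure(vals$ms_u, class = "msencoder_params")
  ms_r <- structure(vals$ms_r, class = "msencoder_params")
  U <- msencoder_forward(Zr, s$graphs$rna$degrees, ms_u)
  R <- msencoder_forward(Za, s$graphs$atac$degrees, ms_r)
  Z <- fuse(concat_views(U, R), att$Z_tilde, att_a$Z_tilde,
            s$cfg$lambda_r, s$cfg$lambda_a)
  expect_equal(scduet:::ag_value(fwd$Z), Z, tolerance = 1e-10)

  dec <- structure(vals$dec, class = "decoder_params")
  zp <- zinb_decode(Z, dec)
  M_a <- bernoulli_decode(Z, dec)
  contra <- contrastive_loss(U, R, gamma = s$cfg$gamma, beta = s$cfg$beta,
                             neg_pairing = s$perm)
  manual <- total_loss(s$inputs$counts, zp, s$inputs$atac_bin, M_a, contra,
                       s$cfg$alpha_1, s$cfg$alpha_2)
  expect_equal(fwd$loss$value[1], manual, tolerance = 1e-8)
})

test_that("training is deterministic and reduces the joint loss", {
  spec <- synthetic_spec(n_cells = 40, n_genes = 25, n_peaks = 20,
                         n_clusters = 2, separation = 1, seed = 5)
  gen <- generate_paired_dataset(spec)
  cfg <- run_config(d = 12, p = 2, d_key = 8, hidden_enc = 16, hidden_dec = 16,
                    epochs_pretrain = 10, epochs_joint = 30, seed = 3)
  m1 <- train(gen$data, cfg)
  m2 <- train(gen$data, cfg)
  expect_equal(tail(m1$losses$joint, 1), tail(m2$losses$joint, 1),
               tolerance = 1e-6)
  expect_identical(m1$Z, m2$Z)
  expect_lt(tail(m1$losses$joint, 1), m1$losses$joint[1])
  expect_lt(tail(m1$losses$pretrain[, "rna"], 1), m1$losses$pretrain[1, "rna"])
})

test_that("impute returns decoder means with valid ranges and shapes", {
  spec <- synthetic_spec(n_cells = 30, n_genes = 15, n_peaks = 12,
                         n_clusters = 2, seed = 6)
  gen <- generate_paired_dataset(spec)
  cfg <- run_config(d = 8, p = 2, d_key = 4, hidden_enc = 8, hidden_dec = 8,
                    epochs_pretrain = 5, epochs_joint = 5, seed = 4)
  m <- train(gen$data, cfg)
  imp <- impute(m)
  expect_equal(dim(imp$M_r), unname(dim(gen$data$rna_counts)))
  expect_equal(dim(imp$M_a), unname(dim(gen$data$atac_counts)))
  expect_true(all(imp$M_r > 0))
  expect_true(all(imp$M_a > 0 & imp$M_a < 1))
  expect_error(impute(list()), "trained")
})
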