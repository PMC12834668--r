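variant_name <- function(cfg) {
  off <- c(if (!cfg$use_centrality) "w/oCen",
           if (!cfg$use_mscl) "w/oMSCL",
           if (!cfg$use_adagcn) "w/oAdaGCN")
  if (length(off) == 0) "full" else paste(off, collapse = "+")
}

#' Run the full clustering pipeline
#'
#' End-to-end orchestration: preprocessing, two-stage training, adaptive
#' graph construction on the fused embedding, adaptive-depth Laplacian
#' smoothing (unless ablated), k-means clustering, and NMI/ARI evaluation
#' when ground-truth labels are available.
#'
#' @param data a [paired_omics] object (e.g. from [load_paired_matrices()]
#'   or [generate_paired_dataset()]).
#' @param config a [run_config()]; `config$K` defaults to the number of
#'   distinct labels in `data` and must be given when labels are absent.
#' @param out_dir optional directory: writes `labels.tsv`
#'   (cell_id, cluster), `metrics.json` (variant, nmi, ari, selected_t,
#'   seed), `xi_trace.tsv`, `loss_joint.tsv`, `embedding.csv` and the
#'   imputed matrices (`imputed_rna.csv`, `imputed_atac.csv`).
#' @return An object of class `scduet_result`: `labels` (integers 1..K),
#'   `embedding` (the clustered matrix), `nmi`/`ari` (NA without truth),
#'   `trace` (a `smoothing_trace`, NULL when smoothing is ablated),
#'   `variant`, `seed`, and the fitted `model`.
#' @export
run_pipeline <- function(data, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(data, "paired_omics"))
  cfg <- config
  if (is.null(cfg$K)) {
    if (is.null(data$labels))
      stop("config$K must be set when the data carry no labels")
    cfg$K <- length(unique(data$labels))
  }
  t0 <- Sys.time()
  model <- train(data, cfg)
  if (cfg$verbose)
    message("training done in ",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")

  trace <- NULL
  emb <- model$Z
  if (cfg$use_adagcn) {
    g_f <- solve_adaptive_graph(model$Z, sigma = cfg$sigma)
    adj <- normalized_adjacency(g_f$A)
    sm <- adaptive_smooth(model$Z, adj, cfg$K, cfg$max_layers,
                          seed = sub_seed(cfg$seed, 7L))
    emb <- sm$embedding
    trace <- sm$trace
  }
  labels <- cluster_cells(emb, cfg$K, seed = sub_seed(cfg$seed, 8L))
  nmi <- NA_real_; ari <- NA_real_
  if (!is.null(data$labels)) {
    sc <- evaluate_clustering(labels, data$labels)
    nmi <- sc$nmi; ari <- sc$ari
  }
  res <- structure(list(labels = labels, embedding = emb, nmi = nmi,
                        ari = ari, trace = trace,
                        variant = variant_name(cfg), seed = cfg$seed,
                        model = model, cell_ids = data$cell_ids),
                   class = "scduet_result")
  if (!is.null(out_dir)) write_result_artifacts(res, out_dir)
  res
}

#' @export
print.scduet_result <- function(x, ...) {
  cat("scduet_result [", x$variant, "]: ", length(unique(x$labels)),
      " clusters over ", length(x$labels), " cells\n", sep = "")
  if (!is.na(x$nmi))
    cat("  NMI", round(x$nmi, 4), "| ARI", round(x$ari, 4), "\n")
  if (!is.null(x$trace))
    cat("  smoothing depth t =", x$trace$selected_t, "\n")
  invisible(x)
}

write_result_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(data.frame(cell_id = res$cell_ids, cluster = res$labels),
                     file.path(out_dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  metrics <- list(variant = res$variant, nmi = res$nmi, ari = res$ari,
                  selected_t = if (is.null(res$trace)) NA_integer_
                               else res$trace$selected_t,
                  seed = res$seed)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(res$trace))
    utils::write.table(data.frame(t = seq_along(res$trace$xi_values) - 1,
                                  xi = res$trace$xi_values),
                       file.path(out_dir, "xi_trace.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(epoch = seq_along(res$model$losses$joint),
                                loss = res$model$losses$joint),
                     file.path(out_dir, "loss_joint.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$embedding, file.path(out_dir, "embedding.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  imp <- impute(res$model)
  utils::write.table(imp$M_r, file.path(out_dir, "imputed_rna.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(imp$M_a, file.path(out_dir, "imputed_atac.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}

#' Noise-robustness sweep
#'
#' Perturbs the inputs with clipped Gaussian noise at each standard
#' deviation in `sds` (at the configured `noise_stage`, by default the
#' normalized/binarized encoder inputs) and reruns the full pipeline,
#' once per seed.
#'
#' @param data a [paired_omics] object with labels.
#' @param config base [run_config()].
#' @param sds non-negative noise standard deviations.
#' @param seeds integer seeds; each (sd, seed) pair is one run.
#' @return data.frame with columns `sd`, `seed`, `nmi`, `ari`, `selected_t`.
#' @export
run_noise_sweep <- function(data, config = run_config(),
                            sds = c(0.1, 0.3, 0.5), seeds = 1L) {
  if (any(sds < 0)) stop("noise sds must be non-negative")
  rows <- list()
  for (sd in sds) for (seed in seeds) {
    cfg <- config
    cfg$noise_sd <- sd
    cfg$seed <- as.integer(seed)
    res <- run_pipeline(data, cfg)
    rows[[length(rows) + 1]] <-
      data.frame(sd = sd, seed = seed, nmi = res$nmi, ari = res$ari,
                 selected_t = if (is.null(res$trace)) NA_integer_
                              else res$trace$selected_t)
  }
  do.call(rbind, rows)
}

#' Ablation comparison
#'
#' Runs the full model and the three single-component ablations (without
#' centrality encoding, without multi-subspace contrastive learning, without
#' adaptive graph-convolution smoothing) for each seed.
#'
#' @param data a [paired_omics] object with labels.
#' @param config base [run_config()].
#' @param seeds integer seeds.
#' @return data.frame with columns `variant`, `seed`, `nmi`, `ari`.
#' @export
run_ablation <- function(data, config = run_config(), seeds = 1L) {
  variants <- list(full = list(),
                   "w/oCen" = list(use_centrality = FALSE),
                   "w/oMSCL" = list(use_mscl = FALSE),
                   "w/oAdaGCN" = list(use_adagcn = FALSE))
  rows <- list()
  for (v in names(variants)) for (seed in seeds) {
    cfg <- config
    cfg[names(variants[[v]])] <- variants[[v]]
    cfg$seed <- as.integer(seed)
    res <- run_pipeline(data, cfg)
    rows[[length(rows) + 1]] <-
      data.frame(variant = v, seed = seed, nmi = res$nmi, ari = res$ari)
  }
  do.call(rbind, rows)
}

#' Default synthetic benchmark specification
#'
#' The dataset used by the package's worked examples and acceptance checks:
#' 300 cells, 3 equally likely well-separated clusters, 500 genes, 800
#' peaks, 30% dropout (the [synthetic_spec()] defaults). `separation`
#' and sizes can be overridden for harder, smaller variants.
#'
#' @param ... overrides forwarded to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
default_benchmark_spec <- function(...) synthetic_spec(...)
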