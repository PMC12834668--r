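# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every node is an environment holding `value` (a matrix; scalars are 1x1),
# its `parents`, and a `vjp` closure mapping the upstream gradient to one
# gradient per parent. `ag_backward()` runs a depth-first topological sort
# and accumulates gradients into `$g`. The engine exists because the joint
# training objective backpropagates through attention, the multi-subspace
# encoder and the ZINB/Bernoulli likelihoods; its correctness is pinned by
# finite-difference tests.

ag_node <- function(value, parents = list(), vjp = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$g <- NULL
  e$.visited <- FALSE
  class(e) <- "ag_node"
  e
}

ag_const <- function(x) ag_node(as.matrix(x))
ag_param <- function(x) ag_node(as.matrix(x))

ag_value <- function(x) x$value

# backward pass from a scalar (1x1) root; fills $g on every reachable node
ag_backward <- function(root) {
  topo <- vector("list", 256L)
  n <- 0L
  visit <- function(node) {
    if (node$.visited) return(invisible())
    node$.visited <- TRUE
    for (p in node$parents) visit(p)
    n <<- n + 1L
    if (n > length(topo)) topo[[2L * n]] <- NULL
    topo[[n]] <<- node
    invisible()
  }
  visit(root)
  for (i in seq_len(n)) topo[[i]]$g <- NULL
  root$g <- matrix(1, nrow(root$value), ncol(root$value))
  for (i in rev(seq_len(n))) {
    nd <- topo[[i]]
    nd$.visited <- FALSE
    if (is.null(nd$vjp) || is.null(nd$g)) next
    gs <- nd$vjp(nd$g)
    for (k in seq_along(nd$parents)) {
      gk <- gs[[k]]
      if (is.null(gk)) next
      p <- nd$parents[[k]]
      p$g <- if (is.null(p$g)) gk else p$g + gk
    }
  }
  invisible(root)
}

# ---- primitive operations ------------------------------------------------

ag_mm <- function(a, b) {
  ag_node(a$value %*% b$value, list(a, b),
          function(g) list(g %*% t(b$value), t(a$value) %*% g))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# add a 1 x d bias row to every row of a
ag_add_bias <- function(a, b) {
  ag_node(sweep(a$value, 2, as.vector(b$value), `+`), list(a, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

ag_emul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_t <- function(a) ag_node(t(a$value), list(a), function(g) list(t(g)))

ag_relu <- function(a) {
  v <- pmax(a$value, 0)
  ag_node(v, list(a), function(g) list(g * (a$value > 0)))
}

ag_elu <- function(a) {
  x <- a$value
  neg <- x <= 0
  v <- x
  v[neg] <- expm1(x[neg])
  ag_node(v, list(a), function(g) {
    d <- g
    d[neg] <- g[neg] * exp(x[neg])
    list(d)
  })
}

ag_sigmoid <- function(a) {
  v <- stats::plogis(a$value)
  ag_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_softplus <- function(a) {
  x <- a$value
  v <- log1p(exp(pmin(x, 30)))
  big <- x > 30
  v[big] <- x[big]
  ag_node(v, list(a), function(g) list(g * stats::plogis(x)))
}

# exp with the pre-activation clamped to [log(lo), log(hi)] for stability;
# gradient is zero outside the clamp
ag_exp_clamp <- function(a, lo = 1e-5, hi = 1e6) {
  x <- a$value
  inside <- x > log(lo) & x < log(hi)
  v <- exp(pmin(pmax(x, log(lo)), log(hi)))
  ag_node(v, list(a), function(g) list(g * v * inside))
}

ag_log1p <- function(a) {
  ag_node(log1p(a$value), list(a), function(g) list(g / (1 + a$value)))
}

ag_row_softmax <- function(a) {
  v <- row_softmax(a$value)
  ag_node(v, list(a),
          function(g) list(v * (g - rowSums(g * v))))
}

ag_mean_all <- function(a) {
  ag_node(matrix(mean(a$value), 1, 1), list(a),
          function(g) list(matrix(g[1] / length(a$value),
                                  nrow(a$value), ncol(a$value))))
}

ag_sum_all <- function(a) {
  ag_node(matrix(sum(a$value), 1, 1), list(a),
          function(g) list(matrix(g[1], nrow(a$value), ncol(a$value))))
}

# row-wise dot products of two N x d matrices -> N x 1
ag_rowdot <- function(a, b) {
  ag_node(matrix(rowSums(a$value * b$value), ncol = 1), list(a, b),
          function(g) list(as.vector(g) * b$value, as.vector(g) * a$value))
}

ag_permute_rows <- function(a, perm) {
  ag_node(a$value[perm, , drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nrow(a$value), ncol(a$value))
            out[perm, ] <- g
            list(out)
          })
}

ag_col <- function(a, k) {
  ag_node(a$value[, k, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nrow(a$value), ncol(a$value))
            out[, k] <- g
            list(out)
          })
}

ag_cols <- function(a, idx) {
  ag_node(a$value[, idx, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nrow(a$value), ncol(a$value))
            out[, idx] <- g
            list(out)
          })
}

ag_colsums <- function(a) {
  ag_node(matrix(colSums(a$value), 1), list(a),
          function(g) list(matrix(g, nrow(a$value), ncol(a$value),
                                  byrow = TRUE)))
}

# scale each row i of `mat` by the scalar colv[i] (colv an N x 1 node)
ag_rowscale <- function(mat, colv) {
  cv <- as.vector(colv$value)
  ag_node(mat$value * cv, list(mat, colv),
          function(g) list(g * cv,
                           matrix(rowSums(g * mat$value), ncol = 1)))
}

ag_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ag_node(do.call(cbind, lapply(nodes, ag_value)), nodes,
          function(g) lapply(seq_along(nodes), function(k)
            g[, starts[k]:ends[k], drop = FALSE]))
}

# outer(dvec, c): constant column vector times a 1 x d parameter row
ag_outer_const <- function(dvec, cnode) {
  ag_node(outer(dvec, as.vector(cnode$value)), list(cnode),
          function(g) list(matrix(as.vector(t(g) %*% dvec), 1)))
}

# mean negative ZINB log-likelihood of counts x under (pi, mu, theta) nodes,
# with analytic gradients (see zinb_loglik_matrix for the likelihood)
ag_zinb_nll <- function(x, pi_n, mu_n, theta_n) {
  pi_ <- pmin(pmax(pi_n$value, 1e-10), 1 - 1e-10)
  mu <- mu_n$value
  theta <- theta_n$value
  n_entries <- length(x)
  l <- zinb_loglik_matrix(x, pi_, mu, theta)
  value <- matrix(-mean(l), 1, 1)

  zero <- x == 0
  pos <- !zero
  dl_dpi <- dl_dmu <- dl_dtheta <- x * 0
  if (any(zero)) {
    th <- theta[zero]; m_ <- mu[zero]; p_ <- pi_[zero]
    p0 <- exp(th * (log(th) - log(th + m_)))
    L0 <- p_ + (1 - p_) * p0
    dl_dpi[zero] <- (1 - p0) / L0
    dl_dmu[zero] <- -(1 - p_) * p0 * th / ((th + m_) * L0)
    dl_dtheta[zero] <- (1 - p_) * p0 *
      (log(th) + 1 - log(th + m_) - th / (th + m_)) / L0
  }
  if (any(pos)) {
    th <- theta[pos]; m_ <- mu[pos]; xp <- x[pos]
    dl_dpi[pos] <- -1 / (1 - pi_[pos])
    dl_dmu[pos] <- xp / m_ - (xp + th) / (th + m_)
    dl_dtheta[pos] <- digamma(xp + th) - digamma(th) +
      log(th) + 1 - log(th + m_) - (xp + th) / (th + m_)
  }
  ag_node(value, list(pi_n, mu_n, theta_n),
          function(g) {
            s <- -g[1] / n_entries
            list(s * dl_dpi, s * dl_dmu, s * dl_dtheta)
          })
}

# mean Bernoulli cross-entropy of binary x under mean matrix m (node)
ag_bernoulli_ce <- function(x, m_node) {
  m <- pmin(pmax(m_node$value, 1e-10), 1 - 1e-10)
  n_entries <- length(x)
  value <- matrix(-mean(x * log(m) + (1 - x) * log(1 - m)), 1, 1)
  ag_node(value, list(m_node),
          function(g) list(-(g[1] / n_entries) * (x / m - (1 - x) / (1 - m))))
}

# ---- shared numeric helpers ---------------------------------------------

row_softmax <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# ---- Adam optimizer ------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * p$value)
  st$v <- lapply(params, function(p) 0 * p$value)
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (is.null(p$g)) next
    st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * p$g
    st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * p$g^2
    p$value <- p$value -
      st$lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + st$eps)
  }
  invisible(st)
}
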