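# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation (enumeration, double
# loops, closed forms, stats:: distribution functions).

# Exact constrained-QP oracle for min_{a in simplex} ||a - v||^2 by
# enumerating candidate active sets: for each support S the equality-
# constrained minimiser is v_S + (1 - sum(v_S))/|S|; keep feasible
# candidates and return the one with the smallest objective.
oracle_simplex_qp <- function(v) {
  n <- length(v)
  best <- NULL
  best_obj <- Inf
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    a <- numeric(n)
    a[S] <- v[S] + (1 - sum(v[S])) / length(S)
    if (any(a[S] < -1e-12)) next
    a[a < 0] <- 0
    obj <- sum((a - v)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- a
    }
  }
  best
}

# Row objective of the adaptive-graph problem, evaluated directly
graph_row_objective <- function(a, d2_row, p_row) {
  sum(d2_row * a) + sum((a - p_row)^2)
}

# Oracle for one row of the adaptive graph: minimise the row objective over
# the simplex by active-set enumeration on the equivalent projection target.
oracle_graph_row <- function(d2_row, p_row) {
  v <- p_row - d2_row / 2
  n <- length(v)
  best <- NULL
  best_obj <- Inf
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    a <- numeric(n)
    a[S] <- v[S] + (1 - sum(v[S])) / length(S)
    if (any(a[S] < -1e-12)) next
    a[a < 0] <- 0
    obj <- graph_row_objective(a, d2_row, p_row)
    if (obj < best_obj) {
      best_obj <- obj
      best <- a
    }
  }
  list(a = best, objective = best_obj)
}

# From-scratch contingency-table NMI (arithmetic normalisation) and ARI
oracle_nmi_ari <- function(labels, truth) {
  tab <- table(labels, truth)
  n <- sum(tab)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  mi <- 0
  for (i in seq_along(p_i)) for (j in seq_along(p_j)) {
    if (p_ij[i, j] > 0)
      mi <- mi + p_ij[i, j] * log(p_ij[i, j] / (p_i[i] * p_j[j]))
  }
  h_i <- -sum(p_i[p_i > 0] * log(p_i[p_i > 0]))
  h_j <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nmi <- unname(if (h_i + h_j == 0) 1 else 2 * mi / (h_i + h_j))

  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_idx <- (sum_i + sum_j) / 2
  ari <- if (max_idx == expected) 0 else (sum_ij - expected) / (max_idx - expected)
  list(nmi = nmi, ari = ari)
}

# Double-loop JS mutual-information estimator
oracle_js <- function(u, r, perm) {
  sp <- function(x) log1p(exp(x))
  n <- nrow(u)
  pos <- neg <- numeric(n)
  for (i in seq_len(n)) {
    pos[i] <- -sp(-sum(u[i, ] * r[i, ]))
    neg[i] <- sp(sum(u[i, ] * r[perm[i], ]))
  }
  mean(pos) - mean(neg)
}

# Double-loop CLUB estimator
oracle_club <- function(u_k, u_l, beta) {
  n <- nrow(u_k)
  pos <- mean(vapply(seq_len(n), function(i) sum((u_l[i, ] - u_k[i, ])^2),
                     numeric(1)))
  negs <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) negs <- c(negs, sum((u_l[j, ] - u_k[i, ])^2))
  }
  (beta / 2) * (mean(negs) - pos)
}

# Triple-loop intra-cluster compactness (ordered pairs, 1/|c|^2 weight)
oracle_intra <- function(X, labels) {
  labs <- unique(labels)
  vals <- vapply(labs, function(l) {
    idx <- which(labels == l)
    s <- 0
    for (i in idx) for (j in idx) s <- s + sum((X[i, ] - X[j, ])^2)
    s / length(idx)^2
  }, numeric(1))
  mean(vals)
}
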