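ms_fixture <- function(N = 4, d = 8, p = 2, seed = 61) {
  set.seed(seed)
  list(Z = matrix(rnorm(N * d), N),
       deg = runif(N, 0.5, 1.5),
       params = init_msencoder(d, N, p = p, d_key = 4, seed = seed))
}

test_that("msencoder attention is a softmax over subspaces with the right limits", {
  f <- ms_fixture(p = 1, d = 8)
  # p = 1: the softmax over one column is identically 1
  s1 <- msencoder_forward(f$Z, f$deg, f$params)
  expect_equal(s1$att, matrix(1, 4, 1), ignore_attr = TRUE)
  V <- f$Z %*% f$params$W_V
  expect_equal(matrix(s1$embeddings[, 1, ], 4), V %*% f$params$proj[[1]],
               tolerance = 1e-12)

  # alpha = 0 and constant key scores: uniform attention 1/p
  f2 <- ms_fixture(p = 2)
  f2$params$alpha <- 0
  f2$params$Q <- matrix(0, 4, 2)   # KQ = 0, constant across subspaces
  s2 <- msencoder_forward(f2$Z, f2$deg, f2$params)
  expect_equal(s2$att, matrix(0.5, 4, 2), ignore_attr = TRUE)
})

test_that("msencoder matches a step-by-step matrix oracle", {
  f <- ms_fixture(N = 4, d = 8, p = 2)
  s <- msencoder_forward(f$Z, f$deg, f$params)
  K <- f$Z %*% f$params$W_K
  V <- f$Z %*% f$params$W_V
  S <- diag(f$deg) %*% f$params$W_S
  raw <- K %*% f$params$Q + f$params$alpha * S
  E <- exp(raw - apply(raw, 1, max))
  att <- E / rowSums(E)
  expect_equal(s$att, att, tolerance = 1e-10)
  for (k in 1:2)
    expect_equal(matrix(s$embeddings[, k, ], 4),
                 diag(att[, k]) %*% (V %*% f$params$proj[[k]]),
                 tolerance = 1e-10)
  expect_equal(rowSums(s$att), rep(1, 4), tolerance = 1e-8)
})

test_that("js_mi closed forms, bounds and enumeration oracle", {
  z <- matrix(0, 4, 2)
  perm <- c(2, 1, 4, 3)
  expect_equal(js_mi(z, z, perm), -2 * log(2), tolerance = 1e-12)

  # perfectly separated positives/negatives push the estimate towards 0:
  # paired dots -> +inf, deranged dots -> -inf
  u <- matrix(c(50, -50, 50, -50), ncol = 1)
  perm2 <- c(2, 1, 4, 3)
  expect_gt(js_mi(u, u, perm2), -1e-6)
  expect_lte(js_mi(u, u, perm2), 0)

  set.seed(62)
  u <- matrix(rnorm(8), 4)
  r <- matrix(rnorm(8), 4)
  expect_equal(js_mi(u, r, perm), oracle_js(u, r, perm), tolerance = 1e-12)
  expect_error(js_mi(u, r, c(1, 2, 4, 3)), "derangement")
  expect_error(js_mi(u[1, , drop = FALSE], r[1, , drop = FALSE]), "N >= 2")
})

test_that("js_mi is non-positive on random inputs", {
  set.seed(63)
  for (i in 1:20) {
    u <- matrix(rnorm(30, sd = 3), 10)
    r <- matrix(rnorm(30, sd = 3), 10)
    expect_lte(js_mi(u, r, seed = i), 0)
  }
})

test_that("club_upper_bound identities and enumeration oracle", {
  same <- matrix(1, 5, 3)
  expect_equal(club_upper_bound(same, same), 0)

  set.seed(64)
  u <- matrix(rnorm(15), 5)
  # u_l = u_k with distinct rows: only the positive cross term remains
  v <- club_upper_bound(u, u)
  expect_gt(v, 0)
  expect_equal(v, oracle_club(u, u, 1), tolerance = 1e-12)

  u_l <- matrix(rnorm(15), 5)
  expect_equal(club_upper_bound(u, u_l, beta = 1.7),
               oracle_club(u, u_l, 1.7), tolerance = 1e-12)
  expect_error(club_upper_bound(u, u_l, beta = 0), "positive")
})

test_that("club on independent views concentrates near zero", {
  set.seed(65)
  u <- matrix(rnorm(2000), ncol = 1)
  v <- matrix(rnorm(2000), ncol = 1)
  expect_lt(abs(club_upper_bound(u, v)), 0.05)
})

test_that("contrastive_loss reduces correctly and composes the two estimators", {
  f <- ms_fixture(N = 6, d = 8, p = 1, seed = 66)
  U <- msencoder_forward(f$Z, f$deg, f$params)
  R <- msencoder_forward(f$Z + 0.1, f$deg, init_msencoder(8, 6, 1, 4, seed = 67))
  perm <- random_derangement(6, 3)
  expect_equal(contrastive_loss(U, R, gamma = 0, neg_pairing = perm),
               -js_mi(matrix(U$embeddings[, 1, ], 6),
                      matrix(R$embeddings[, 1, ], 6), perm),
               tolerance = 1e-12)

  # all-zero embeddings: p * 2 log 2, CLUB terms vanish
  Uz <- U; Uz$embeddings[] <- 0
  Rz <- R; Rz$embeddings[] <- 0
  expect_equal(contrastive_loss(Uz, Rz, gamma = 3, neg_pairing = perm),
               2 * log(2), tolerance = 1e-12)

  f2 <- ms_fixture(N = 6, d = 8, p = 2, seed = 68)
  U2 <- msencoder_forward(f2$Z, f2$deg, f2$params)
  R2 <- msencoder_forward(f2$Z * 0.5, f2$deg,
                          init_msencoder(8, 6, 2, 4, seed = 69))
  perm <- random_derangement(6, 4)
  u1 <- matrix(U2$embeddings[, 1, ], 6); u2 <- matrix(U2$embeddings[, 2, ], 6)
  r1 <- matrix(R2$embeddings[, 1, ], 6); r2 <- matrix(R2$embeddings[, 2, ], 6)
  manual <- -(js_mi(u1, r1, perm) + js_mi(u2, r2, perm)) +
    0.7 * max(0, club_upper_bound(u1, u2, beta = 1.3))
  expect_equal(contrastive_loss(U2, R2, gamma = 0.7, beta = 1.3,
                                neg_pairing = perm),
               manual, tolerance = 1e-10)
})

test_that("concat_views interleaves subspaces recoverably", {
  # one cell-pair toy case
  mk <- function(vals, N, p, d_sub) {
    structure(list(embeddings = array(vals, c(N, p, d_sub)),
                   att = matrix(1 / p, N, p), d_sub = d_sub),
              class = "subspace_set")
  }
  U <- mk(c(1, 3), 2, 1, 1)
  R <- mk(c(2, 4), 2, 1, 1)
  expect_equal(concat_views(U, R), cbind(c(1, 3), c(2, 4)))

  set.seed(70)
  arr <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  arr2 <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  U2 <- mk(arr, 6, 2, 3)
  R2 <- mk(arr2, 6, 2, 3)
  Z <- concat_views(U2, R2)
  expect_equal(dim(Z), c(6L, 12L))
  expect_equal(Z[, 1:3], matrix(arr[, 1, ], 6))
  expect_equal(Z[, 4:6], matrix(arr[, 2, ], 6))
  expect_equal(Z[, 7:9], matrix(arr2[, 1, ], 6))
  expect_equal(Z[, 10:12], matrix(arr2[, 2, ], 6))
})

test_that("random_derangement has no fixed points and is seeded", {
  for (s in 1:10) {
    p <- random_derangement(8, s)
    expect_true(all(p != 1:8))
    expect_equal(sort(p), 1:8)
  }
  expect_identical(random_derangement(15, 3), random_derangement(15, 3))
  expect_error(random_derangement(1), "n >= 2")
})
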