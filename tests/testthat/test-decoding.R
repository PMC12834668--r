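test_that("fuse is the weighted elementwise sum", {
  set.seed(71)
  A <- matrix(rnorm(12), 3); B <- matrix(rnorm(12), 3); C <- matrix(rnorm(12), 3)
  expect_equal(fuse(A, B, C, 0, 0), A)
  expect_equal(fuse(A, A, A, 1, 1), 3 * A)
  out <- fuse(A, B, C, 0.3, 0.7)
  oracle <- A
  for (i in 1:3) for (j in 1:4)
    oracle[i, j] <- A[i, j] + 0.3 * B[i, j] + 0.7 * C[i, j]
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(fuse(A, B[1:2, ], C), "shape")
})

test_that("zinb_nll matches closed-form values at the analytic cases", {
  # x = 0, pi -> 0, mu = theta = 1: NB(0) = 0.5
  expect_equal(zinb_nll(matrix(0), matrix(1e-15), matrix(1), matrix(1)),
               -log(0.5), tolerance = 1e-9)
  # x = 0, pi = 0.5, mu = theta = 1: 0.5 + 0.5 * 0.5 = 0.75
  expect_equal(zinb_nll(matrix(0), matrix(0.5), matrix(1), matrix(1)),
               -log(0.75), tolerance = 1e-12)
})

test_that("zinb_nll equals the NB log-likelihood oracle at pi ~ 0", {
  grid <- expand.grid(x = 0:10, mu = c(0.5, 3, 20), theta = c(0.4, 2, 50))
  ours <- mapply(function(x, mu, theta)
    zinb_nll(matrix(x), matrix(1e-300), matrix(mu), matrix(theta)),
    grid$x, grid$mu, grid$theta)
  oracle <- -stats::dnbinom(grid$x, size = grid$theta, mu = grid$mu, log = TRUE)
  expect_equal(ours, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("zinb_nll converges to the Poisson NLL as dispersion grows", {
  x <- matrix(0:10, 1)
  mu <- matrix(3, 1, 11)
  nll <- zinb_nll(x, matrix(1e-300, 1, 11), mu, matrix(1e6, 1, 11))
  poisson <- mean(-stats::dpois(0:10, 3, log = TRUE))
  expect_equal(nll, poisson, tolerance = 1e-4)
})

test_that("zinb_nll mixes the zero point mass correctly on matrices", {
  set.seed(72)
  x <- matrix(rpois(20, 2), 4)
  pi_ <- matrix(runif(20, 0.1, 0.6), 4)
  mu <- matrix(runif(20, 0.5, 5), 4)
  theta <- matrix(runif(20, 0.5, 4), 4)
  nb <- stats::dnbinom(x, size = theta, mu = mu)
  lik <- ifelse(x == 0, pi_ + (1 - pi_) * nb, (1 - pi_) * nb)
  expect_equal(zinb_nll(x, pi_, mu, theta), -mean(log(lik)), tolerance = 1e-10)
  expect_error(zinb_nll(-x, pi_, mu, theta), "non-negative")
  expect_error(zinb_nll(x, pi_ + 1, mu, theta), "strictly in")
})

test_that("the NLL over mu is minimised near the sample mean of NB data", {
  set.seed(73)
  x <- matrix(rnbinom(5000, size = 2, mu = 4), ncol = 1)
  grid <- seq(2, 6, by = 0.01)
  nll <- vapply(grid, function(m)
    zinb_nll(x, matrix(1e-300, nrow(x)), matrix(m, nrow(x)),
             matrix(2, nrow(x))), numeric(1))
  expect_lt(abs(grid[which.min(nll)] - 4) / 4, 0.05)
})

test_that("decoder heads respect their ranges; zero weights give the fixed point", {
  p <- init_decoder(3, 4, 5, hidden = 6, seed = 74)
  for (nm in c("W_h", "W_pi", "W_mu", "W_theta", "W_ha", "W_a")) p[[nm]][] <- 0
  Z <- matrix(0, 2, 3)
  zp <- zinb_decode(Z, p)
  expect_equal(zp$Pi, matrix(0.5, 2, 4))
  expect_equal(zp$M_r, matrix(1, 2, 4))
  expect_equal(zp$Theta, matrix(1, 2, 4))
  expect_equal(bernoulli_decode(Z, p), matrix(0.5, 2, 5))

  p2 <- init_decoder(3, 4, 5, hidden = 6, seed = 75)
  set.seed(76)
  Z <- matrix(rnorm(6, sd = 2), 2)
  zp2 <- zinb_decode(Z, p2)
  expect_true(all(zp2$Pi > 0 & zp2$Pi < 1))
  expect_true(all(zp2$M_r > 0 & zp2$Theta > 0))
  ma <- bernoulli_decode(Z, p2)
  expect_true(all(ma > 0 & ma < 1))

  # hand oracle: each modality trunk is ELU(Z W + b), heads linear
  h <- Z %*% p2$W_h
  h <- ifelse(h > 0, h, exp(h) - 1)
  expect_equal(zp2$Pi, plogis(h %*% p2$W_pi), tolerance = 1e-10)
  expect_equal(zp2$M_r, exp(h %*% p2$W_mu), tolerance = 1e-10)
  h_a <- Z %*% p2$W_ha
  h_a <- ifelse(h_a > 0, h_a, exp(h_a) - 1)
  expect_equal(ma, plogis(h_a %*% p2$W_a), tolerance = 1e-10)
})

test_that("bernoulli_ce matches the elementwise formula", {
  expect_equal(bernoulli_ce(matrix(1), matrix(0.5)), log(2), tolerance = 1e-12)
  expect_lt(bernoulli_ce(matrix(0), matrix(1e-12)), 1e-10)
  set.seed(77)
  x <- matrix(rbinom(20, 1, 0.4), 4)
  u <- matrix(runif(20, 0.05, 0.95), 4)
  oracle <- -mean(x * log(u) + (1 - x) * log(1 - u))
  expect_equal(bernoulli_ce(x, u), oracle, tolerance = 1e-12)
  expect_error(bernoulli_ce(x + 0.5, u), "binary")
})

test_that("total_loss is linear in its weights and composes components", {
  set.seed(78)
  x_r <- matrix(rpois(12, 3), 3)
  x_a <- matrix(rbinom(15, 1, 0.3), 3)
  zp <- structure(list(Pi = matrix(runif(12, 0.2, 0.8), 3),
                       M_r = matrix(runif(12, 1, 5), 3),
                       Theta = matrix(runif(12, 1, 3), 3)),
                  class = "zinb_params")
  m_a <- matrix(runif(15, 0.1, 0.9), 3)
  contra <- -0.42
  base <- zinb_nll(x_r, zp$Pi, zp$M_r, zp$Theta)
  ce <- bernoulli_ce(x_a, m_a)
  expect_equal(total_loss(x_r, zp, x_a, m_a, contra, 0, 0), base)
  l1 <- total_loss(x_r, zp, x_a, m_a, contra, 0.2, 0.5)
  l2 <- total_loss(x_r, zp, x_a, m_a, contra, 0.4, 0.5)
  expect_equal(l2 - l1, 0.2 * ce, tolerance = 1e-10)
  expect_equal(l1, base + 0.2 * ce + 0.5 * contra, tolerance = 1e-10)
})

test_that("the likelihood losses are invariant to cell permutation", {
  set.seed(79)
  x_r <- matrix(rpois(40, 3), 8)
  x_a <- matrix(rbinom(24, 1, 0.4), 8)
  pi_ <- matrix(runif(40, 0.2, 0.8), 8)
  mu <- matrix(runif(40, 1, 4), 8)
  th <- matrix(runif(40, 1, 4), 8)
  ma <- matrix(runif(24, 0.1, 0.9), 8)
  perm <- sample(8)
  expect_equal(zinb_nll(x_r, pi_, mu, th),
               zinb_nll(x_r[perm, ], pi_[perm, ], mu[perm, ], th[perm, ]),
               tolerance = 1e-9)
  expect_equal(bernoulli_ce(x_a, ma), bernoulli_ce(x_a[perm, ], ma[perm, ]),
               tolerance = 1e-9)
})
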