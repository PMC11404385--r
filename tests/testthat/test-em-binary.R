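test_that("the quadrature grid integrates Gaussian moments exactly enough", {
  Snu <- matrix(c(1.3, 0.4, 0.4, 0.9), 2)
  gr <- gauss_hermite_grid(12, Snu)
  expect_equal(sum(gr$weights), 1, tolerance = 1e-10)   # phi == 1
  expect_lt(max(abs(colSums(gr$weights * gr$nodes))), 1e-10)
  M2 <- crossprod(gr$nodes, gr$weights * gr$nodes)
  expect_lt(max(abs(M2 - Snu)), 1e-8)
  # K = 1, Sigma = I2, M = 2: nodes at +/- 1 on each axis
  g2 <- gauss_hermite_grid(2, diag(2))
  expect_equal(sort(unique(round(g2$nodes[, 1], 10))), c(-1, 1))
  expect_equal(sort(unique(round(g2$nodes[, 2], 10))), c(-1, 1))
  expect_true(all(gr$weights > 0))
  expect_error(gauss_hermite_grid(1, diag(2)), "at least 2")
})

test_that("the conditional outcome probability is a stable logistic", {
  nu <- matrix(rnorm(20), 10, 2)
  p1 <- bernoulli_conditional(1, nu, beta = c(0, 0, 0), B = 1)
  expect_equal(p1, rep(0.5, 10))
  beta <- c(0.3, 1.2, -0.7)
  expect_equal(bernoulli_conditional(1, nu, beta, B = 0.8) +
                 bernoulli_conditional(0, nu, beta, B = 0.8),
               rep(1, 10))
  big <- bernoulli_conditional(1, matrix(c(40, 0), 1), c(0, 1, 0), B = 1)
  expect_equal(big, 1)
  expect_equal(bernoulli_conditional(0, matrix(c(40, 0), 1), c(0, 1, 0), B = 1),
               exp(-40), tolerance = 1e-10)
})

# small K = 1 binary toy shared by the integration tests; noise is kept at
# the same order as the latent signal so the prior-scaled quadrature grid
# resolves the per-subject posterior
.binary_toy <- function(seed = 31, N = 8) {
  pr <- random_params(p = 2, q = 2, seed = seed, family = "bernoulli")
  pr$sig_e2 <- 2; pr$sig_f2 <- 2.5
  sc <- sim_scenario(N = N, p = 2, q = 2, family = "bernoulli", seed = seed)
  dat <- simulate_dataset(sc, params = pr)
  list(pr = pr, dat = dat)
}

test_that("quadrature log-likelihood matches dense grid integration", {
  toy <- .binary_toy()
  ll <- loglik_binary(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z, M = 32)
  orc <- oracle_binary_marginal(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z,
                                lim = 8, ngrid = 401)
  expect_equal(ll, sum(log(orc$f)), tolerance = 1e-6)
  # quadrature convergence: doubling M barely moves the value
  ll32 <- loglik_binary(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z, M = 32)
  ll64 <- loglik_binary(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z, M = 64)
  expect_lt(abs(ll64 - ll32), 1e-6)
})

test_that("beta = 0 factorizes the likelihood into the omics marginal", {
  toy <- .binary_toy(seed = 32)
  pr0 <- toy$pr; pr0$a0 <- 0; pr0$a <- 0; pr0$b <- 0
  ll <- loglik_binary(pr0, toy$dat$x, toy$dat$y, toy$dat$z, M = 32)
  Sxy <- oracle_sigma_theta(pr0)[1:4, 1:4]
  llxy <- oracle_mvn_loglik(cbind(toy$dat$x, toy$dat$y), Sxy)
  expect_equal(ll, llxy + nrow(toy$dat$x) * log(0.5), tolerance = 1e-6)
})

test_that("binary E-step moments match the dense grid and are coherent", {
  toy <- .binary_toy(seed = 33, N = 10)
  mom <- e_step_binary(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z, M = 32)
  orc <- oracle_binary_marginal(toy$pr, toy$dat$x, toy$dat$y, toy$dat$z,
                                lim = 8, ngrid = 401)
  expect_lt(max(abs(mom$mean[, 1] - orc$Et)), 1e-5)
  expect_lt(max(abs(mom$mean[, 2] - orc$Eu)), 1e-5)
  agg <- cbind(orc$Ett, orc$Etu, orc$Euu)
  expect_lt(max(abs(c(mom$M[1, 1], mom$M[1, 2], mom$M[2, 2]) -
                      colSums(agg))), 1e-4)
  # per-subject conditional covariance of nu is PSD
  gr <- mom$grid
  for (i in seq_len(nrow(mom$omega))) {
    m2 <- crossprod(gr$nodes, mom$omega[i, ] * gr$nodes)
    cc <- m2 - tcrossprod(mom$mean[i, 1:2])
    expect_gt(min(eigen((cc + t(cc)) / 2, only.values = TRUE)$values), -1e-10)
  }
  # beta = 0: moments condition on (x, y) only
  pr0 <- toy$pr; pr0$a0 <- 0; pr0$a <- 0; pr0$b <- 0
  mom0 <- e_step_binary(pr0, toy$dat$x, toy$dat$y, toy$dat$z, M = 32)
  orc0 <- oracle_conditioning(pr0, cbind(toy$dat$x, toy$dat$y),
                              with_z = FALSE)
  expect_lt(max(abs(mom0$mean[, 1:2] - orc0$mean[, 1:2])), 1e-6)
  expect_lt(max(abs(mom0$mean[, 3:4] - orc0$mean[, 3:4])), 1e-6)
})

test_that("the Q-beta gradient matches central differences", {
  toy <- .binary_toy(seed = 34, N = 12)
  pr <- toy$pr
  grid <- gauss_hermite_grid(16, build_joint_covariance(pr)$Sigma_nu)
  co <- glmpo2pls:::.binary_core(pr, toy$dat$x, toy$dat$y, toy$dat$z, grid)
  parts <- glmpo2pls:::.Qbeta_parts(co$omega, toy$dat$z, co$Tn, co$Un, pr$B)
  beta <- c(0.1, 0.8, -0.4)
  g <- glmpo2pls:::.Qbeta_grad(parts, beta)
  g2 <- grad_Q_beta(pr, toy$dat$x, toy$dat$y, toy$dat$z, grid, beta)
  expect_equal(g, g2, tolerance = 1e-12)
  eps <- 1e-5
  for (j in 1:3) {
    e <- numeric(3); e[j] <- eps
    fd <- (glmpo2pls:::.Qbeta_value(parts, beta + e) -
             glmpo2pls:::.Qbeta_value(parts, beta - e)) / (2 * eps)
    expect_equal(g[j], fd, tolerance = 1e-5)
  }
  # at the maximizer of Q-beta the gradient vanishes
  opt <- optim(beta, function(b) -glmpo2pls:::.Qbeta_value(parts, b),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(sqrt(sum(glmpo2pls:::.Qbeta_grad(parts, opt$par)^2)), 1e-5)
})

test_that("backtracking satisfies the Armijo rule on closed-form objectives", {
  # concave quadratic Q(beta) = -||beta||^2 / 2 from beta = (1, 0, 0)
  Q <- function(b) -sum(b^2) / 2
  beta <- c(1, 0, 0)
  up <- backtracking_update(beta, grad = -beta, Qfun = Q)
  expect_gte(Q(up$beta) - Q(beta), 0.5 * up$s * sum(beta^2) - 1e-12)
  expect_equal(up$s, 1)   # closed form: s = 1 already satisfies the rule
  # linear objective: s = 1 accepted
  upl <- backtracking_update(c(0, 0), grad = c(1, 2),
                             Qfun = function(b) sum(b * c(1, 2)))
  expect_equal(upl$s, 1)
  # zero gradient: no movement
  up0 <- backtracking_update(c(1, 2), grad = c(0, 0), Qfun = Q)
  expect_equal(up0$beta, c(1, 2))
  # a descent direction forces the step to shrink towards zero with warning
  expect_warning(
    backtracking_update(c(1, 0), grad = c(1, 0),
                        Qfun = function(b) -sum(b^2) * 1e6),
    "underflow")
})

test_that("the binary EM ascends and recovers sign-correct coefficients", {
  sc <- sim_scenario(N = 500, p = 20, q = 6, family = "bernoulli", seed = 41)
  dat <- simulate_dataset(sc)
  fit <- glmpo2pls(dat$x, dat$y, dat$z, family = "bernoulli",
                   max_iter = 300, keep_data = FALSE)
  expect_gt(min(diff(fit$loglik_trace)), -1e-6)
  est <- glmpo2pls:::.align_to_truth(fit$params, dat$params)
  expect_gt(est$a, 0)
  expect_gt(est$b, 0)
  expect_lt(abs((est$a - 2) / 2), 0.5)
  expect_lt(abs((est$b - 1) / 1), 0.5)
})

test_that("degenerate binary outcomes are rejected", {
  sc <- sim_scenario(N = 30, p = 6, q = 4, family = "bernoulli", seed = 3)
  dat <- simulate_dataset(sc)
  expect_error(glmpo2pls(dat$x, dat$y, rep(1, 30), family = "bernoulli"),
               "separation|variation")
  expect_error(glmpo2pls(dat$x, dat$y, dat$z + 1, family = "bernoulli"),
               "0/1")
  expect_error(fit_binary(dat$x, dat$y, dat$z,
                          po2pls_dims(6, 4, 3, 1, 1, 30), M = 12),
               "grid")
})
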