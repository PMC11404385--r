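test_that("low-rank log-likelihood equals the dense-matrix evaluation", {
  for (sd in c(1, 2)) {
    pr <- random_params(p = 5, q = 4, seed = sd)
    sc <- sim_scenario(N = 30, p = 5, q = 4, seed = sd + 10)
    dat <- simulate_dataset(sc, params = pr)
    S <- cbind(dat$x, dat$y, dat$z)
    expect_equal(loglik_normal(pr, dat$x, dat$y, dat$z),
                 oracle_mvn_loglik(S, oracle_sigma_theta(pr)),
                 tolerance = 1e-10)
  }
  # larger p exercises the low-rank path against the same dense oracle
  pr <- random_params(p = 50, q = 6, K = 2, Kx = 2, Ky = 1, seed = 3,
                      a = c(2, 1), b = c(1, 0.5))
  sc <- sim_scenario(N = 25, p = 50, q = 6, K = 2, Kx = 2, Ky = 1,
                     a_coef = c(2, 1), b_coef = c(1, 0.5), seed = 13)
  dat <- simulate_dataset(sc, params = pr)
  expect_equal(loglik_normal(pr, dat$x, dat$y, dat$z),
               oracle_mvn_loglik(cbind(dat$x, dat$y, dat$z),
                                 oracle_sigma_theta(pr)),
               tolerance = 1e-8)
  # all-zero data: quadratic form vanishes
  z0 <- matrix(0, 7, 5); y0 <- matrix(0, 7, 4)
  pr0 <- random_params(p = 5, q = 4, seed = 1)
  ld <- determinant(oracle_sigma_theta(pr0))$modulus
  expect_equal(loglik_normal(pr0, z0, y0, rep(0, 7)),
               -(7 / 2) * (10 * log(2 * pi) + as.numeric(ld)),
               tolerance = 1e-9)
})

test_that("E-step moments equal brute-force Gaussian conditioning", {
  for (cfg in list(list(p = 5, q = 4, K = 1, Kx = 1, Ky = 1),
                   list(p = 40, q = 15, K = 2, Kx = 2, Ky = 2))) {
    K <- cfg$K
    pr <- random_params(p = cfg$p, q = cfg$q, K = K, Kx = cfg$Kx,
                        Ky = cfg$Ky, seed = 5,
                        a = seq_len(K) + 1, b = rev(seq_len(K)) / 2)
    sc <- sim_scenario(N = 12, p = cfg$p, q = cfg$q, K = K, Kx = cfg$Kx,
                       Ky = cfg$Ky, a_coef = seq_len(K) + 1,
                       b_coef = rev(seq_len(K)) / 2, seed = 15)
    dat <- simulate_dataset(sc, params = pr)
    mom <- e_step_normal(pr, dat$x, dat$y, dat$z)
    orc <- oracle_conditioning(pr, cbind(dat$x, dat$y, dat$z))
    expect_lt(max(abs(mom$mean - orc$mean)), 1e-8)
    expect_lt(max(abs(mom$cov - orc$cov)), 1e-8)
    expect_lt(max(abs(mom$M - (crossprod(orc$mean) + nrow(orc$mean) * orc$cov))),
              1e-6)
  }
})

test_that("zero data and zero coefficients degenerate the E-step as expected", {
  pr <- random_params(p = 5, q = 4, seed = 2)
  mom0 <- e_step_normal(pr, matrix(0, 6, 5), matrix(0, 6, 4), rep(0, 6))
  expect_equal(max(abs(mom0$mean)), 0)
  # a = b = 0: z is uninformative, moments condition on (x, y) alone
  pr0 <- pr; pr0$a <- 0; pr0$b <- 0
  sc <- sim_scenario(N = 10, p = 5, q = 4, seed = 3)
  dat <- simulate_dataset(sc, params = pr)
  mom <- e_step_normal(pr0, dat$x, dat$y, dat$z)
  orc <- oracle_conditioning(pr0, cbind(dat$x, dat$y), with_z = FALSE)
  expect_lt(max(abs(mom$mean - orc$mean)), 1e-10)
})

test_that("outcome M-step solves the printed normal equations", {
  pr <- random_params(p = 6, q = 5, seed = 7)
  sc <- sim_scenario(N = 60, p = 6, q = 5, seed = 17)
  dat <- simulate_dataset(sc, params = pr)
  mom <- e_step_normal(pr, dat$x, dat$y, dat$z)
  up <- m_step_outcome_normal(mom, dat$z)

  # generalized-least-squares oracle on the same sufficient statistics
  K <- 1
  Et <- mom$mean[, 1]; Eu <- mom$mean[, 2]
  Eh <- Eu - pr$B * Et
  G <- mom$cov
  Vth <- matrix(c(G[1, 1], G[1, 2] - pr$B * G[1, 1],
                  G[1, 2] - pr$B * G[1, 1],
                  G[2, 2] - 2 * pr$B * G[1, 2] + pr$B^2 * G[1, 1]), 2)
  D <- cbind(Et, Eh)
  Mo <- crossprod(D) + nrow(D) * Vth
  ab <- solve(Mo, drop(crossprod(D, dat$z)))
  expect_equal(c(up$a, up$b), unname(ab), tolerance = 1e-10)
  sg <- (sum(dat$z^2) - 2 * sum(ab * crossprod(D, dat$z)) +
           drop(crossprod(ab, Mo %*% ab))) / length(dat$z)
  expect_equal(up$sig_g2, sg, tolerance = 1e-10)

  # z orthogonal to the moment columns: zero coefficients, sig_g2 = mean(z^2)
  mom2 <- mom
  mom2$Sz <- rep(0, length(mom2$Sz))
  mom2$Szz <- sum(dat$z^2)
  up2 <- m_step_outcome_normal(mom2, dat$z)
  expect_equal(c(up2$a, up2$b), c(0, 0))
  expect_equal(up2$sig_g2, mean(dat$z^2))
})

test_that("the true parameters are a fixed point of the M-step at population statistics", {
  pr <- canonicalize_signs(random_params(p = 6, q = 5, seed = 8))
  mom <- population_moments(pr, N = 1e6)
  up <- m_step_outcome_normal(mom, NULL)
  expect_equal(up$a, pr$a, tolerance = 1e-6)
  expect_equal(up$b, pr$b, tolerance = 1e-6)
  expect_equal(up$sig_g2, pr$sig_g2, tolerance = 1e-6)
  newp <- m_step_po2pls_block(mom, NULL, NULL, pr, z = NULL)
  expect_equal(newp$W, pr$W, tolerance = 1e-6)
  expect_equal(newp$C, pr$C, tolerance = 1e-6)
  expect_equal(newp$Wo, pr$Wo, tolerance = 1e-6)
  expect_equal(newp$Co, pr$Co, tolerance = 1e-6)
  expect_equal(newp$B, pr$B, tolerance = 1e-5)
  expect_equal(newp$St, pr$St, tolerance = 1e-6)
  expect_equal(newp$Sh, pr$Sh, tolerance = 1e-5)
  expect_equal(newp$sig_e2, pr$sig_e2, tolerance = 1e-6)
  expect_equal(newp$sig_f2, pr$sig_f2, tolerance = 1e-6)
})

test_that("EM iterations never decrease the observed-data log-likelihood", {
  for (sd in 1:3) {
    sc <- sim_scenario(N = 80, p = 15, q = 6, seed = sd,
                       noise_x = ifelse(sd == 2, 0.8, 0.4))
    dat <- simulate_dataset(sc)
    fit <- suppressWarnings(
      fit_normal(dat$x, dat$y, dat$z - mean(dat$z),
                 po2pls_dims(15, 6, 1, 1, 1, 80),
                 tol = 1e-8, max_iter = 200))
    expect_gt(min(diff(fit$loglik_trace)), -1e-8)
  }
})

test_that("tol = Inf stops after a single iteration", {
  sc <- sim_scenario(N = 40, p = 8, q = 5, seed = 4)
  dat <- simulate_dataset(sc)
  fit <- fit_normal(dat$x, dat$y, dat$z - mean(dat$z),
                    po2pls_dims(8, 5, 1, 1, 1, 40), tol = Inf)
  expect_length(fit$loglik_trace, 2)
  expect_true(fit$converged)
})

test_that("fitting recovers the generating coefficients at N = 1000", {
  sc <- sim_scenario(N = 1000, p = 40, q = 8, seed = 51)
  dat <- simulate_dataset(sc)
  fit <- glmpo2pls(dat$x, dat$y, dat$z, keep_data = FALSE)
  est <- glmpo2pls:::.align_to_truth(fit$params, dat$params)
  expect_lt(abs((est$a - 2) / 2), 0.15)
  expect_lt(abs((est$b - 1) / 1), 0.15)
  expect_gt(abs(sum(est$W[, 1] * dat$params$W[, 1])), 0.95)
})

test_that("a fit re-fitted on data from its own parameters is self-consistent", {
  sc <- sim_scenario(N = 300, p = 10, q = 6, seed = 61)
  dat <- simulate_dataset(sc)
  fit1 <- glmpo2pls(dat$x, dat$y, dat$z, keep_data = FALSE)
  big <- simulate(fit1, nsim = 1, seed = 99, N = 20000)[[1]]
  fit2 <- glmpo2pls(big$x, big$y, big$z, keep_data = FALSE)
  est <- glmpo2pls:::.align_to_truth(fit2$params, fit1$params)
  expect_equal(est$a, fit1$params$a, tolerance = 0.1)
  expect_equal(est$b, fit1$params$b, tolerance = 0.15)
  expect_gt(abs(sum(est$W[, 1] * fit1$params$W[, 1])), 0.99)
})
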