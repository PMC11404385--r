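test_that("chi-square test statistics behave as quadratic forms", {
  # null statistic
  t0 <- test_full(c(0, 0), diag(2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
  # r = 1, alpha = (1,1), Pi = I: T = 2, p = exp(-1)
  t1 <- test_full(c(1, 1), diag(2))
  expect_equal(t1$statistic, 2)
  expect_equal(t1$df, 2)
  expect_equal(t1$p.value, exp(-1))
  # invariance under joint invertible reparameterization
  set.seed(5)
  alpha <- rnorm(4)
  A <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  Pi <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  M <- matrix(rnorm(16), 4)
  t_a <- test_full(alpha, Pi)
  t_b <- test_full(drop(alpha %*% t(M)), M %*% Pi %*% t(M))
  expect_equal(t_a$statistic, t_b$statistic, tolerance = 1e-10)
  # p monotone decreasing in the statistic
  expect_gt(test_full(c(0.5, 0.5), diag(2))$p.value, t1$p.value)
  expect_error(test_full(c(1, 1), matrix(c(1, 2, 2, 1), 2)), "positive")
})

test_that("the component-wise test extracts the right sub-block", {
  tk <- test_componentwise(c(0, 1, 0, 2), diag(4), 2)
  expect_equal(tk$statistic, 5)
  expect_equal(tk$df, 2L)
  # K = 1: component-wise equals the full test
  a <- c(0.7, -0.3); Pi <- matrix(c(0.5, 0.1, 0.1, 0.4), 2)
  expect_equal(test_componentwise(a, Pi, 1)$statistic,
               test_full(a, Pi)$statistic)
  expect_error(test_componentwise(a, Pi, 2), "k must be")
})

test_that("the information collapses to classical regression when latents are observed", {
  set.seed(9)
  n <- 400
  D <- cbind(rnorm(n), rnorm(n))
  alpha <- c(1.5, -0.5)
  sg <- 0.49
  z <- drop(D %*% alpha) + rnorm(n, sd = sqrt(sg))
  ab <- drop(solve(crossprod(D), crossprod(D, z)))
  # synthetic fit whose E-step has no latent uncertainty
  fit <- list(params = list(a = ab[1], b = ab[2], sig_g2 = sg,
                            family = "gaussian",
                            dims = po2pls_dims(5, 4, 1, 1, 1, n)),
              moments = list(mean = cbind(D[, 1], D[, 1] + D[, 2],
                                          rnorm(n), rnorm(n)),
                             cov = matrix(0, 4, 4), B_used = 1,
                             dims = po2pls_dims(5, 4, 1, 1, 1, n)))
  info <- alpha_information(fit, z)
  expect_equal(info$Pi_alpha, sg * solve(crossprod(D)), tolerance = 1e-8)

  # duplicating every subject doubles the information, halving Pi
  fit2 <- fit
  fit2$moments$mean <- rbind(fit$moments$mean, fit$moments$mean)
  info2 <- alpha_information(fit2, c(z, z))
  expect_equal(info2$Pi_alpha, info$Pi_alpha / 2, tolerance = 1e-6)
})

test_that("estimator dispersion matches the Louis covariance across replicates", {
  reps <- 120
  alphas <- matrix(NA_real_, reps, 2)
  Pis <- matrix(NA_real_, reps, 2)
  sc <- sim_scenario(N = 150, p = 15, q = 6, seed = 1)
  for (r in seq_len(reps)) {
    sc$seed <- glmpo2pls:::.subseed(202, r)
    dat <- simulate_dataset(sc)
    fit <- glmpo2pls(dat$x, dat$y, dat$z, keep_data = FALSE)
    est <- glmpo2pls:::.align_to_truth(fit$params, dat$params)
    alphas[r, ] <- c(est$a, est$b)
    info <- alpha_information(fit, fit$z)
    Pis[r, ] <- diag(info$Pi_alpha)
  }
  ratio <- apply(alphas, 2, var) / colMeans(Pis)
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})

test_that("full-test wrapper ties the pieces together", {
  sc <- sim_scenario(N = 200, p = 12, q = 6, seed = 71)
  dat <- simulate_dataset(sc)
  fit <- glmpo2pls(dat$x, dat$y, dat$z)
  tst <- test_association(fit, fit$z)
  expect_s3_class(tst, "po2pls_test")
  expect_lt(tst$full$p.value, 1e-6)   # strong simulated association
  expect_equal(tst$full$df, 2L)
  expect_equal(tst$componentwise$statistic, tst$full$statistic)  # K = 1
  expect_false(tst$caveat)
  sm <- summary(fit)
  expect_output(print(sm), "Full test")
})

test_that("the inner-relation Wald test flags a strong t-u link and respects the sign gauge", {
  sc <- sim_scenario(N = 500, p = 15, q = 6, seed = 81)
  dat <- simulate_dataset(sc)
  fit <- glmpo2pls(dat$x, dat$y, dat$z, keep_data = FALSE)
  tb <- test_omics_association(fit)
  expect_equal(tb$df, 1L)
  expect_lt(tb$p.value, 1e-3)   # truth B = 1, strongly coupled
  # flipping a joint component's sign leaves the statistic unchanged
  flip <- fit
  flip$params$W[, 1] <- -flip$params$W[, 1]
  flip$params$C[, 1] <- -flip$params$C[, 1]
  flip$params$a <- -flip$params$a
  flip$params$b <- -flip$params$b
  flip$moments$mean[, 1:2] <- -flip$moments$mean[, 1:2]
  tb2 <- test_omics_association(flip)
  expect_equal(tb2$statistic, tb$statistic, tolerance = 1e-10)
})

test_that("binary-family inference is computed under the normality caveat", {
  sc <- sim_scenario(N = 300, p = 12, q = 5, family = "bernoulli", seed = 91)
  dat <- simulate_dataset(sc)
  fit <- glmpo2pls(dat$x, dat$y, dat$z, family = "bernoulli",
                   max_iter = 200, keep_data = FALSE)
  tst <- test_association(fit, dat$z)
  expect_true(tst$caveat)
  expect_true(tst$full$p.value >= 0 && tst$full$p.value <= 1)
  expect_lt(tst$full$p.value, 0.05)
  expect_output(print(tst), "asymptotic normality")
})
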