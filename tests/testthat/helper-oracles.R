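# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths (dense linear algebra, blockwise
# textbook formulas, brute-force grids) than the package internals.

# Small valid random parameter set.
random_params <- function(p = 5, q = 4, K = 1, Kx = 1, Ky = 1, seed = 1,
                          family = "gaussian", a = NULL, b = NULL) {
  set.seed(seed)
  Lx <- qr.Q(qr(matrix(rnorm(p * (K + Kx)), p)))
  Ly <- qr.Q(qr(matrix(rnorm(q * (K + Ky)), q)))
  St <- if (K == 1) 1 else as.numeric(K:1)
  po2pls_params(W = Lx[, 1:K, drop = FALSE],
                C = Ly[, 1:K, drop = FALSE],
                Wo = Lx[, K + seq_len(Kx), drop = FALSE],
                Co = Ly[, K + seq_len(Ky), drop = FALSE],
                B = rep(1, K), St = St, Sto = rep(1, Kx), Suo = rep(1, Ky),
                Sh = rep(2 / 3, K), sig_e2 = 0.3, sig_f2 = 0.4,
                a = if (is.null(a)) rep(2, K) else a,
                b = if (is.null(b)) rep(1, K) else b,
                a0 = if (family == "bernoulli") 0.2 else 0,
                sig_g2 = if (family == "gaussian") 0.9 else NULL,
                family = family)
}

# Blockwise joint covariance of (x, y, z) assembled term by term from the
# model's covariance formula, independent of the package's low-rank builder.
oracle_sigma_theta <- function(pr) {
  K <- pr$dims$K
  Bm <- diag(pr$B, K); Stm <- diag(pr$St, K); Shm <- diag(pr$Sh, K)
  Sum <- Bm %*% Stm %*% Bm + Shm
  Sxx <- pr$W %*% Stm %*% t(pr$W) + pr$Wo %*% diag(pr$Sto, pr$dims$Kx) %*%
    t(pr$Wo) + pr$sig_e2 * diag(pr$dims$p)
  Syy <- pr$C %*% Sum %*% t(pr$C) + pr$Co %*% diag(pr$Suo, pr$dims$Ky) %*%
    t(pr$Co) + pr$sig_f2 * diag(pr$dims$q)
  Sxy <- pr$W %*% Stm %*% Bm %*% t(pr$C)
  Sxz <- pr$W %*% Stm %*% matrix(pr$a, K)
  Syz <- pr$C %*% (Shm %*% matrix(pr$b, K) + Bm %*% Stm %*% matrix(pr$a, K))
  szz <- drop(t(pr$a) %*% Stm %*% pr$a + t(pr$b) %*% Shm %*% pr$b) +
    if (pr$family == "gaussian") pr$sig_g2 else 0
  rbind(cbind(Sxx, Sxy, Sxz),
        cbind(t(Sxy), Syy, Syz),
        cbind(t(Sxz), t(Syz), szz))
}

# Loading map and latent covariance of zeta = (t, u, t_o, u_o), re-derived.
oracle_lambda <- function(pr) {
  d <- pr$dims; K <- d$K
  Lz <- c(pr$a - pr$B * pr$b, pr$b, numeric(d$Kx + d$Ky))
  rbind(cbind(pr$W, matrix(0, d$p, K), pr$Wo, matrix(0, d$p, d$Ky)),
        cbind(matrix(0, d$q, K), pr$C, matrix(0, d$q, d$Kx), pr$Co),
        Lz)
}

oracle_sigma_zeta <- function(pr) {
  d <- pr$dims; K <- d$K
  Bm <- diag(pr$B, K); Stm <- diag(pr$St, K)
  top <- cbind(Stm, Stm %*% Bm)
  bot <- cbind(Bm %*% Stm, Bm %*% Stm %*% Bm + diag(pr$Sh, K))
  Snu <- rbind(top, bot)
  out <- matrix(0, 2 * K + d$Kx + d$Ky, 2 * K + d$Kx + d$Ky)
  out[1:(2 * K), 1:(2 * K)] <- Snu
  out[2 * K + seq_len(d$Kx), 2 * K + seq_len(d$Kx)] <- diag(pr$Sto, d$Kx)
  out[2 * K + d$Kx + seq_len(d$Ky), 2 * K + d$Kx + seq_len(d$Ky)] <-
    diag(pr$Suo, d$Ky)
  out
}

# Brute-force Gaussian conditioning of zeta on the observed vector, through
# a dense solve of the full joint covariance.
oracle_conditioning <- function(pr, S, with_z = TRUE) {
  L <- oracle_lambda(pr)
  if (!with_z) L <- L[-nrow(L), , drop = FALSE]
  Sz <- oracle_sigma_zeta(pr)
  d <- pr$dims
  Dvec <- c(rep(pr$sig_e2, d$p), rep(pr$sig_f2, d$q),
            if (with_z) pr$sig_g2)
  Sobs <- L %*% Sz %*% t(L) + diag(Dvec)
  Czs <- Sz %*% t(L)
  mean <- t(Czs %*% solve(Sobs, t(S)))
  cov <- Sz - Czs %*% solve(Sobs, t(Czs))
  list(mean = mean, cov = (cov + t(cov)) / 2, Sobs = Sobs)
}

# Dense multivariate-normal log-density of centered rows of S.
oracle_mvn_loglik <- function(S, Sigma) {
  ch <- chol(Sigma)
  quad <- colSums(forwardsolve(t(ch), t(S))^2)
  -0.5 * sum(ncol(S) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

# Dense trapezoid integration over nu = (t, u) for the K = 1 binary model:
# per-subject marginal density of (x, y, z).
oracle_binary_marginal <- function(pr, x, y, z, lim = 8, ngrid = 201) {
  stopifnot(pr$dims$K == 1)
  Snu <- oracle_sigma_zeta(pr)[1:2, 1:2]
  sdt <- sqrt(Snu[1, 1]); sdu <- sqrt(Snu[2, 2])
  tg <- seq(-lim * sdt, lim * sdt, length.out = ngrid)
  ug <- seq(-lim * sdu, lim * sdu, length.out = ngrid)
  gr <- as.matrix(expand.grid(t = tg, u = ug))
  fnu <- exp(-0.5 * rowSums((gr %*% solve(Snu)) * gr)) /
    (2 * pi * sqrt(det(Snu)))
  Sxt <- pr$Wo %*% diag(pr$Sto, 1) %*% t(pr$Wo) + pr$sig_e2 * diag(pr$dims$p)
  Syu <- pr$Co %*% diag(pr$Suo, 1) %*% t(pr$Co) + pr$sig_f2 * diag(pr$dims$q)
  Pxi <- solve(Sxt); Pyi <- solve(Syu)
  cx <- 1 / sqrt((2 * pi)^pr$dims$p * det(Sxt))
  cy <- 1 / sqrt((2 * pi)^pr$dims$q * det(Syu))
  dt <- tg[2] - tg[1]; du <- ug[2] - ug[1]
  n <- nrow(x)
  out <- list(f = numeric(n), Et = numeric(n), Eu = numeric(n),
              Ett = numeric(n), Euu = numeric(n), Etu = numeric(n))
  for (i in seq_len(n)) {
    lp <- pr$a0 + gr[, 1] * (pr$a - pr$B * pr$b) + gr[, 2] * pr$b
    pz <- if (z[i] == 1) plogis(lp) else plogis(-lp)
    rx <- sweep(outer(gr[, 1], drop(pr$W)), 2, x[i, ], `-`)
    fx <- cx * exp(-0.5 * rowSums((rx %*% Pxi) * rx))
    ry <- sweep(outer(gr[, 2], drop(pr$C)), 2, y[i, ], `-`)
    fy <- cy * exp(-0.5 * rowSums((ry %*% Pyi) * ry))
    w <- pz * fx * fy * fnu * dt * du
    f <- sum(w)
    out$f[i] <- f
    out$Et[i] <- sum(w * gr[, 1]) / f
    out$Eu[i] <- sum(w * gr[, 2]) / f
    out$Ett[i] <- sum(w * gr[, 1]^2) / f
    out$Euu[i] <- sum(w * gr[, 2]^2) / f
    out$Etu[i] <- sum(w * gr[, 1] * gr[, 2]) / f
  }
  out
}

# Population-level (infinite-N) sufficient statistics at given parameters,
# scaled to N pseudo-subjects, assembled densely.
population_moments <- function(pr, N = 1e6) {
  cond <- oracle_conditioning(pr, matrix(0, 1, pr$dims$p + pr$dims$q + 1))
  Sobs <- cond$Sobs
  L <- oracle_lambda(pr); Sz <- oracle_sigma_zeta(pr)
  d <- pr$dims
  P <- solve(Sobs, L %*% Sz)          # (p+q+1) x dlat, posterior-mean map'
  M <- N * (cond$cov + t(P) %*% Sobs %*% P)
  SxyzP <- Sobs %*% P                  # rows: cov(obs_j, posterior mean)
  ix <- seq_len(d$p); iy <- d$p + seq_len(d$q); iz <- d$p + d$q + 1
  structure(list(mean = NULL, cov = cond$cov, M = M,
                 Sx = N * SxyzP[ix, , drop = FALSE],
                 Sy = N * SxyzP[iy, , drop = FALSE],
                 Sz = N * SxyzP[iz, ],
                 Sxx = N * sum(diag(Sobs)[ix]),
                 Syy = N * sum(diag(Sobs)[iy]),
                 Szz = N * Sobs[iz, iz],
                 N = N, B_used = pr$B, dims = d),
            class = "latent_moments")
}
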