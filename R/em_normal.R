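# --- low-rank Gaussian machinery -------------------------------------------
#
# The observed vector s = (x, y[, z]) is a linear map of the latent vector
# zeta = (t, u, t_o, u_o) plus independent diagonal noise:
#   s = Lambda zeta + eps,  eps ~ N(0, diag(Dvec)),  zeta ~ N(0, Sigma_zeta).
# Posterior: Cov(zeta | s) = (Sigma_zeta^-1 + Lambda' D^-1 Lambda)^-1 =: G
# (shared by all subjects), E[zeta | s] = G Lambda' D^-1 s. Determinant and
# quadratic form of Sigma_s = Lambda Sigma_zeta Lambda' + D come from the
# matrix determinant lemma / Woodbury, so no (p+q) x (p+q) solve is formed.
.gauss_posterior <- function(L, Sz, Dvec, S) {
  M <- crossprod(L, L / Dvec)
  P <- solve(Sz)
  H <- (P + M + t(P + M)) / 2
  ch <- tryCatch(chol(H), error = function(e)
    stop("conditioning block is not positive definite"))
  G <- chol2inv(ch)
  A <- S %*% (L / Dvec)
  Em <- A %*% G
  logdet <- sum(log(Dvec)) + as.numeric(determinant(Sz)$modulus) +
    2 * sum(log(diag(ch)))
  quad <- rowSums(sweep(S, 2, Dvec, `/`) * S) - rowSums(A * Em)
  list(Em = Em, G = G, quad = quad, logdet = logdet)
}

# Latent index helpers for zeta = (t, u, t_o, u_o)
.zidx <- function(d) {
  it <- seq_len(d$K)
  list(t = it, u = d$K + it, to = 2L * d$K + seq_len(d$Kx),
       uo = 2L * d$K + d$Kx + seq_len(d$Ky))
}

#' Observed-data log-likelihood, gaussian outcome
#'
#' Sum over subjects of the zero-mean multivariate normal log-density of
#' (x, y, z) with the model-implied covariance, evaluated through a low-rank
#' factorization whose cost is linear in p + q (the dense covariance is
#' never inverted).
#'
#' @param params Valid gaussian-family \code{po2pls_params}.
#' @param x,y Column-centered data matrices (N x p, N x q).
#' @param z Centered outcome vector.
#' @return Scalar log-likelihood.
#' @export
loglik_normal <- function(params, x, y, z) {
  d <- params$dims
  S <- cbind(x, y, z)
  L <- .lambda_zeta(params, with_z = TRUE)
  Dvec <- c(rep(params$sig_e2, d$p), rep(params$sig_f2, d$q), params$sig_g2)
  po <- .gauss_posterior(L, .sigma_zeta(params), Dvec, S)
  n <- nrow(S)
  -0.5 * (n * ((d$p + d$q + 1) * log(2 * pi) + po$logdet) + sum(po$quad))
}

#' E-step for the gaussian-outcome model
#'
#' Exact Gaussian conditional first and second moments of the latent vector
#' (t, u, t-specific, u-specific) given (x, y, z), plus the aggregated
#' sufficient statistics used by all M-step blocks. The conditional
#' covariance is identical across subjects and stored once.
#'
#' @inheritParams loglik_normal
#' @return Object of class \code{"latent_moments"}: per-subject means
#'   (\code{mean}), shared conditional covariance (\code{cov}), aggregated
#'   second moment \code{M = sum E[zeta zeta']}, data cross-products and
#'   scalar sums.
#' @export
e_step_normal <- function(params, x, y, z) {
  d <- params$dims
  S <- cbind(x, y, z)
  L <- .lambda_zeta(params, with_z = TRUE)
  Dvec <- c(rep(params$sig_e2, d$p), rep(params$sig_f2, d$q), params$sig_g2)
  po <- .gauss_posterior(L, .sigma_zeta(params), Dvec, S)
  .collect_moments(po$Em, po$G, x, y, z, params)
}

# Assemble aggregated sufficient statistics from per-subject posterior means
# and the shared posterior covariance.
.collect_moments <- function(Em, G, x, y, z, params) {
  n <- nrow(Em)
  M <- crossprod(Em) + n * G
  structure(list(mean = Em, cov = G, M = M,
                 Sx = crossprod(x, Em), Sy = crossprod(y, Em),
                 Sz = if (is.null(z)) NULL else drop(crossprod(z, Em)),
                 Sxx = sum(x * x), Syy = sum(y * y),
                 Szz = if (is.null(z)) NULL else sum(z * z),
                 N = n, B_used = params$B, dims = params$dims),
            class = "latent_moments")
}

# Second moments of (t, h) with h = u - t B at the B used in the E-step.
.th_moments <- function(mom) {
  d <- mom$dims; ix <- .zidx(d); B <- mom$B_used
  Mtt <- mom$M[ix$t, ix$t, drop = FALSE]
  Mtu <- mom$M[ix$t, ix$u, drop = FALSE]
  Muu <- mom$M[ix$u, ix$u, drop = FALSE]
  Mth <- Mtu - Mtt %*% diag(B, d$K)
  Mhh <- Muu - diag(B, d$K) %*% Mtu - t(Mtu) %*% diag(B, d$K) +
    diag(B, d$K) %*% Mtt %*% diag(B, d$K)
  Szt <- mom$Sz[ix$t]
  Szu <- mom$Sz[ix$u]
  Szh <- Szu - B * Szt
  Mthth <- rbind(cbind(Mtt, Mth), cbind(t(Mth), Mhh))
  Mthth <- (Mthth + t(Mthth)) / 2
  list(Mthth = Mthth, Szth = c(Szt, Szh))
}

#' M-step for the outcome block (gaussian)
#'
#' Closed-form update of the outcome coefficients,
#' \code{(a, b) = z' E[(t,h)] (E[(t,h)'(t,h)])^-1}, followed by the residual
#' variance update for \code{sig_g2} given those coefficients.
#'
#' @param moments \code{latent_moments} from \code{\link{e_step_normal}}.
#' @param z Centered outcome vector.
#' @return List with \code{a}, \code{b} (length-K vectors) and
#'   \code{sig_g2}.
#' @export
m_step_outcome_normal <- function(moments, z) {
  K <- moments$dims$K
  th <- .th_moments(moments)
  ab <- tryCatch(drop(solve(th$Mthth, th$Szth)),
                 error = function(e)
                   stop("E[(t,h)'(t,h)] is singular; consider fewer components"))
  sig_g2 <- (moments$Szz - 2 * sum(ab * th$Szth) +
               drop(crossprod(ab, th$Mthth %*% ab))) / moments$N
  list(a = ab[seq_len(K)], b = ab[K + seq_len(K)],
       sig_g2 = max(sig_g2, 1e-12))
}

# Exact maximizer of tr(W'A) over semi-orthogonal W (orthogonal Procrustes);
# the quadratic term tr(W'W Msec) is constant on the Stiefel manifold.
.procrustes <- function(A) {
  sv <- svd(A)
  tcrossprod(sv$u, sv$v)
}

#' M-step for the PO2PLS block
#'
#' Updates all non-outcome parameters as exact blockwise maximizers of the
#' factorized Gaussian Q terms: alternating orthogonal-Procrustes updates
#' for each semi-orthogonal loading block, closed-form residual variances,
#' diagonal latent variances from conditional second moments, and the inner
#' relation \code{B} (for a gaussian outcome the \code{B} update also
#' accounts for the outcome term, which involves \code{B} through
#' \code{h = u - t B}).
#'
#' @param moments \code{latent_moments}.
#' @param x,y Centered data matrices.
#' @param params Current parameter set (provides previous loadings as the
#'   starting point and the outcome coefficients for the B update).
#' @param z Centered outcome (gaussian family; \code{NULL} to update B from
#'   the latent relation only).
#' @return Updated \code{po2pls_params}.
#' @export
m_step_po2pls_block <- function(moments, x, y, params, z = NULL) {
  d <- params$dims; ix <- .zidx(d); n <- moments$N
  M <- moments$M
  Mtt <- M[ix$t, ix$t, drop = FALSE]
  Muu <- M[ix$u, ix$u, drop = FALSE]
  Mtu <- M[ix$t, ix$u, drop = FALSE]
  Mtto <- M[ix$t, ix$to, drop = FALSE]
  Muuo <- M[ix$u, ix$uo, drop = FALSE]
  Mtoto <- M[ix$to, ix$to, drop = FALSE]
  Muouo <- M[ix$uo, ix$uo, drop = FALSE]
  Sxt <- moments$Sx[, ix$t, drop = FALSE]
  Sxto <- moments$Sx[, ix$to, drop = FALSE]
  Syu <- moments$Sy[, ix$u, drop = FALSE]
  Syuo <- moments$Sy[, ix$uo, drop = FALSE]

  W <- params$W; Wo <- params$Wo
  for (i in 1:2) {
    W <- .procrustes(Sxt - Wo %*% t(Mtto))
    Wo <- .procrustes(Sxto - W %*% Mtto)
  }
  C <- params$C; Co <- params$Co
  for (i in 1:2) {
    C <- .procrustes(Syu - Co %*% t(Muuo))
    Co <- .procrustes(Syuo - C %*% Muuo)
  }

  fit2 <- function(Sdd, S1, S2, L1, L2, M11, M12, M22) {
    # E sum ||data - L1 lat1 - L2 lat2||^2 under the posterior
    Sdd - 2 * sum(L1 * S1) - 2 * sum(L2 * S2) +
      sum(crossprod(L1, L1) * M11) + 2 * sum(crossprod(L1, L2) * t(M12)) +
      sum(crossprod(L2, L2) * M22)
  }
  sig_e2 <- fit2(moments$Sxx, Sxt, Sxto, W, Wo, Mtt, Mtto, Mtoto) / (n * d$p)
  sig_f2 <- fit2(moments$Syy, Syu, Syuo, C, Co, Muu, Muuo, Muouo) / (n * d$q)

  St <- pmax(diag(Mtt) / n, 1e-12)
  Sto <- pmax(diag(Mtoto) / n, 1e-12)
  Suo <- pmax(diag(Muouo) / n, 1e-12)

  # B: coordinate maximizer over the diagonal, from the u|t term and (for a
  # gaussian outcome) the outcome term z = t a' + (u - t B) b' + g.
  Sh_old <- params$Sh
  Amat <- diag(diag(Mtt) / Sh_old, d$K)
  rhs <- diag(as.matrix(Mtu)) / Sh_old
  if (!is.null(z) && params$family == "gaussian") {
    a <- params$a; b <- params$b; sg <- params$sig_g2
    Szt <- moments$Sz[ix$t]
    Amat <- Amat + (b %o% b) * t(Mtt) / sg
    rhs <- rhs - b / sg * (Szt - drop(Mtt %*% a) - drop(t(Mtu) %*% b))
  }
  B <- drop(solve(Amat, rhs))
  if (any(B <= 0)) B <- pmax(B, 1e-8)
  Bd <- diag(B, d$K)
  Sh <- pmax(diag(Muu - Bd %*% Mtu - t(Mtu) %*% Bd + Bd %*% Mtt %*% Bd) / n,
             1e-12)

  po2pls_params(W = W, C = C, Wo = Wo, Co = Co, B = B, St = St, Sto = Sto,
                Suo = Suo, Sh = Sh,
                sig_e2 = max(sig_e2, 1e-12), sig_f2 = max(sig_f2, 1e-12),
                a = params$a, b = params$b, a0 = params$a0,
                sig_g2 = params$sig_g2, family = params$family)
}

# --- initialization ---------------------------------------------------------

# Top-k right singular directions of E (N x p) by blocked power iteration on
# E'E, never forming the p x p matrix. Deterministic start.
.top_dirs <- function(E, k, iters = 30L) {
  p <- ncol(E)
  X <- crossprod(E, E[, seq_len(k), drop = FALSE])
  if (max(abs(X)) < 1e-300) X <- diag(p)[, seq_len(k), drop = FALSE]
  Q <- qr.Q(qr(X))
  for (i in seq_len(iters)) Q <- qr.Q(qr(crossprod(E, E %*% Q)))
  Q
}

# Method-of-moments starting values shared by both EM variants.
.init_params <- function(x, y, z, dims, family) {
  d <- dims; n <- nrow(x)
  sv <- svd(crossprod(x, y) / n, nu = d$K, nv = d$K)
  W <- sv$u; C <- sv$v
  Tsc <- x %*% W; Usc <- y %*% C
  B <- diag(crossprod(Tsc, Usc)) / pmax(diag(crossprod(Tsc)), 1e-12)
  flip <- ifelse(B < 0, -1, 1)
  C <- sweep(C, 2, flip, `*`); Usc <- sweep(Usc, 2, flip, `*`)
  B <- pmax(abs(B), 1e-4)
  Ex <- x - tcrossprod(Tsc, W)
  Ey <- y - tcrossprod(Usc, C)
  Wo <- .top_dirs(Ex, d$Kx)
  Co <- .top_dirs(Ey, d$Ky)
  Tso <- Ex %*% Wo; Uso <- Ey %*% Co
  sig_e2 <- max(mean((Ex - tcrossprod(Tso, Wo))^2), 1e-8)
  sig_f2 <- max(mean((Ey - tcrossprod(Uso, Co))^2), 1e-8)
  St <- pmax(colMeans(Tsc^2) - sig_e2, 0.1 * colMeans(Tsc^2))
  Sto <- pmax(colMeans(Tso^2) - sig_e2, 0.1 * colMeans(Tso^2))
  Suo <- pmax(colMeans(Uso^2) - sig_f2, 0.1 * colMeans(Uso^2))
  Hsc <- Usc - sweep(Tsc, 2, B, `*`)
  Sh <- pmax(colMeans(Hsc^2) - sig_f2, 0.1 * colMeans(Hsc^2))
  D <- cbind(Tsc, Hsc)
  if (family == "gaussian") {
    cf <- stats::lm.fit(D, z)$coefficients
    cf[is.na(cf)] <- 0
    res <- z - D %*% cf
    po2pls_params(W, C, Wo, Co, B, St, Sto, Suo, Sh, sig_e2, sig_f2,
                  a = cf[seq_len(d$K)], b = cf[d$K + seq_len(d$K)],
                  sig_g2 = max(mean(res^2), 1e-8), family = "gaussian")
  } else {
    cf <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, D), z,
                                      family = stats::binomial())$coefficients),
      error = function(e) rep(0, 1 + 2 * d$K))
    cf[is.na(cf)] <- 0
    cf <- pmin(pmax(cf, -5), 5)  # guard against separation at init
    po2pls_params(W, C, Wo, Co, B, St, Sto, Suo, Sh, sig_e2, sig_f2,
                  a = cf[1 + seq_len(d$K)], b = cf[1 + d$K + seq_len(d$K)],
                  a0 = cf[1], family = "bernoulli")
  }
}

#' Fit the gaussian-outcome model by EM
#'
#' Alternates the exact conditional-moment E-step with the closed-form
#' M-step blocks until the relative change of the observed-data
#' log-likelihood falls below \code{tol}. Data are column-centered
#' internally; the fitted loadings are sign-canonicalized on exit.
#'
#' @param x,y Data matrices (N x p, N x q).
#' @param z Outcome vector.
#' @param dims A \code{po2pls_dims} object (or list with K, Kx, Ky).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param init Optional \code{po2pls_params} starting value.
#' @return List of class \code{"po2pls_fit"}: \code{params},
#'   \code{loglik_trace}, \code{n_iter}, \code{converged}, \code{tol_used},
#'   \code{moments} (final E-step at the fitted parameters).
#' @export
fit_normal <- function(x, y, z, dims, tol = 1e-6, max_iter = 10000L,
                       init = NULL) {
  d <- if (inherits(dims, "po2pls_dims")) dims else
    po2pls_dims(ncol(x), ncol(y), dims$K, dims$Kx, dims$Ky, nrow(x))
  if (nrow(x) <= d$K + d$Kx + d$Ky)
    stop("sample size must exceed the total number of components")
  params <- if (is.null(init)) .init_params(x, y, z, d, "gaussian") else init
  trace <- loglik_normal(params, x, y, z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mom <- e_step_normal(params, x, y, z)
    out <- m_step_outcome_normal(mom, z)
    params$a <- out$a; params$b <- out$b; params$sig_g2 <- out$sig_g2
    params <- m_step_po2pls_block(mom, x, y, params, z)
    ll <- loglik_normal(params, x, y, z)
    trace <- c(trace, ll)
    if (!is.finite(ll)) break
    prev <- trace[length(trace) - 1L]
    if (abs(ll - prev) < tol * (abs(prev) + 1e-3)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  params <- canonicalize_signs(params)
  structure(list(params = params, loglik_trace = trace,
                 n_iter = length(trace) - 1L, converged = converged,
                 tol_used = tol,
                 moments = e_step_normal(params, x, y, z)),
            class = "po2pls_fit")
}
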