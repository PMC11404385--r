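# --- Gauss-Hermite machinery ------------------------------------------------

#' Tensor-product Gauss-Hermite grid for the joint components
#'
#' Builds the 2K-dimensional tensor-product quadrature grid used to
#' integrate over nu = (t, u) under its N(0, Sigma_nu) law. Standard
#' M-point Hermite nodes nu* are mapped through nu = sqrt(2) nu* R with
#' R the Cholesky factor of Sigma_nu, and the product weights are
#' normalized by pi^(-d/2) so that the constant function integrates to 1.
#'
#' @param M Nodes per dimension (>= 2).
#' @param Sigma_nu 2K x 2K covariance of (t, u).
#' @return List of class \code{"gh_grid"}: \code{nodes} (M^d x d matrix,
#'   one node per row), \code{weights} (length M^d), \code{M}, \code{d}.
#' @export
gauss_hermite_grid <- function(M, Sigma_nu) {
  if (M < 2) stop("M must be at least 2")
  Sigma_nu <- as.matrix(Sigma_nu)
  d <- nrow(Sigma_nu)
  R <- tryCatch(chol(Sigma_nu),
                error = function(e) stop("Sigma_nu is not positive definite"))
  gh <- pracma::gaussHermite(M)
  idx <- do.call(expand.grid, rep(list(seq_len(M)), d))
  nustar <- as.matrix(idx)
  nodes <- sqrt(2) * (matrix(gh$x[nustar], ncol = d) %*% R)
  weights <- apply(matrix(gh$w[nustar], ncol = d), 1, prod) / pi^(d / 2)
  structure(list(nodes = nodes, weights = weights, M = as.integer(M),
                 d = as.integer(d)), class = "gh_grid")
}

#' Conditional outcome probability given the joint components
#'
#' Logistic probability mass of a binary outcome given nu = (t, u), with
#' linear predictor \code{a0 + t a' + (u - t B) b'}. Numerically stable for
#' extreme predictors.
#'
#' @param z Outcome value(s), 0 or 1 (recycled against rows of \code{nu}).
#' @param nu Matrix of nu values, one row per point (2K columns).
#' @param beta Coefficient vector \code{(a0, a, b)}.
#' @param B Diagonal of the inner relation (length K).
#' @return Vector of probabilities \code{p(z | nu)}.
#' @export
bernoulli_conditional <- function(z, nu, beta, B) {
  nu <- if (is.matrix(nu)) nu else matrix(nu, nrow = 1)
  K <- ncol(nu) / 2
  a0 <- beta[1]; a <- beta[1 + seq_len(K)]; b <- beta[1 + K + seq_len(K)]
  lp <- drop(a0 + nu[, seq_len(K), drop = FALSE] %*% (a - B * b) +
               nu[, K + seq_len(K), drop = FALSE] %*% b)
  ifelse(rep_len(z, length(lp)) == 1, stats::plogis(lp), stats::plogis(-lp))
}

# log N(data | loading %*% lat, low-rank-plus-diagonal cov) for every
# (subject, node) pair: returns the N x nnode matrix of log-densities of one
# omics block given its joint latent scores at the nodes.
.logdens_block <- function(data, W, Wo, Svo, sig2, lat) {
  n <- nrow(data); p <- ncol(data); Ko <- ncol(Wo)
  WotWo <- crossprod(Wo)
  Gi <- solve(diag(1 / Svo, Ko) + WotWo / sig2)
  logdet <- p * log(sig2) +
    as.numeric(determinant(diag(Ko) + (Svo * WotWo) / sig2)$modulus)
  XWo <- data %*% Wo
  XW <- data %*% W
  qx <- rowSums(data^2) / sig2 - rowSums((XWo %*% Gi) * XWo) / sig2^2
  WPW <- crossprod(W) / sig2 - crossprod(W, Wo) %*% Gi %*% crossprod(Wo, W) / sig2^2
  Qxt <- XW / sig2 - XWo %*% Gi %*% crossprod(Wo, W) / sig2^2
  nodequad <- rowSums((lat %*% WPW) * lat)
  quad <- outer(qx, nodequad, `+`) - 2 * tcrossprod(Qxt, lat)
  -0.5 * (p * log(2 * pi) + logdet + quad)
}

# Shared core of the binary-outcome likelihood/E-step: per-subject marginal
# log-likelihood and the posterior node weights omega (N x nnode, rows sum
# to 1) at the current parameters.
.binary_core <- function(params, x, y, z, grid) {
  d <- params$dims; K <- d$K
  Tn <- grid$nodes[, seq_len(K), drop = FALSE]
  Un <- grid$nodes[, K + seq_len(K), drop = FALSE]
  lfx <- .logdens_block(x, params$W, params$Wo, params$Sto, params$sig_e2, Tn)
  lfy <- .logdens_block(y, params$C, params$Co, params$Suo, params$sig_f2, Un)
  beta <- c(params$a0, params$a, params$b)
  lp <- drop(params$a0 + Tn %*% (params$a - params$B * params$b) +
               Un %*% params$b)
  lp1 <- stats::plogis(lp, log.p = TRUE)
  lp0 <- stats::plogis(-lp, log.p = TRUE)
  logpz <- matrix(0, nrow(x), length(lp))
  logpz[z == 1, ] <- matrix(lp1, sum(z == 1), length(lp), byrow = TRUE)
  logpz[z == 0, ] <- matrix(lp0, sum(z == 0), length(lp), byrow = TRUE)
  logint <- sweep(lfx + lfy + logpz, 2, log(grid$weights), `+`)
  mx <- apply(logint, 1, max)
  ll_i <- mx + log(rowSums(exp(logint - mx)))
  omega <- exp(logint - ll_i)
  list(ll = sum(ll_i), ll_i = ll_i, omega = omega, Tn = Tn, Un = Un, lp = lp)
}

#' Observed-data log-likelihood, bernoulli outcome
#'
#' Marginal likelihood with the specific components integrated out
#' analytically and the 2K-dimensional integral over nu = (t, u) evaluated
#' by Gauss-Hermite quadrature; all products are accumulated in log space.
#'
#' @param params Valid bernoulli-family \code{po2pls_params}.
#' @param x,y Column-centered data matrices.
#' @param z 0/1 outcome vector.
#' @param grid Optional \code{gh_grid}; built from the model's Sigma_nu with
#'   \code{M} nodes per dimension when missing.
#' @param M Nodes per dimension for the default grid.
#' @return Scalar log-likelihood.
#' @export
loglik_binary <- function(params, x, y, z, grid = NULL, M = 16L) {
  if (is.null(grid))
    grid <- gauss_hermite_grid(M, build_joint_covariance(params)$Sigma_nu)
  .binary_core(params, x, y, z, grid)$ll
}

#' E-step for the bernoulli-outcome model
#'
#' Quadrature posterior moments of nu = (t, u) given (x, y, z), extended to
#' the specific components through exact Gaussian conditioning of
#' (t-specific, u-specific) given nu and the data, and aggregated into the
#' same sufficient-statistic container the gaussian M-step blocks consume.
#'
#' @inheritParams loglik_binary
#' @return A \code{latent_moments} object; additionally carries the
#'   per-subject marginal log-likelihood (\code{ll_i}), its sum
#'   (\code{ll}), and the posterior node weights (\code{omega}).
#' @export
e_step_binary <- function(params, x, y, z, grid = NULL, M = 16L) {
  if (is.null(grid))
    grid <- gauss_hermite_grid(M, build_joint_covariance(params)$Sigma_nu)
  d <- params$dims; n <- nrow(x); K <- d$K
  co <- .binary_core(params, x, y, z, grid)
  om <- co$omega
  Et <- om %*% co$Tn
  Eu <- om %*% co$Un
  wtot <- colSums(om)
  Mnn <- crossprod(grid$nodes, wtot * grid$nodes)  # sum_i E[nu' nu | i]
  Mtt <- Mnn[seq_len(K), seq_len(K), drop = FALSE]
  Mtu <- Mnn[seq_len(K), K + seq_len(K), drop = FALSE]
  Muu <- Mnn[K + seq_len(K), K + seq_len(K), drop = FALSE]

  # specific blocks: xi | nu, data is Gaussian; its mean is linear in the
  # data and the nu posterior mean
  spec <- function(data, W, Wo, Svo, sig2, Ej, Mjj) {
    Ko <- ncol(Wo)
    Gi <- solve(diag(1 / Svo, Ko) + crossprod(Wo) / sig2)
    XWo <- data %*% Wo
    WotW <- crossprod(Wo, W)
    A1 <- -Gi %*% WotW / sig2
    a0s <- XWo %*% Gi / sig2            # N x Ko, per-subject constant term
    Eo <- a0s + Ej %*% t(A1)
    Moo <- n * Gi + crossprod(a0s) + crossprod(a0s, Ej) %*% t(A1) +
      A1 %*% crossprod(Ej, a0s) + A1 %*% Mjj %*% t(A1)
    list(Eo = Eo, Moo = (Moo + t(Moo)) / 2, a0s = a0s, A1 = A1)
  }
  sx <- spec(x, params$W, params$Wo, params$Sto, params$sig_e2, Et, Mtt)
  sy <- spec(y, params$C, params$Co, params$Suo, params$sig_f2, Eu, Muu)

  cross_j_o <- function(Ej, Mjj_with, s) crossprod(Ej, s$a0s) + Mjj_with %*% t(s$A1)
  Mt_to <- cross_j_o(Et, Mtt, sx)             # sum E[t t_o']
  Mu_to <- cross_j_o(Eu, t(Mtu), sx)          # sum E[u t_o']
  Mt_uo <- cross_j_o(Et, Mtu, sy)             # sum E[t u_o']
  Mu_uo <- cross_j_o(Eu, Muu, sy)             # sum E[u u_o']
  # t_o and u_o are conditionally independent given (nu, data)
  Mto_uo <- crossprod(sx$a0s, sy$a0s) + crossprod(sx$a0s, Eu) %*% t(sy$A1) +
    sx$A1 %*% crossprod(Et, sy$a0s) + sx$A1 %*% Mtu %*% t(sy$A1)

  dm <- 2L * K + d$Kx + d$Ky
  Mfull <- matrix(0, dm, dm)
  ix <- .zidx(d)
  Mfull[ix$t, ix$t] <- Mtt; Mfull[ix$t, ix$u] <- Mtu
  Mfull[ix$u, ix$t] <- t(Mtu); Mfull[ix$u, ix$u] <- Muu
  Mfull[ix$t, ix$to] <- Mt_to; Mfull[ix$to, ix$t] <- t(Mt_to)
  Mfull[ix$u, ix$to] <- Mu_to; Mfull[ix$to, ix$u] <- t(Mu_to)
  Mfull[ix$t, ix$uo] <- Mt_uo; Mfull[ix$uo, ix$t] <- t(Mt_uo)
  Mfull[ix$u, ix$uo] <- Mu_uo; Mfull[ix$uo, ix$u] <- t(Mu_uo)
  Mfull[ix$to, ix$to] <- sx$Moo; Mfull[ix$uo, ix$uo] <- sy$Moo
  Mfull[ix$to, ix$uo] <- Mto_uo; Mfull[ix$uo, ix$to] <- t(Mto_uo)

  Em <- cbind(Et, Eu, sx$Eo, sy$Eo)
  mom <- structure(list(mean = Em, cov = NULL, M = Mfull,
                        Sx = crossprod(x, Em), Sy = crossprod(y, Em),
                        Sz = drop(crossprod(z, Em)),
                        Sxx = sum(x * x), Syy = sum(y * y), Szz = sum(z * z),
                        N = n, B_used = params$B, dims = d),
                   class = "latent_moments")
  mom$ll <- co$ll; mom$ll_i <- co$ll_i; mom$omega <- co$omega
  mom$grid <- grid
  mom
}

# Q_beta and its gradient from fixed posterior node weights. h = u - t B is
# taken at the B of the E-step parameters.
.Qbeta_parts <- function(omega, z, Tn, Un, B) {
  K <- ncol(Tn)
  Dm <- cbind(1, Tn, Un - sweep(Tn, 2, B, `*`))
  w1 <- colSums(omega[z == 1, , drop = FALSE])
  w0 <- colSums(omega[z == 0, , drop = FALSE])
  list(Dm = Dm, w1 = w1, w0 = w0)
}

.Qbeta_value <- function(parts, beta) {
  lp <- drop(parts$Dm %*% beta)
  sum(parts$w1 * stats::plogis(lp, log.p = TRUE)) +
    sum(parts$w0 * stats::plogis(-lp, log.p = TRUE))
}

.Qbeta_grad <- function(parts, beta) {
  lp <- drop(parts$Dm %*% beta)
  s <- stats::plogis(lp)
  drop(crossprod(parts$Dm, parts$w1 * (1 - s) - parts$w0 * s))
}

#' Gradient of the outcome Q-term (bernoulli)
#'
#' Quadrature evaluation of the gradient of \code{Q_beta} with respect to
#' \code{beta = (a0, a, b)}: the logistic score times the design vector
#' \code{(1, t, u - t B)}, averaged over the posterior of nu.
#'
#' @inheritParams loglik_binary
#' @param beta Coefficient vector \code{(a0, a, b)} at which to evaluate.
#' @param grid A \code{gh_grid} (built from the model when missing).
#' @return Gradient vector of length 1 + 2K.
#' @export
grad_Q_beta <- function(params, x, y, z, grid = NULL, beta = NULL, M = 16L) {
  if (is.null(grid))
    grid <- gauss_hermite_grid(M, build_joint_covariance(params)$Sigma_nu)
  if (is.null(beta)) beta <- c(params$a0, params$a, params$b)
  co <- .binary_core(params, x, y, z, grid)
  parts <- .Qbeta_parts(co$omega, z, co$Tn, co$Un, params$B)
  .Qbeta_grad(parts, beta)
}

#' One backtracking (Armijo) gradient step
#'
#' Moves \code{beta} along the supplied gradient with the first step size in
#' \code{1, 0.8, 0.8^2, ...} satisfying the ascent condition
#' \code{Q(beta + s g) >= Q(beta) + 0.5 s g g'}. If the step underflows
#' below 1e-12 the update is skipped with a warning.
#'
#' @param beta Current coefficient vector.
#' @param grad Gradient at \code{beta}.
#' @param Qfun Function evaluating the objective at a coefficient vector.
#' @return List with the updated \code{beta}, accepted step \code{s} (0 if
#'   skipped) and \code{grad}.
#' @export
backtracking_update <- function(beta, grad, Qfun) {
  Q0 <- Qfun(beta)
  g2 <- sum(grad^2)
  if (g2 == 0) return(list(beta = beta, s = 1, grad = grad))
  s <- 1
  while (Qfun(beta + s * grad) < Q0 + 0.5 * s * g2) {
    s <- 0.8 * s
    if (s < 1e-12) {
      warning("backtracking step underflow; beta update skipped (flat region)")
      return(list(beta = beta, s = 0, grad = grad))
    }
  }
  list(beta = beta + s * grad, s = s, grad = grad)
}

#' Fit the bernoulli-outcome model by EM
#'
#' Alternates the quadrature E-step, a single backtracking gradient update
#' of \code{beta = (a0, a, b)}, and the closed-form updates of the remaining
#' blocks, until the relative change of the quadrature log-likelihood falls
#' below \code{tol}. This is a generalized EM: each iteration does not
#' decrease the observed-data log-likelihood (up to quadrature error).
#'
#' @param x,y Data matrices (column-centered internally).
#' @param z 0/1 outcome vector; must show both classes.
#' @param dims \code{po2pls_dims} (or list with K, Kx, Ky).
#' @param M Quadrature nodes per dimension (grid size M^(2K)).
#' @param tol Relative log-likelihood tolerance.
#' @param max_iter Iteration cap.
#' @param init Optional starting \code{po2pls_params}.
#' @return A \code{"po2pls_fit"} object (see \code{\link{fit_normal}}).
#' @export
fit_binary <- function(x, y, z, dims, M = 16L, tol = 1e-6, max_iter = 1000L,
                       init = NULL) {
  d <- if (inherits(dims, "po2pls_dims")) dims else
    po2pls_dims(ncol(x), ncol(y), dims$K, dims$Kx, dims$Ky, nrow(x))
  if (!all(z %in% c(0, 1))) stop("binary outcome must be coded 0/1")
  if (length(unique(z)) < 2L)
    stop("outcome shows no variation; the intercept diverges (separation)")
  npts <- as.numeric(M)^(2 * d$K)
  if (npts > 1e6)
    stop("quadrature grid of ", format(npts), " points exceeds the budget; ",
         "reduce K or M (the binary model is intended for small K)")
  if (npts > 2e4)
    warning("large quadrature grid (", format(npts), " points); ",
            "fitting will be slow")
  params <- if (is.null(init)) .init_params(x, y, z, d, "bernoulli") else init
  trace <- numeric(0)
  converged <- FALSE
  mom <- NULL
  for (it in seq_len(max_iter)) {
    grid <- gauss_hermite_grid(M, .sigma_zeta(params)[seq_len(2 * d$K),
                                                      seq_len(2 * d$K)])
    mom <- e_step_binary(params, x, y, z, grid)
    if (it == 1L) trace <- mom$ll
    co_parts <- .Qbeta_parts(mom$omega, z, grid$nodes[, seq_len(d$K), drop = FALSE],
                             grid$nodes[, d$K + seq_len(d$K), drop = FALSE],
                             params$B)
    beta <- c(params$a0, params$a, params$b)
    up <- backtracking_update(beta, .Qbeta_grad(co_parts, beta),
                              function(b) .Qbeta_value(co_parts, b))
    params$a0 <- up$beta[1]
    params$a <- up$beta[1 + seq_len(d$K)]
    params$b <- up$beta[1 + d$K + seq_len(d$K)]
    params <- m_step_po2pls_block(mom, x, y, params, z = NULL)
    ll <- loglik_binary(params, x, y, z, M = M)
    trace <- c(trace, ll)
    prev <- trace[length(trace) - 1L]
    if (abs(ll - prev) < tol * (abs(prev) + 1e-3)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  params <- canonicalize_signs(params)
  structure(list(params = params, loglik_trace = trace,
                 n_iter = length(trace) - 1L, converged = converged,
                 tol_used = tol, M = M,
                 moments = e_step_binary(params, x, y, z, M = M)),
            class = "po2pls_fit")
}
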