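# Posterior mean/covariance of (t, h) from a fit's final E-step. For the
# gaussian family the conditional covariance is shared across subjects.
.th_posterior <- function(fit) {
  mom <- fit$moments
  d <- mom$dims; K <- d$K
  B <- mom$B_used
  A <- rbind(cbind(diag(K), -diag(B, K)),
             cbind(matrix(0, K, K), diag(K)))
  m <- mom$mean[, seq_len(2 * K), drop = FALSE] %*% A
  V <- if (!is.null(mom$cov))
    crossprod(A, mom$cov[seq_len(2 * K), seq_len(2 * K)] %*% A)
  else NULL
  list(m = m, V = V, A = A)
}

#' Louis observed information for the outcome coefficients
#'
#' Assembles the alpha-block of the observed Fisher information from the
#' complete-data score and negative Hessian of the outcome term, evaluated
#' at the fitted parameters with conditional expectations from the E-step:
#' \code{I = sum E[B_i] - sum_i E[S_i S_i'] - sum_{i != j} E[S_i] E[S_j]'}.
#' This uses the approximation that \code{alpha = (a, b)} is asymptotically
#' independent of the remaining parameters and that the outcome residual
#' variance is treated as fixed. Its inverse estimates the covariance of
#' \code{alpha}-hat. For the bernoulli family the (a0, a, b) information is
#' computed by quadrature and the p-values carry a validity caveat, as the
#' asymptotic normality is assumed rather than derived.
#'
#' @param fit A converged \code{po2pls_fit}.
#' @param z The (centered, for gaussian) outcome used in the fit.
#' @return List of class \code{"alpha_information"}: \code{I_alpha},
#'   \code{Pi_alpha}, \code{alpha_hat}, \code{family}, \code{caveat}.
#' @export
alpha_information <- function(fit, z) {
  params <- fit$params
  K <- params$dims$K
  alpha <- c(params$a, params$b)
  if (params$family == "gaussian") {
    po <- .th_posterior(fit)
    m <- po$m; V <- po$V; sg <- params$sig_g2
    n <- nrow(m)
    rbar <- drop(z - m %*% alpha)
    aV <- drop(alpha %*% V)
    avA <- drop(alpha %*% V %*% alpha)
    mr <- m * rbar
    u1 <- colSums(mr)
    sumEB <- (crossprod(m) + n * V) / sg
    sumESS <- (crossprod(mr) + sum(rbar^2) * V -
                 2 * (outer(u1, aV) + outer(aV, u1)) +
                 avA * crossprod(m) + n * (avA * V + 2 * outer(aV, aV))) / sg^2
    ES <- (mr - matrix(aV, n, 2 * K, byrow = TRUE)) / sg
    sumES <- colSums(ES)
    cross <- outer(sumES, sumES) - crossprod(ES)
    I_alpha <- sumEB - sumESS - cross
    I_alpha <- (I_alpha + t(I_alpha)) / 2
    Pi <- tryCatch(solve(I_alpha), error = function(e)
      stop("information block is singular; consider a smaller K"))
    caveat <- FALSE
  } else {
    mom <- fit$moments
    om <- mom$omega; grid <- mom$grid
    Tn <- grid$nodes[, seq_len(K), drop = FALSE]
    Un <- grid$nodes[, K + seq_len(K), drop = FALSE]
    Dm <- cbind(1, Tn, Un - sweep(Tn, 2, params$B, `*`))
    lp <- drop(Dm %*% c(params$a0, alpha))
    s <- stats::plogis(lp)
    n <- nrow(om)
    Rim <- matrix(z, n, length(s)) - matrix(s, n, length(s), byrow = TRUE)
    sumEB <- crossprod(Dm, (colSums(om) * s * (1 - s)) * Dm)
    sumESS <- crossprod(Dm, colSums(om * Rim^2) * Dm)
    ES <- (om * Rim) %*% Dm
    sumES <- colSums(ES)
    cross <- outer(sumES, sumES) - crossprod(ES)
    I_beta <- sumEB - sumESS - cross
    I_beta <- (I_beta + t(I_beta)) / 2
    Pi_beta <- tryCatch(solve(I_beta), error = function(e)
      stop("information block is singular; consider a smaller K"))
    Pi <- Pi_beta[-1, -1, drop = FALSE]
    I_alpha <- I_beta[-1, -1, drop = FALSE]
    caveat <- TRUE
  }
  structure(list(I_alpha = I_alpha, Pi_alpha = Pi, alpha_hat = alpha,
                 family = params$family, caveat = caveat),
            class = "alpha_information")
}

#' Full chi-square test of the omics-outcome association
#'
#' Wald statistic \code{T = alpha Pi^-1 alpha'} for the null hypothesis that
#' all outcome coefficients vanish (\code{a = b = 0}), referred to a
#' chi-square distribution with 2r degrees of freedom (r = K).
#'
#' @param alpha_hat Estimated coefficient vector \code{(a, b)} (length 2K).
#' @param Pi_alpha Its estimated covariance matrix.
#' @return List with \code{statistic}, \code{df}, \code{p.value}.
#' @export
test_full <- function(alpha_hat, Pi_alpha) {
  ev <- eigen(Pi_alpha, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Pi_alpha must be positive definite")
  T <- drop(alpha_hat %*% solve(Pi_alpha, alpha_hat))
  df <- length(alpha_hat)
  list(statistic = T, df = df, p.value = stats::pchisq(T, df, lower.tail = FALSE))
}

#' Component-wise chi-square test
#'
#' Wald statistic for the null hypothesis \code{a_k = b_k = 0} of one pair
#' of joint components, built from the matching 2 x 2 sub-block of the
#' coefficient covariance; 2 degrees of freedom.
#'
#' @inheritParams test_full
#' @param k Component index in 1..K.
#' @return List with \code{statistic}, \code{df} (= 2), \code{p.value}.
#' @export
test_componentwise <- function(alpha_hat, Pi_alpha, k) {
  K <- length(alpha_hat) / 2
  if (k < 1 || k > K) stop("k must be in 1..K")
  ii <- c(k, K + k)
  ak <- alpha_hat[ii]
  Pk <- Pi_alpha[ii, ii, drop = FALSE]
  ev <- eigen(Pk, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("coefficient covariance sub-block is not positive definite")
  T <- drop(ak %*% solve(Pk, ak))
  list(statistic = T, df = 2L, p.value = stats::pchisq(T, 2, lower.tail = FALSE))
}

#' Association tests between the outcome and the joint components
#'
#' Convenience wrapper computing the Louis information, the full test and
#' all component-wise tests for a converged fit.
#'
#' @param fit A \code{po2pls_fit}.
#' @param z The outcome used in the fit (centered internally for the
#'   gaussian family when it was fit through \code{\link{glmpo2pls}}).
#' @return Object of class \code{"po2pls_test"}: \code{alpha_hat},
#'   \code{Pi_alpha}, \code{full} (statistic, df, p), \code{componentwise}
#'   (data frame), \code{caveat}.
#' @export
test_association <- function(fit, z) {
  info <- alpha_information(fit, z)
  full <- test_full(info$alpha_hat, info$Pi_alpha)
  K <- length(info$alpha_hat) / 2
  comp <- do.call(rbind, lapply(seq_len(K), function(k) {
    tk <- test_componentwise(info$alpha_hat, info$Pi_alpha, k)
    data.frame(component = k, statistic = tk$statistic, df = tk$df,
               p.value = tk$p.value)
  }))
  structure(list(alpha_hat = info$alpha_hat, Pi_alpha = info$Pi_alpha,
                 full = full, componentwise = comp, caveat = info$caveat),
            class = "po2pls_test")
}

#' @export
print.po2pls_test <- function(x, ...) {
  cat("Chi-square tests of the omics-outcome association\n")
  cat(sprintf("Full test: T = %.4g on %d df, p = %.4g\n",
              x$full$statistic, x$full$df, x$full$p.value))
  cat("Component-wise (df = 2):\n")
  print(x$componentwise, row.names = FALSE)
  if (isTRUE(x$caveat))
    cat("Note: binary-family p-values assume asymptotic normality of the\n",
        "estimator; this has not been established for the logistic link.\n")
  invisible(x)
}

#' Wald tests of the inner relation between joint components
#'
#' Tests \code{B_k = 0} for each pair (t_k, u_k): no linear relation between
#' the x-side and y-side joint components. Uses the same Louis
#' observed-information construction, applied to the complete-data term of
#' the latent regression \code{u = t B + h}; one degree of freedom per
#' component. The statistic is invariant to the allowed per-component sign
#' flips.
#'
#' @param fit A converged \code{po2pls_fit}.
#' @return Data frame with component, estimate, statistic, df, p.value.
#' @export
test_omics_association <- function(fit) {
  params <- fit$params
  mom <- fit$moments
  K <- params$dims$K
  out <- lapply(seq_len(K), function(k) {
    Bk <- params$B[k]; sh <- params$Sh[k]
    if (params$family == "gaussian") {
      mt <- mom$mean[, k]; mu <- mom$mean[, K + k]
      V <- mom$cov[c(k, K + k), c(k, K + k)]
      mw <- mu - Bk * mt
      Vtt <- V[1, 1]; Vuu <- V[2, 2]; Vtu <- V[1, 2]
      Vww <- Vuu - 2 * Bk * Vtu + Bk^2 * Vtt
      Vwt <- Vtu - Bk * Vtt
      Ett <- mt^2 + Vtt
      Ewt <- mw * mt + Vwt
      Ew2t2 <- mw^2 * mt^2 + mw^2 * Vtt + mt^2 * Vww +
        4 * mw * mt * Vwt + Vww * Vtt + 2 * Vwt^2
    } else {
      om <- mom$omega; grid <- mom$grid
      tn <- grid$nodes[, k]; un <- grid$nodes[, K + k]
      wn <- un - Bk * tn
      Ett <- drop(om %*% tn^2)
      Ewt <- drop(om %*% (wn * tn))
      Ew2t2 <- drop(om %*% (wn^2 * tn^2))
    }
    EB <- Ett / sh
    ES <- Ewt / sh
    ESS <- Ew2t2 / sh^2
    sES <- sum(ES)
    I_B <- sum(EB) - sum(ESS) - (sES^2 - sum(ES^2))
    stat <- Bk^2 * I_B
    data.frame(component = k, estimate = Bk, statistic = stat, df = 1L,
               p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
  })
  do.call(rbind, out)
}
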