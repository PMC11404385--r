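#' Fit a GLM-PO2PLS model
#'
#' One-stage joint model of two omics matrices and an outcome. The omics
#' blocks are decomposed into joint parts (paired latent components t and u
#' with inner relation \code{u = t B + h}), data-specific parts and residual
#' noise; the outcome is linked to the joint structure through the linear
#' predictor \code{a0 + t a' + h b'} with identity (gaussian) or logit
#' (bernoulli) link. Estimation is by maximum likelihood via EM.
#'
#' Columns of \code{x} and \code{y} are centered internally (and \code{z}
#' for the gaussian family); centering statistics are stored for prediction.
#' Scaling is left to the user.
#'
#' @param x,y Numeric sample-by-feature matrices with matching rows.
#' @param z Outcome vector: numeric (gaussian) or 0/1 (bernoulli).
#' @param K,Kx,Ky Numbers of joint, x-specific and y-specific components.
#' @param family Outcome family.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param M Gauss-Hermite nodes per dimension (bernoulli family).
#' @param keep_data Keep the centered data in the returned object (needed
#'   for \code{residuals} and \code{fitted}).
#' @return Object of class \code{"glmpo2pls"} with the fitted parameters,
#'   log-likelihood trace, convergence information, final E-step moments and
#'   centering statistics. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals}, \code{fitted},
#'   \code{plot}, \code{simulate}, \code{logLik}.
#' @examples
#' sc <- sim_scenario(N = 80, p = 20, q = 6, seed = 7)
#' dat <- simulate_dataset(sc)
#' fit <- glmpo2pls(dat$x, dat$y, dat$z, K = 1, Kx = 1, Ky = 1)
#' summary(fit)
#' @export
glmpo2pls <- function(x, y, z, K = 1L, Kx = 1L, Ky = 1L,
                      family = c("gaussian", "bernoulli"),
                      tol = 1e-6, max_iter = 10000L, M = 16L,
                      keep_data = TRUE) {
  family <- match.arg(family)
  x <- as.matrix(x); y <- as.matrix(y); z <- as.numeric(z)
  if (nrow(x) != nrow(y) || nrow(x) != length(z))
    stop("x, y and z must describe the same samples")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("missing values are not supported")
  dims <- po2pls_dims(ncol(x), ncol(y), K, Kx, Ky, nrow(x))
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  if (family == "gaussian") {
    cz <- mean(z)
    zc <- z - cz
    core <- fit_normal(xc, yc, zc, dims, tol = tol, max_iter = max_iter)
  } else {
    if (!all(z %in% c(0, 1)))
      stop("bernoulli outcome must be coded 0/1")
    cz <- 0
    zc <- z
    core <- fit_binary(xc, yc, zc, dims, M = M, tol = tol,
                       max_iter = max_iter)
  }
  structure(c(core,
              list(family = family, dims = dims,
                   centers = list(x = cx, y = cy, z = cz),
                   z = zc,
                   x = if (keep_data) xc else NULL,
                   y = if (keep_data) yc else NULL,
                   call = match.call())),
            class = c("glmpo2pls", "po2pls_fit"))
}

#' @export
print.glmpo2pls <- function(x, ...) {
  d <- x$dims
  cat(sprintf("GLM-PO2PLS fit (%s outcome)\n", x$family))
  cat(sprintf("  p = %d, q = %d; K = %d joint, Kx = %d, Ky = %d specific; N = %d\n",
              d$p, d$q, d$K, d$Kx, d$Ky, d$N))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              tail(x$loglik_trace, 1), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  coefficients:\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.glmpo2pls <- function(object, ...) {
  p <- object$params
  K <- object$dims$K
  cf <- c(if (object$family == "bernoulli") c(a0 = p$a0),
          stats::setNames(p$a, paste0("a", seq_len(K))),
          stats::setNames(p$b, paste0("b", seq_len(K))))
  cf
}

#' @export
logLik.glmpo2pls <- function(object, ...) {
  val <- tail(object$loglik_trace, 1)
  attr(val, "df") <- NA_integer_
  class(val) <- "logLik"
  val
}

#' Predict the outcome for new samples
#'
#' Conditional-mean prediction under the fitted model: the posterior means
#' of the joint components given (x, y) alone are pushed through the
#' outcome equation. For the gaussian family this is the exact conditional
#' mean E[z | x, y]; for the bernoulli family the posterior-mean linear
#' predictor is returned on the probability (\code{type = "response"}) or
#' logit (\code{type = "link"}) scale.
#'
#' @param object A \code{glmpo2pls} fit.
#' @param newx,newy New data with the training feature sets; centered by the
#'   training statistics.
#' @param type Prediction scale (bernoulli only).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.glmpo2pls <- function(object, newx, newy,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- sweep(as.matrix(newx), 2, object$centers$x)
  newy <- sweep(as.matrix(newy), 2, object$centers$y)
  pr <- predict_outcome(object, newx, newy, centered = TRUE)
  if (object$family == "gaussian") pr$response + object$centers$z
  else if (type == "response") pr$response else pr$link
}

#' Outcome prediction from a core fit
#'
#' Low-level prediction operating on already-centered matrices; see
#' \code{\link{predict.glmpo2pls}} for the user-facing method.
#'
#' @param fit A \code{po2pls_fit} or \code{glmpo2pls} object.
#' @param x_new,y_new Centered matrices with p resp. q columns.
#' @param centered Assert that the inputs are centered (only FALSE raises an
#'   error; kept explicit to avoid silent misuse).
#' @return List with \code{response} (expected outcome / probability) and
#'   \code{link} (linear predictor).
#' @export
predict_outcome <- function(fit, x_new, y_new, centered = TRUE) {
  if (!centered) stop("predict_outcome expects centered inputs")
  params <- fit$params
  d <- params$dims
  if (ncol(x_new) != d$p || ncol(y_new) != d$q)
    stop("new data dimensions do not match the fitted model")
  L <- .lambda_zeta(params, with_z = FALSE)
  Dvec <- c(rep(params$sig_e2, d$p), rep(params$sig_f2, d$q))
  po <- .gauss_posterior(L, .sigma_zeta(params), Dvec, cbind(x_new, y_new))
  K <- d$K
  Et <- po$Em[, seq_len(K), drop = FALSE]
  Eh <- po$Em[, K + seq_len(K), drop = FALSE] - sweep(Et, 2, params$B, `*`)
  lp <- drop(params$a0 + Et %*% params$a + Eh %*% params$b)
  list(response = if (params$family == "gaussian") lp else stats::plogis(lp),
       link = lp,
       scores = list(t = Et, h = Eh, u = po$Em[, K + seq_len(K), drop = FALSE]))
}

#' @export
fitted.glmpo2pls <- function(object, ...) {
  if (is.null(object$x)) stop("refit with keep_data = TRUE to use fitted()")
  pr <- predict_outcome(object, object$x, object$y)
  if (object$family == "gaussian") pr$response + object$centers$z
  else pr$response
}

#' @export
residuals.glmpo2pls <- function(object, ...) {
  if (is.null(object$x)) stop("refit with keep_data = TRUE to use residuals()")
  pr <- predict_outcome(object, object$x, object$y)
  object$z - pr$response
}

#' @export
summary.glmpo2pls <- function(object, ...) {
  tst <- test_association(object, object$z)
  d <- object$dims
  varx <- c(joint = sum(object$params$St), specific = sum(object$params$Sto),
            residual = object$params$sig_e2 * d$p)
  Su <- object$params$B^2 * object$params$St + object$params$Sh
  vary <- c(joint = sum(Su), specific = sum(object$params$Suo),
            residual = object$params$sig_f2 * d$q)
  structure(list(fit = object, test = tst,
                 var_x = varx / sum(varx), var_y = vary / sum(vary),
                 inner = test_omics_association(object)),
            class = "summary.glmpo2pls")
}

#' @export
print.summary.glmpo2pls <- function(x, ...) {
  print(x$fit)
  cat("\nVariance decomposition (fractions of expected total):\n")
  cat("  x:", paste(sprintf("%s %.3f", names(x$var_x), x$var_x),
                    collapse = ", "), "\n")
  cat("  y:", paste(sprintf("%s %.3f", names(x$var_y), x$var_y),
                    collapse = ", "), "\n\n")
  print(x$test)
  cat("\nInner relation u = t B + h (Wald, df = 1):\n")
  print(x$inner, row.names = FALSE)
  invisible(x)
}

#' @export
plot.glmpo2pls <- function(x, which = c("trace", "scores"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$loglik_trace) - 1L, x$loglik_trace,
                   type = "b", xlab = "EM iteration",
                   ylab = "observed-data log-likelihood", ...)
  } else {
    K <- x$dims$K
    Et <- x$moments$mean[, 1L, drop = TRUE]
    Eu <- x$moments$mean[, K + 1L, drop = TRUE]
    graphics::plot(Et, Eu, xlab = "t score (component 1)",
                   ylab = "u score (component 1)", ...)
    graphics::abline(0, x$params$B[1], lty = 2)
  }
  invisible(x)
}

#' Simulate responses and omics data from a fitted model
#'
#' Draws complete datasets (x, y, z) from the generative model at the
#' fitted parameters, on the original (uncentered) scale.
#'
#' @param object A \code{glmpo2pls} fit.
#' @param nsim Number of datasets.
#' @param seed Seed.
#' @param N Samples per dataset (defaults to the training size).
#' @param ... Unused.
#' @return A list of length \code{nsim} of lists with x, y, z.
#' @export
simulate.glmpo2pls <- function(object, nsim = 1, seed = NULL, N = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(N)) N <- object$dims$N
  p <- object$params; d <- object$dims
  out <- replicate(nsim, {
    Tm <- matrix(stats::rnorm(N * d$K), N) %*% diag(sqrt(p$St), d$K)
    H <- matrix(stats::rnorm(N * d$K), N) %*% diag(sqrt(p$Sh), d$K)
    U <- Tm %*% diag(p$B, d$K) + H
    To <- matrix(stats::rnorm(N * d$Kx), N) %*% diag(sqrt(p$Sto), d$Kx)
    Uo <- matrix(stats::rnorm(N * d$Ky), N) %*% diag(sqrt(p$Suo), d$Ky)
    x <- tcrossprod(Tm, p$W) + tcrossprod(To, p$Wo) +
      matrix(stats::rnorm(N * d$p, sd = sqrt(p$sig_e2)), N)
    y <- tcrossprod(U, p$C) + tcrossprod(Uo, p$Co) +
      matrix(stats::rnorm(N * d$q, sd = sqrt(p$sig_f2)), N)
    lp <- drop(p$a0 + Tm %*% p$a + H %*% p$b)
    z <- if (object$family == "gaussian")
      lp + stats::rnorm(N, sd = sqrt(p$sig_g2)) + object$centers$z
    else stats::rbinom(N, 1L, stats::plogis(lp))
    list(x = sweep(x, 2, object$centers$x, `+`),
         y = sweep(y, 2, object$centers$y, `+`), z = z)
  }, simplify = FALSE)
  out
}
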