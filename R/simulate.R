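# Deterministic sub-streams from one master seed, so loadings, latents and
# noise are independently reproducible. Kept below 2^31 - 1.
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Simulation scenario
#'
#' Describes one cell of the simulation grid used to study the model:
#' sample size, dimensions, component counts, the heterogeneity level (share
#' of the variance of \code{u} carried by \code{h}), the residual-variance
#' fractions of the two omics blocks and of the continuous outcome, and the
#' true outcome coefficients. Defaults are the grid anchors: coefficients
#' a = 2 and b = 1, moderate (40\%) heterogeneity, low noise (40\%/40\%) in
#' x and y, 20\% noise in the continuous outcome, one joint and one specific
#' component per block.
#'
#' @param N Sample size.
#' @param p,q Feature counts of x and y.
#' @param K,Kx,Ky Component counts.
#' @param heterogeneity Fraction of var(u) explained by h (0.4 or 0.8 in the
#'   grid).
#' @param noise_x,noise_y Residual variance fractions of x and y (0.4/0.4 or
#'   0.95/0.05 in the grid).
#' @param noise_z Residual fraction of the variance of the continuous
#'   outcome (0.2 in the grid).
#' @param a_coef,b_coef True coefficients (recycled to length K).
#' @param a0 Intercept of the binary linear predictor.
#' @param family Outcome family.
#' @param seed Master seed; expanded into sub-streams for loadings, latents
#'   and noise.
#' @return Object of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(N = 100, p = 100, q = 10, K = 1, Kx = 1, Ky = 1,
                         heterogeneity = 0.4, noise_x = 0.4, noise_y = 0.4,
                         noise_z = 0.2, a_coef = 2, b_coef = 1, a0 = 0,
                         family = c("gaussian", "bernoulli"), seed = 1L) {
  family <- match.arg(family)
  fr <- c(heterogeneity = heterogeneity, noise_x = noise_x,
          noise_y = noise_y, noise_z = noise_z)
  if (any(fr <= 0 | fr >= 1))
    stop("variance fractions must lie strictly between 0 and 1")
  po2pls_dims(p, q, K, Kx, Ky, N)  # dimension sanity
  structure(list(N = as.integer(N), p = as.integer(p), q = as.integer(q),
                 K = as.integer(K), Kx = as.integer(Kx), Ky = as.integer(Ky),
                 heterogeneity = heterogeneity, noise_x = noise_x,
                 noise_y = noise_y, noise_z = noise_z,
                 a_coef = rep_len(a_coef, K), b_coef = rep_len(b_coef, K),
                 a0 = a0, family = family, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Draw a random semi-orthogonal loading matrix
#'
#' Entries are drawn standard normal and the columns orthonormalized (QR),
#' the construction used for all true loading matrices in the simulator.
#'
#' @param dim Number of rows (features).
#' @param ncomp Number of columns (components); at most \code{dim}.
#' @param seed Seed making the draw reproducible.
#' @return A \code{dim} x \code{ncomp} matrix with orthonormal columns.
#' @export
make_loadings <- function(dim, ncomp, seed = 1L) {
  if (ncomp > dim) stop("ncomp must not exceed dim")
  set.seed(seed)
  M <- matrix(stats::rnorm(dim * ncomp), dim, ncomp)
  Q <- qr.Q(qr(M))
  # fix QR's column-sign ambiguity so the draw is a pure function of the seed
  s <- sign(Q[cbind(apply(abs(Q), 2, which.max), seq_len(ncomp))])
  sweep(Q, 2, s, `*`)
}

#' Calibrate model variances for a scenario
#'
#' Turns a scenario's variance fractions into a concrete parameter set.
#' Latent variances follow the standard-normal convention (\code{St} is 1
#' for one joint component; a decreasing sequence K..1 for several, keeping
#' \code{diag(St * B)} strictly decreasing with \code{B = I}), and only the
#' heterogeneity variance \code{Sh} is scaled:
#' \code{Sh = het/(1-het) * B^2 St}. Noise fractions are trace ratios of
#' expected variance, giving \code{sig_e2 = noise_x/(1-noise_x) *
#' (tr St + tr Sto)/p} and the analogues for y and the outcome.
#'
#' @param scenario A \code{sim_scenario}.
#' @param loadings Optional list with W, C, Wo, Co; drawn from the
#'   scenario's seed when missing. The pairs [W Wo] and [C Co] are
#'   orthonormalized jointly so specific subspaces are orthogonal to joint
#'   ones.
#' @return A valid \code{po2pls_params} object.
#' @export
calibrate_variances <- function(scenario, loadings = NULL) {
  s <- scenario
  if (is.null(loadings)) {
    Lx <- make_loadings(s$p, s$K + s$Kx, .subseed(s$seed, 1L))
    Ly <- make_loadings(s$q, s$K + s$Ky, .subseed(s$seed, 2L))
    loadings <- list(W = Lx[, seq_len(s$K), drop = FALSE],
                     Wo = Lx[, s$K + seq_len(s$Kx), drop = FALSE],
                     C = Ly[, seq_len(s$K), drop = FALSE],
                     Co = Ly[, s$K + seq_len(s$Ky), drop = FALSE])
  }
  St <- if (s$K == 1L) 1 else as.numeric(s$K:1)
  B <- rep(1, s$K)
  Sto <- rep(1, s$Kx); Suo <- rep(1, s$Ky)
  het <- s$heterogeneity
  Sh <- het / (1 - het) * B^2 * St
  Su <- B^2 * St + Sh
  sig_e2 <- s$noise_x / (1 - s$noise_x) * (sum(St) + sum(Sto)) / s$p
  sig_f2 <- s$noise_y / (1 - s$noise_y) * (sum(Su) + sum(Suo)) / s$q
  a <- s$a_coef; b <- s$b_coef
  var_lp <- sum(a^2 * St) + sum(b^2 * Sh)
  sig_g2 <- s$noise_z / (1 - s$noise_z) * var_lp
  po2pls_params(W = loadings$W, C = loadings$C, Wo = loadings$Wo,
                Co = loadings$Co, B = B, St = St, Sto = Sto, Suo = Suo,
                Sh = Sh, sig_e2 = sig_e2, sig_f2 = sig_f2,
                a = a, b = b, a0 = s$a0,
                sig_g2 = if (s$family == "gaussian") sig_g2 else NULL,
                family = s$family)
}

#' Simulate a dataset from the generative model
#'
#' Draws latent components (t, t-specific, u-specific standard normal with
#' the calibrated variances; h normal; \code{u = t B + h}), assembles
#' \code{x = t W' + t_o Wo' + e} and \code{y = u C' + u_o Co' + f}, and the
#' outcome: continuous \code{z = t a' + h b' + g} or binary
#' \code{z ~ Bernoulli(plogis(a0 + t a' + h b'))}.
#'
#' @param scenario A \code{sim_scenario}.
#' @param params Optional parameter set (defaults to
#'   \code{calibrate_variances(scenario)}).
#' @return List with matrices \code{x}, \code{y}, vector \code{z}, the
#'   latent truth (\code{latents}) and the true parameters (\code{params}).
#' @export
simulate_dataset <- function(scenario, params = NULL) {
  s <- scenario
  if (is.null(params)) params <- calibrate_variances(s)
  N <- s$N
  set.seed(.subseed(s$seed, 3L))
  Tm <- matrix(stats::rnorm(N * s$K), N) %*% diag(sqrt(params$St), s$K)
  H <- matrix(stats::rnorm(N * s$K), N) %*% diag(sqrt(params$Sh), s$K)
  U <- Tm %*% diag(params$B, s$K) + H
  To <- matrix(stats::rnorm(N * s$Kx), N) %*% diag(sqrt(params$Sto), s$Kx)
  Uo <- matrix(stats::rnorm(N * s$Ky), N) %*% diag(sqrt(params$Suo), s$Ky)
  set.seed(.subseed(s$seed, 4L))
  x <- tcrossprod(Tm, params$W) + tcrossprod(To, params$Wo) +
    matrix(stats::rnorm(N * s$p, sd = sqrt(params$sig_e2)), N)
  y <- tcrossprod(U, params$C) + tcrossprod(Uo, params$Co) +
    matrix(stats::rnorm(N * s$q, sd = sqrt(params$sig_f2)), N)
  lp <- drop(params$a0 + Tm %*% params$a + H %*% params$b)
  z <- if (s$family == "gaussian") {
    lp + stats::rnorm(N, sd = sqrt(params$sig_g2))
  } else {
    stats::rbinom(N, 1L, stats::plogis(lp))
  }
  dimnames(x) <- list(paste0("S", seq_len(N)), paste0("x", seq_len(s$p)))
  dimnames(y) <- list(rownames(x), paste0("y", seq_len(s$q)))
  names(z) <- rownames(x)
  list(x = x, y = y, z = z,
       latents = list(t = Tm, u = U, to = To, uo = Uo, h = H, lp = lp),
       params = params, scenario = s)
}

#' Outcome under the null hypothesis
#'
#' Standard-normal outcome drawn independently of both omics blocks, the
#' protocol used to measure the empirical type-I error of the association
#' tests.
#'
#' @param x,y Ignored except for determining the sample size when \code{N}
#'   is missing.
#' @param seed Seed.
#' @param N Number of samples (defaults to \code{nrow(x)}).
#' @return Numeric vector of length N.
#' @export
simulate_null_outcome <- function(x = NULL, y = NULL, seed = 1L, N = NULL) {
  if (is.null(N)) N <- nrow(x)
  set.seed(seed)
  stats::rnorm(N)
}
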