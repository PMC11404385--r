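#' Model dimensions
#'
#' Bundle and validate the dimensions of a GLM-PO2PLS model: feature counts
#' of the two omics blocks, numbers of joint and data-specific latent
#' components, and sample size. The coefficient vectors \code{a} and \code{b}
#' have one entry per joint component, so their length \code{r} equals
#' \code{K} throughout.
#'
#' @param p,q Number of features in \code{x} resp. \code{y}.
#' @param K Number of joint components (latent pairs \code{t}, \code{u}).
#' @param Kx,Ky Number of x-specific resp. y-specific components.
#' @param N Sample count (optional, 0 when not tied to data).
#' @return An object of class \code{"po2pls_dims"}.
#' @export
po2pls_dims <- function(p, q, K, Kx, Ky, N = 0L) {
  d <- list(p = as.integer(p), q = as.integer(q), K = as.integer(K),
            Kx = as.integer(Kx), Ky = as.integer(Ky), r = as.integer(K),
            N = as.integer(N))
  with(d, {
    if (p < 1L || q < 1L || K < 1L || Kx < 1L || Ky < 1L)
      stop("all dimensions must be positive integers")
    if (K > min(p, q)) stop("K must not exceed min(p, q)")
    if (Kx >= p) stop("Kx must be smaller than p")
    if (Ky >= q) stop("Ky must be smaller than q")
  })
  structure(d, class = "po2pls_dims")
}

#' Parameter collection of the GLM-PO2PLS model
#'
#' The full parameter set theta: semi-orthogonal loading matrices for the
#' joint (\code{W}, \code{C}) and specific (\code{Wo}, \code{Co}) subspaces,
#' diagonal latent covariances (stored as vectors), the diagonal inner
#' relation \code{u = t B + h}, residual variances, and the outcome part.
#' Coefficients are stored in the collinearity-reduced parameterization: the
#' linear predictor is \code{a0 + t a' + h b'}, so \code{a} is the total
#' x-effect and \code{b} the direct y-effect on the outcome.
#'
#' @param W,C p x K and q x K joint loading matrices (semi-orthogonal).
#' @param Wo,Co p x Kx and q x Ky specific loading matrices.
#' @param B Length-K vector, the diagonal of the positive inner relation.
#' @param St,Sto,Suo,Sh Diagonals of the latent covariances of t, t-specific,
#'   u-specific and the heterogeneity term h.
#' @param sig_e2,sig_f2 Residual variances of x resp. y.
#' @param a,b Length-K outcome coefficient vectors (total and direct effect).
#' @param a0 Intercept of the linear predictor (0 for the gaussian family,
#'   which assumes a centered outcome).
#' @param sig_g2 Outcome residual variance (gaussian family only).
#' @param family \code{"gaussian"} or \code{"bernoulli"}.
#' @return An object of class \code{"po2pls_params"}.
#' @export
po2pls_params <- function(W, C, Wo, Co, B, St, Sto, Suo, Sh,
                          sig_e2, sig_f2, a, b, a0 = 0,
                          sig_g2 = NULL, family = c("gaussian", "bernoulli")) {
  family <- match.arg(family)
  W <- as.matrix(W); C <- as.matrix(C)
  Wo <- as.matrix(Wo); Co <- as.matrix(Co)
  p <- nrow(W); q <- nrow(C); K <- ncol(W)
  dims <- po2pls_dims(p, q, K, ncol(Wo), ncol(Co))
  if (nrow(Wo) != p || nrow(Co) != q || ncol(C) != K)
    stop("loading matrix dimensions are inconsistent")
  if (length(B) != K || length(St) != K || length(Sh) != K ||
      length(a) != K || length(b) != K)
    stop("B, St, Sh, a, b must all have length K")
  if (length(Sto) != dims$Kx || length(Suo) != dims$Ky)
    stop("Sto/Suo length must match Kx/Ky")
  if (family == "gaussian") {
    if (is.null(sig_g2)) stop("sig_g2 is required for the gaussian family")
    a0 <- 0
  }
  structure(list(W = W, C = C, Wo = Wo, Co = Co,
                 B = as.numeric(B), St = as.numeric(St),
                 Sto = as.numeric(Sto), Suo = as.numeric(Suo),
                 Sh = as.numeric(Sh),
                 sig_e2 = as.numeric(sig_e2), sig_f2 = as.numeric(sig_f2),
                 a = as.numeric(a), b = as.numeric(b), a0 = as.numeric(a0),
                 sig_g2 = if (is.null(sig_g2)) NULL else as.numeric(sig_g2),
                 family = family, dims = dims),
            class = "po2pls_params")
}

#' Validate identifiability constraints of a parameter set
#'
#' Checks the conditions under which the model is identified up to component
#' sign: semi-orthogonal loading blocks, full column rank of the stacked
#' loadings, positive diagonal inner relation with strictly decreasing
#' \code{diag(St * B)}, and positive variances. Structural (dimension)
#' problems raise an error; constraint violations are reported.
#'
#' @param params A \code{po2pls_params} object.
#' @param tol Numeric tolerance for the orthonormality and ordering checks.
#' @return Character vector of violated constraints; empty when all hold.
#' @export
validate_params <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "po2pls_params"))
  v <- character(0)
  orth <- function(M, label) {
    dev <- max(abs(crossprod(M) - diag(ncol(M))))
    if (dev > tol) sprintf("%s semi-orthogonality (max deviation %.3g)", label, dev)
  }
  v <- c(v, orth(params$W, "W"), orth(params$C, "C"),
         orth(params$Wo, "Wo"), orth(params$Co, "Co"))
  if (qr(cbind(params$W, params$Wo))$rank < params$dims$K + params$dims$Kx)
    v <- c(v, "[W Wo] rank deficiency")
  if (qr(cbind(params$C, params$Co))$rank < params$dims$K + params$dims$Ky)
    v <- c(v, "[C Co] rank deficiency")
  if (any(params$B <= 0))
    v <- c(v, sprintf("B positivity (min %.3g)", min(params$B)))
  stb <- params$St * params$B
  if (params$dims$K > 1L && any(diff(stb) > -tol))
    v <- c(v, "diag(St * B) not strictly decreasing")
  pos <- c(St = min(params$St), Sto = min(params$Sto), Suo = min(params$Suo),
           Sh = min(params$Sh), sig_e2 = params$sig_e2, sig_f2 = params$sig_f2)
  if (params$family == "gaussian") pos <- c(pos, sig_g2 = params$sig_g2)
  bad <- names(pos)[pos <= 0]
  if (length(bad))
    v <- c(v, paste0(bad, " positivity"))
  v
}

# Loading map Lambda of (x, y, z-linear-predictor) on zeta = (t, u, t_o, u_o)
# and the latent covariance Sigma_zeta. Shared by the covariance builder and
# both E-steps. The z row uses the (t, h) form: z = (a - B b) t + b u + g.
.lambda_zeta <- function(params, with_z = TRUE) {
  d <- params$dims
  K <- d$K
  Lx <- cbind(params$W, matrix(0, d$p, K), params$Wo,
              matrix(0, d$p, d$Ky))
  Ly <- cbind(matrix(0, d$q, K), params$C, matrix(0, d$q, d$Kx), params$Co)
  L <- rbind(Lx, Ly)
  if (with_z) {
    Lz <- c(params$a - params$B * params$b, params$b,
            numeric(d$Kx), numeric(d$Ky))
    L <- rbind(L, Lz)
  }
  unname(L)
}

.sigma_zeta <- function(params) {
  d <- params$dims
  K <- d$K
  n <- 2L * K + d$Kx + d$Ky
  S <- matrix(0, n, n)
  it <- seq_len(K); iu <- K + it
  S[cbind(it, it)] <- params$St
  S[cbind(it, iu)] <- S[cbind(iu, it)] <- params$St * params$B
  S[cbind(iu, iu)] <- params$B^2 * params$St + params$Sh
  io <- 2L * K + seq_len(d$Kx)
  S[cbind(io, io)] <- params$Sto
  jo <- 2L * K + d$Kx + seq_len(d$Ky)
  S[cbind(jo, jo)] <- params$Suo
  S
}

#' Joint covariance implied by the model
#'
#' Builds the covariance matrix of the observed vector: for the gaussian
#' family the full (p+q+1) x (p+q+1) covariance of (x, y, z); for the
#' bernoulli family the z row/column holds the covariance structure of the
#' linear predictor (which is normally distributed), excluding any outcome
#' residual variance. Also returns the sub-covariances used by the EM
#' algorithms.
#'
#' @param params A valid \code{po2pls_params} object.
#' @return List with \code{Sigma_theta}, \code{Sigma_nu} (covariance of
#'   (t,u)), \code{Sigma_x_given_t}, \code{Sigma_y_given_u}, \code{Sigma_u}.
#' @export
build_joint_covariance <- function(params) {
  bad <- validate_params(params)
  if (length(bad)) stop("invalid parameters: ", paste(bad, collapse = "; "))
  d <- params$dims
  L <- .lambda_zeta(params, with_z = TRUE)
  Sz <- .sigma_zeta(params)
  Sig <- L %*% Sz %*% t(L)
  dg <- c(rep(params$sig_e2, d$p), rep(params$sig_f2, d$q),
          if (params$family == "gaussian") params$sig_g2 else 0)
  diag(Sig) <- diag(Sig) + dg
  Sig <- (Sig + t(Sig)) / 2
  K <- d$K
  Sigma_nu <- .sigma_zeta(params)[seq_len(2 * K), seq_len(2 * K), drop = FALSE]
  Sxt <- params$Wo %*% (params$Sto * t(params$Wo))
  diag(Sxt) <- diag(Sxt) + params$sig_e2
  Syu <- params$Co %*% (params$Suo * t(params$Co))
  diag(Syu) <- diag(Syu) + params$sig_f2
  list(Sigma_theta = Sig, Sigma_nu = Sigma_nu,
       Sigma_x_given_t = Sxt, Sigma_y_given_u = Syu,
       Sigma_u = params$B^2 * params$St + params$Sh)
}

#' Canonicalize component signs
#'
#' The model is identified up to a per-component sign flip: negating a joint
#' component flips the matching columns of \code{W} and \code{C} and the
#' entries of \code{a} and \code{b} together; negating a specific component
#' flips one column of \code{Wo} or \code{Co}. This picks the representative
#' in which the largest-absolute-value entry of each reference loading column
#' (\code{W} for joint components) is positive, with ties broken by the first
#' index. The implied joint covariance is unchanged.
#'
#' @param params A \code{po2pls_params} object.
#' @return The canonicalized parameter object.
#' @export
canonicalize_signs <- function(params) {
  flip_of <- function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  }
  for (k in seq_len(params$dims$K)) {
    s <- flip_of(params$W[, k])
    params$W[, k] <- s * params$W[, k]
    params$C[, k] <- s * params$C[, k]
    params$a[k] <- s * params$a[k]
    params$b[k] <- s * params$b[k]
  }
  for (k in seq_len(params$dims$Kx)) {
    s <- flip_of(params$Wo[, k])
    params$Wo[, k] <- s * params$Wo[, k]
  }
  for (k in seq_len(params$dims$Ky)) {
    s <- flip_of(params$Co[, k])
    params$Co[, k] <- s * params$Co[, k]
  }
  params
}

#' Collinearity-reducing reparameterization of the outcome coefficients
#'
#' The linear predictor \code{a0 + t a_raw' + u b_raw'} written in terms of
#' \code{t} and the heterogeneity \code{h = u - t B} becomes
#' \code{a0 + t (a_raw + B b_raw)' + h b_raw'}. The returned \code{a} is the
#' total x-effect, \code{b} the direct y-effect; this is the parameterization
#' the package stores internally.
#'
#' @param a_raw,b_raw Length-K coefficient vectors on (t, u).
#' @param B Diagonal of the inner relation (length-K vector or diagonal
#'   matrix).
#' @return List with components \code{a} and \code{b}.
#' @export
reparameterize <- function(a_raw, b_raw, B) {
  if (is.matrix(B)) B <- diag(B)
  stopifnot(length(a_raw) == length(b_raw), length(B) == length(a_raw))
  list(a = a_raw + B * b_raw, b = b_raw)
}
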