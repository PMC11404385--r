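#' Scree spectra for choosing component numbers
#'
#' Computes the singular values of \code{x'y} (joint spectrum) and the
#' eigenvalues of \code{x'x} and \code{y'y} after removing the estimated
#' joint part (specific spectra), without forming p x p products: all
#' spectra come from N-dimensional or q-dimensional Gram matrices. A
#' largest-successive-ratio-drop heuristic turns each spectrum into an
#' advisory suggested count; inspecting the plot remains the intended use.
#'
#' @param x,y Column-centered data matrices with matching rows.
#' @param K Number of joint components to remove before the specific
#'   spectra; when \code{NULL}, the joint suggestion is used.
#' @param nmax Maximum number of spectrum values to return per block.
#' @return Object of class \code{"scree_result"}: \code{joint} (singular
#'   values of x'y), \code{x_specific}, \code{y_specific} (eigenvalues of
#'   the deflated cross-products), \code{suggested} (list with K, Kx, Ky).
#' @export
scree <- function(x, y, K = NULL, nmax = 10L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 2L || nrow(y) != n) stop("x and y need at least 2 matching rows")
  # singular values of x'y via the q x q Gram matrix y' (x x') y
  Gx <- tcrossprod(x)                       # N x N
  A <- crossprod(y, Gx %*% y)               # q x q, = (x'y)'(x'y)
  sv <- sqrt(pmax(eigen((A + t(A)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values, 0))
  joint <- sv[seq_len(min(nmax, length(sv)))]
  suggest <- function(v) {
    v <- v[v > max(v) * 1e-12]
    if (length(v) < 2L) return(1L)
    which.max(v[-length(v)] / v[-1])
  }
  Ksel <- if (is.null(K)) suggest(joint) else as.integer(K)
  # joint directions from the top-K right/left singular pairs of x'y
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  Cjoint <- ev$vectors[, seq_len(Ksel), drop = FALSE]
  # deflate via the joint score subspaces and take Gram eigenvalues
  # (x-side scores are proportional to x x' y c = Gx y c)
  defl <- function(M, S) {
    Q <- qr.Q(qr(S))
    M - Q %*% crossprod(Q, M)
  }
  ex <- defl(x, x %*% crossprod(x, y %*% Cjoint))
  ey <- defl(y, y %*% Cjoint)
  eig_gram <- function(E) {
    v <- eigen(tcrossprod(E), symmetric = TRUE, only.values = TRUE)$values
    pmax(v[seq_len(min(nmax, length(v)))], 0)
  }
  xs <- eig_gram(ex); ys <- eig_gram(ey)
  structure(list(joint = joint, x_specific = xs, y_specific = ys,
                 suggested = list(K = Ksel, Kx = suggest(xs),
                                  Ky = suggest(ys))),
            class = "scree_result")
}

#' @export
print.scree_result <- function(x, ...) {
  cat("Scree spectra\n")
  cat("  joint (singular values of x'y):",
      paste(signif(x$joint, 4), collapse = " "), "\n")
  cat("  x-specific (eigenvalues of deflated x'x):",
      paste(signif(x$x_specific, 4), collapse = " "), "\n")
  cat("  y-specific (eigenvalues of deflated y'y):",
      paste(signif(x$y_specific, 4), collapse = " "), "\n")
  cat(sprintf("  suggested (advisory): K = %d, Kx = %d, Ky = %d\n",
              x$suggested$K, x$suggested$Kx, x$suggested$Ky))
  invisible(x)
}

#' @export
plot.scree_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  sp <- list(joint = x$joint, `x specific` = x$x_specific,
             `y specific` = x$y_specific)
  for (nm in names(sp))
    graphics::plot(sp[[nm]], type = "b", xlab = "component",
                   ylab = "spectrum value", main = nm, ...)
  invisible(x)
}
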