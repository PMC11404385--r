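#' Root mean square error of prediction
#'
#' For a continuous outcome, the root mean squared difference between
#' predicted and realized outcome. For a binary outcome, predictions and
#' truth are probabilities and the error is measured on the logit scale;
#' probabilities at 0 or 1 are clipped to \code{[eps, 1 - eps]} with a
#' warning.
#'
#' @param pred,truth Equal-length numeric vectors (probabilities for the
#'   bernoulli family).
#' @param family Outcome family.
#' @param eps Clipping bound for the bernoulli logit.
#' @return Scalar RMSEP.
#' @export
rmsep <- function(pred, truth, family = c("gaussian", "bernoulli"),
                  eps = 1e-12) {
  family <- match.arg(family)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (family == "bernoulli") {
    if (any(pred <= 0 | pred >= 1 | truth <= 0 | truth >= 1)) {
      warning("probabilities at 0/1 clipped before taking logits")
      pred <- pmin(pmax(pred, eps), 1 - eps)
      truth <- pmin(pmax(truth, eps), 1 - eps)
    }
    pred <- stats::qlogis(pred); truth <- stats::qlogis(truth)
  }
  sqrt(mean((pred - truth)^2))
}

#' True-positive rate of top-fraction feature recovery
#'
#' Fraction of the truly largest-magnitude loading features (top 25\% by
#' default) recovered among the same-sized set of estimated top features:
#' TP / (TP + FN). Ties at the cutoff are broken by feature index.
#'
#' @param loadings_est,loadings_true Equal-length loading vectors.
#' @param fraction Top fraction in (0, 1).
#' @return Scalar in [0, 1].
#' @export
tpr_top_quantile <- function(loadings_est, loadings_true, fraction = 0.25) {
  if (length(loadings_est) != length(loadings_true))
    stop("loading vectors must have equal length")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- ceiling(fraction * length(loadings_true))
  top <- function(v) order(-abs(v), seq_along(v))[seq_len(m)]
  length(intersect(top(loadings_est), top(loadings_true))) / m
}

#' Ridge regression baseline
#'
#' Standard ridge regression of the outcome on one omics block, with the
#' penalty chosen by 10-fold cross-validation (or fixed via \code{lambda}).
#' Used as the ridge-x / ridge-y comparators in the simulation harness.
#'
#' @param x Predictor matrix.
#' @param z Outcome vector.
#' @param folds CV folds.
#' @param family \code{"gaussian"} or \code{"bernoulli"}.
#' @param lambda Optional fixed penalty (skips CV).
#' @param seed Seed controlling the CV fold assignment.
#' @return List with \code{coef} (including intercept), \code{lambda}, and
#'   \code{predict(newx)} returning predictions (probabilities for the
#'   bernoulli family).
#' @export
ridge_baseline <- function(x, z, folds = 10L,
                           family = c("gaussian", "bernoulli"),
                           lambda = NULL, seed = 1L) {
  family <- match.arg(family)
  gfam <- if (family == "gaussian") "gaussian" else "binomial"
  if (is.null(lambda)) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, z, alpha = 0, nfolds = folds, family = gfam)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, z, alpha = 0, lambda = lambda, family = gfam,
                          standardize = FALSE, thresh = 1e-12)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda))
  list(coef = cf, lambda = lambda,
       predict = function(newx)
         as.numeric(stats::predict(fit, newx = as.matrix(newx), s = lambda,
                                   type = "response")))
}

# Align estimated joint loadings/coefficients to the truth's sign gauge
# (the model is identified up to per-component sign flips).
.align_to_truth <- function(fit_params, true_params) {
  K <- fit_params$dims$K
  s <- sign(colSums(fit_params$W * true_params$W))
  s[s == 0] <- 1
  fit_params$W <- sweep(fit_params$W, 2, s, `*`)
  fit_params$C <- sweep(fit_params$C, 2, s, `*`)
  fit_params$a <- s * fit_params$a
  fit_params$b <- s * fit_params$b
  so <- sign(colSums(fit_params$Wo * true_params$Wo)); so[so == 0] <- 1
  fit_params$Wo <- sweep(fit_params$Wo, 2, so, `*`)
  sc <- sign(colSums(fit_params$Co * true_params$Co)); sc[sc == 0] <- 1
  fit_params$Co <- sweep(fit_params$Co, 2, sc, `*`)
  fit_params
}

#' Metrics of one simulated fit against the truth
#'
#' Scaled coefficient errors, per-block loading inner products, top-25\%
#' feature-recovery TPR in x, and (when a test set is supplied) RMSEP of
#' the outcome prediction.
#'
#' @param fit A \code{po2pls_fit} on simulated data.
#' @param truth The simulation truth (\code{params} element of
#'   \code{\link{simulate_dataset}} output).
#' @param test Optional independent test dataset (list with x, y, z and,
#'   for the bernoulli family, latent linear predictor \code{latents$lp}).
#' @return One-row data frame of metrics.
#' @export
fit_metrics <- function(fit, truth, test = NULL) {
  est <- .align_to_truth(fit$params, truth)
  K <- truth$dims$K
  out <- data.frame(
    scaled_error_a = (est$a[1] - truth$a[1]) / truth$a[1],
    scaled_error_b = (est$b[1] - truth$b[1]) / truth$b[1],
    ip_W = sum(est$W[, 1] * truth$W[, 1]),
    ip_C = sum(est$C[, 1] * truth$C[, 1]),
    ip_Wo = sum(est$Wo[, 1] * truth$Wo[, 1]),
    ip_Co = sum(est$Co[, 1] * truth$Co[, 1]),
    tpr_top25 = tpr_top_quantile(est$W[, 1], truth$W[, 1], 0.25))
  if (!is.null(test)) {
    if (inherits(fit, "glmpo2pls")) {
      pred <- predict(fit, test$x, test$y)
    } else {
      pred <- predict_outcome(fit, scale(test$x, scale = FALSE),
                              scale(test$y, scale = FALSE))$response
    }
    out$rmsep <- if (truth$family == "gaussian")
      rmsep(pred, test$z, "gaussian")
    else rmsep(pred, stats::plogis(test$latents$lp), "bernoulli")
  }
  out
}

# Shared replicate driver: simulate (x, y) (and optionally an outcome under
# the model), fit the gaussian model and apply the full test.
.one_rep <- function(scenario, rep_seed, null_z, level, tol, max_iter) {
  sc <- scenario
  sc$seed <- rep_seed
  dat <- simulate_dataset(sc)
  z <- if (null_z) simulate_null_outcome(seed = .subseed(rep_seed, 11L),
                                         N = sc$N) else dat$z
  fit <- glmpo2pls(dat$x, dat$y, z, K = sc$K, Kx = sc$Kx, Ky = sc$Ky,
                   family = "gaussian", tol = tol, max_iter = max_iter,
                   keep_data = FALSE)
  tst <- test_association(fit, fit$z)
  list(reject = tst$full$p.value < level, p = tst$full$p.value, fit = fit,
       dat = dat)
}

#' Empirical type-I error of the full test
#'
#' Simulates (x, y) under the scenario, draws the outcome standard normal
#' independently of both blocks, fits the gaussian-outcome model and applies
#' the full chi-square test; repeats and reports the rejection fraction
#' (the empirical type-I error at the given level) with its binomial
#' standard error. Replicates whose fit fails are excluded and counted.
#'
#' @param scenario A gaussian \code{sim_scenario}.
#' @param reps Number of replicates.
#' @param level Significance level.
#' @param seed Master seed (one sub-seed per replicate).
#' @param tol,max_iter Fitting controls.
#' @return List with \code{rate}, \code{se}, \code{rejections},
#'   \code{reps_used}, \code{failures}.
#' @export
run_type1_experiment <- function(scenario, reps = 200L, level = 0.05,
                                 seed = 1L, tol = 1e-6, max_iter = 10000L) {
  rej <- logical(0); fail <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      .one_rep(scenario, .subseed(seed, r), TRUE, level, tol, max_iter),
      error = function(e) NULL)
    if (is.null(res)) fail <- fail + 1L else rej <- c(rej, res$reject)
  }
  rate <- mean(rej)
  list(rate = rate, se = sqrt(rate * (1 - rate) / length(rej)),
       rejections = rej, reps_used = length(rej), failures = fail)
}

#' Empirical power of the full test
#'
#' As \code{\link{run_type1_experiment}}, but with the outcome generated
#' under the model (true coefficients from the scenario, a = 2, b = 1 by
#' default), so the rejection fraction estimates power.
#'
#' @inheritParams run_type1_experiment
#' @return List with \code{rate}, \code{se}, \code{rejections},
#'   \code{reps_used}, \code{failures}.
#' @export
run_power_experiment <- function(scenario, reps = 200L, level = 0.05,
                                 seed = 1L, tol = 1e-6, max_iter = 10000L) {
  rej <- logical(0); fail <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      .one_rep(scenario, .subseed(seed, r), FALSE, level, tol, max_iter),
      error = function(e) NULL)
    if (is.null(res)) fail <- fail + 1L else rej <- c(rej, res$reject)
  }
  rate <- mean(rej)
  list(rate = rate, se = sqrt(rate * (1 - rate) / length(rej)),
       rejections = rej, reps_used = length(rej), failures = fail)
}

#' Run a grid of simulation scenarios
#'
#' For each scenario, simulates \code{reps} datasets, fits the model and
#' collects the accuracy metrics; optionally evaluates prediction RMSEP on
#' an independent test set (and ridge baselines on request).
#'
#' @param scenarios A \code{sim_scenario} or list of them.
#' @param reps Replicates per scenario.
#' @param seed Master seed.
#' @param test_n Test-set size for RMSEP (0 disables prediction metrics).
#' @param ridge Also fit ridge-x and ridge-y baselines and record their
#'   RMSEP.
#' @param tol,max_iter Fitting controls.
#' @return Long-format data frame, one row per (scenario, replicate).
#' @export
run_scenario_grid <- function(scenarios, reps = 100L, seed = 1L,
                              test_n = 0L, ridge = FALSE,
                              tol = 1e-6, max_iter = 10000L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(reps)) {
      rs <- .subseed(seed, 1000L * si + r)
      sc_r <- sc; sc_r$seed <- rs
      dat <- simulate_dataset(sc_r)
      test <- NULL
      if (test_n > 0L) {
        sc_t <- sc; sc_t$seed <- .subseed(rs, 17L); sc_t$N <- as.integer(test_n)
        test <- simulate_dataset(sc_t, params = dat$params)
      }
      row <- tryCatch({
        fit <- glmpo2pls(dat$x, dat$y, dat$z, K = sc$K, Kx = sc$Kx,
                         Ky = sc$Ky, family = sc$family, tol = tol,
                         max_iter = max_iter, keep_data = FALSE)
        m <- fit_metrics(fit, dat$params, test)
        if (ridge && !is.null(test)) {
          fam <- sc$family
          rx <- ridge_baseline(dat$x, dat$z, family = fam,
                               seed = .subseed(rs, 19L))
          ry <- ridge_baseline(dat$y, dat$z, family = fam,
                               seed = .subseed(rs, 23L))
          if (fam == "gaussian") {
            m$rmsep_ridge_x <- rmsep(rx$predict(test$x), test$z, "gaussian")
            m$rmsep_ridge_y <- rmsep(ry$predict(test$y), test$z, "gaussian")
          } else {
            pt <- stats::plogis(test$latents$lp)
            m$rmsep_ridge_x <- rmsep(rx$predict(test$x), pt, "bernoulli")
            m$rmsep_ridge_y <- rmsep(ry$predict(test$y), pt, "bernoulli")
          }
        }
        m
      }, error = function(e) NULL)
      if (!is.null(row)) {
        row$scenario <- si; row$rep <- r
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
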