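#' Efron partial log-likelihood at a fixed linear predictor
#'
#' @param eta Linear predictor (one value per patient).
#' @param time,event Survival outcome vectors.
#' @return Scalar log partial likelihood.
#' @export
cox_loglik <- function(eta, time, event) {
  ord <- order(time)
  st <- cox_efron_stats(eta[ord], time[ord], as.integer(event[ord]))
  st$loglik
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the objective `-(1/n) l(X beta) + lambda * sum(|beta|)`, the zero
#' vector is a solution exactly when `lambda >= max_j |(1/n) x_j' g0|`, with
#' `g0` the gradient of the partial likelihood at `beta = 0`.
#'
#' @param x Feature matrix.
#' @param time,event Survival outcome vectors.
#' @return The critical penalty `lambda_max`.
#' @export
lambda_max <- function(x, time, event) {
  n <- nrow(x)
  ord <- order(time)
  st <- cox_efron_stats(rep(0, n), time[ord], as.integer(event[ord]))
  g <- st$grad
  max(abs(crossprod(x[ord, , drop = FALSE], g))) / n
}

#' Decreasing penalty path
#'
#' Log-spaced sequence from `lambda_max` down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @param x,time,event As in [fit_l1_cox()].
#' @param nlambda Path length.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @return Decreasing numeric vector.
#' @export
lambda_path <- function(x, time, event, nlambda = 30, lambda_min_ratio = 0.05) {
  lmax <- lambda_max(x, time, event)
  if (lmax <= 0) return(rep(0, nlambda))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' L1-penalized Cox regression by cyclic coordinate descent
#'
#' Minimizes `-(1/n) l_Efron(X beta) + lambda * sum(|beta|)` by cyclic
#' coordinate descent on the quadratic approximation of the partial
#' likelihood, with warm starts along a decreasing penalty path. Columns are
#' expected to be standardized (the penalty is applied as-is to each
#' coefficient). Convergence is declared when the largest coefficient change
#' falls below `tol`.
#'
#' @param x Feature matrix (patients x features, typically z-scored).
#' @param time,event Survival outcome vectors.
#' @param lambda Penalty value or decreasing path; default a 30-step path
#'   from [lambda_path()].
#' @param tol Coefficient-change convergence tolerance.
#' @param max_iter Maximum outer (reweighting) iterations per penalty.
#' @param dev_ratio_max Saturation guard: descending the path stops once the
#'   model explains this fraction of the null partial-likelihood deviance
#'   (the returned path is truncated accordingly; the first requested
#'   penalty is always fitted). Set to `Inf` to disable.
#' @return Object of class `l1_cox_path`: list with `beta` (features x
#'   penalties), `lambda`, `loglik`, `features`, `n`, `n_events`,
#'   `path_truncated`.
#' @export
fit_l1_cox <- function(x, time, event, lambda = NULL, tol = 1e-7,
                       max_iter = 200, dev_ratio_max = 0.99) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(event) < 1) stop("at least one event is required")
  if (any(lambda %||% 0 < 0)) stop("lambda must be >= 0")
  if (is.null(lambda)) lambda <- lambda_path(x, time, event)
  lambda <- sort(lambda, decreasing = TRUE)
  ord <- order(time)
  fit <- lasso_cox_cd_path(x[ord, , drop = FALSE], time[ord],
                           as.integer(event[ord]), lambda, tol = tol,
                           maxit_outer = max_iter,
                           dev_ratio_max = dev_ratio_max)
  nf <- fit$n_fitted
  truncated <- nf < length(lambda)
  conv <- fit$converged[seq_len(nf)]
  if (conv[1] == 0)
    stop("coordinate descent failed to converge at lambda = ",
         signif(lambda[1], 4), " (", max_iter, " outer iterations)")
  if (any(conv == 0)) {
    # near-saturated tail of the path: stop where the solver last converged
    nf <- which(conv == 0)[1] - 1
    truncated <- TRUE
    warning("path truncated at lambda = ", signif(lambda[nf], 4),
            "; smaller penalties did not converge in ", max_iter,
            " outer iterations")
  }
  lambda <- lambda[seq_len(nf)]
  beta <- fit$beta[, seq_len(nf), drop = FALSE]
  dimnames(beta) <- list(colnames(x), signif(lambda, 6))
  structure(list(beta = beta, lambda = lambda,
                 loglik = as.numeric(fit$loglik)[seq_len(nf)],
                 features = colnames(x), n = nrow(x),
                 n_events = sum(event), path_truncated = truncated),
            class = "l1_cox_path")
}

#' Coefficients at one penalty
#'
#' @param fit An `l1_cox_path` object.
#' @param lambda Penalty; defaults to the smallest on the path. The closest
#'   path value is used.
#' @return Named coefficient vector.
#' @export
coef_l1_cox <- function(fit, lambda = NULL) {
  stopifnot(inherits(fit, "l1_cox_path"))
  i <- if (is.null(lambda)) length(fit$lambda)
       else which.min(abs(fit$lambda - lambda))
  stats::setNames(fit$beta[, i], fit$features)
}

#' Cross-validated penalty selection by partial-likelihood deviance
#'
#' K-fold cross-validation with the subtraction (Verweij-van-Houwelingen)
#' deviance: for each fold, the path is refit without the fold and the
#' fold's contribution is `-2 (l(beta; all) - l(beta; train))`. Fold
#' assignment is locally seeded, so identical inputs and seed reproduce the
#' same selection. Folds whose training part has no events are skipped and
#' recorded.
#'
#' @param x,time,event As in [fit_l1_cox()].
#' @param lambda Penalty path (default computed from the full data).
#' @param nfolds Number of folds.
#' @param seed Integer seed for fold assignment.
#' @return List with `lambda`, `cv_deviance`, `lambda_min`, `n_folds_used`.
#' @export
cv_l1_cox <- function(x, time, event, lambda = NULL, nfolds = 5, seed = 1) {
  x <- as.matrix(x)
  if (is.null(lambda)) lambda <- lambda_path(x, time, event)
  lambda <- sort(lambda, decreasing = TRUE)
  n <- nrow(x)
  folds <- with_local_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  dev <- rep(0, length(lambda))
  used <- 0
  max_common <- length(lambda)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (sum(event[tr]) < 1) next
    fit <- fit_l1_cox(x[tr, , drop = FALSE], time[tr], event[tr],
                      lambda = lambda)
    max_common <- min(max_common, length(fit$lambda))
    for (i in seq_along(fit$lambda)) {
      b <- fit$beta[, i]
      l_all <- cox_loglik(drop(x %*% b), time, event)
      l_tr <- cox_loglik(drop(x[tr, , drop = FALSE] %*% b), time[tr], event[tr])
      dev[i] <- dev[i] - 2 * (l_all - l_tr)
    }
    used <- used + 1
  }
  if (used == 0) stop("every cross-validation fold lacked events")
  # restrict selection to penalties every fold fitted (saturation guard)
  lambda <- lambda[seq_len(max_common)]
  dev <- dev[seq_len(max_common)]
  list(lambda = lambda, cv_deviance = dev,
       lambda_min = lambda[which.min(dev)], n_folds_used = used)
}
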