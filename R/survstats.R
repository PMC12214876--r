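#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function by the product-limit method. The median is
#' the smallest time at which the estimate drops to 0.5 or below; when the
#' curve never reaches 0.5 the median is `NA` and `median_reached` is FALSE
#' (a distinguished value, never infinity arithmetic).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = progressed, 0 = censored).
#' @return List with `curve` (data.frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, rows at event times), `median`,
#'   `median_reached`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord])
  ut <- unique(time)
  n <- length(time)
  f <- factor(time, levels = ut)
  n_total <- as.integer(table(f))
  n_risk <- n - c(0, cumsum(n_total)[-length(ut)])
  n_event <- as.integer(tapply(event, f, sum))
  n_censor <- n_total - n_event
  surv <- cumprod(1 - n_event / n_risk)
  curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, survival = surv)
  evt <- curve[curve$n_event > 0, , drop = FALSE]
  below <- evt$time[evt$survival <= 0.5]
  med <- if (length(below)) min(below) else NA_real_
  list(curve = curve, median = med, median_reached = length(below) > 0,
       n = n, n_events = sum(event))
}

#' Log-rank test
#'
#' Observed-minus-expected test for equality of survival across groups, with
#' hypergeometric variance at each event time. For two groups the statistic
#' is the square of the standardized O - E with 1 degree of freedom; k groups
#' use the (k-1)-dimensional quadratic form.
#'
#' @param time,event Survival outcome vectors.
#' @param group Group labels (at least two non-empty groups).
#' @return List with `chisq`, `df`, `p_value`, and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) < 2) stop("at least two groups are required")
  if (any(table(factor(group, levels = lv)) == 0)) stop("empty group")
  if (sum(event) < 1) stop("no events")
  k <- length(lv)
  ut <- sort(unique(time))
  f <- factor(time, levels = ut)
  gf <- factor(group, levels = lv)
  # per-time counts and events by group, at-risk via suffix sums
  cnt <- table(f, gf)                       # removals at each time, by group
  dmat <- table(f[event == 1], gf[event == 1])
  dmat <- unclass(dmat)[match(ut, rownames(dmat)), , drop = FALSE]
  dmat[is.na(dmat)] <- 0
  atrisk <- apply(unclass(cnt), 2, function(col) rev(cumsum(rev(col))))
  atrisk <- matrix(atrisk, ncol = k)
  d_t <- rowSums(dmat)
  keep <- d_t > 0
  dmat <- dmat[keep, , drop = FALSE]
  atrisk <- atrisk[keep, , drop = FALSE]
  d_t <- d_t[keep]
  n_t <- rowSums(atrisk)
  pg <- atrisk / n_t
  O <- colSums(dmat)
  E <- colSums(dmat * 0 + d_t * pg)
  fvar <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  V <- matrix(0, k - 1, k - 1)
  for (a in seq_len(k - 1)) for (b in seq_len(k - 1)) {
    V[a, b] <- sum(fvar * (pg[, a] * ((a == b) - pg[, b])))
  }
  names(O) <- names(E) <- lv
  u <- (O - E)[-k]
  chisq <- tryCatch(drop(t(u) %*% solve(V, u)), error = function(e) 0)
  df <- k - 1
  list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(group = lv, n = as.vector(table(factor(group, levels = lv))),
                          observed = as.numeric(O), expected = as.numeric(E)))
}

# Efron partial log-likelihood, gradient and full Hessian for design matrix x.
cox_efron_lgh <- function(beta, x, time, event) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)
  r <- exp(eta)
  ord <- order(time)
  time_s <- time[ord]; event_s <- event[ord]; x_s <- x[ord, , drop = FALSE]
  r_s <- r[ord]; eta_s <- eta[ord]
  rx <- x_s * r_s
  # suffix sums over the risk set
  cr <- rev(cumsum(rev(r_s)))
  crx <- apply(rx, 2, function(v) rev(cumsum(rev(v))))
  crx <- matrix(crx, nrow = n)
  pair_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  rxx <- rx[, pair_idx[, 1], drop = FALSE] * x_s[, pair_idx[, 2], drop = FALSE]
  crxx <- apply(rxx, 2, function(v) rev(cumsum(rev(v))))
  crxx <- matrix(crxx, nrow = n)

  ll <- 0; grad <- rep(0, p); hess <- matrix(0, p, p)
  s <- 1
  while (s <= n) {
    e <- s
    while (e < n && time_s[e + 1] == time_s[s]) e <- e + 1
    ev <- which(event_s[s:e] == 1) + s - 1
    d <- length(ev)
    if (d > 0) {
      SR <- cr[s]; SRx <- crx[s, ]; SRxx <- crxx[s, ]
      SD <- sum(r_s[ev])
      SDx <- colSums(rx[ev, , drop = FALSE])
      SDxx <- colSums(rxx[ev, , drop = FALSE])
      ll <- ll + sum(eta_s[ev])
      grad <- grad + colSums(x_s[ev, , drop = FALSE])
      for (k in 0:(d - 1)) {
        f <- k / d
        denom <- SR - f * SD
        mu <- (SRx - f * SDx) / denom
        m2v <- (SRxx - f * SDxx) / denom
        m2 <- matrix(0, p, p)
        m2[cbind(pair_idx[, 1], pair_idx[, 2])] <- m2v
        m2[cbind(pair_idx[, 2], pair_idx[, 1])] <- m2v
        ll <- ll - log(denom)
        grad <- grad - mu
        hess <- hess + m2 - outer(mu, mu)
      }
    }
    s <- e + 1
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Cox proportional-hazards regression (Efron ties)
#'
#' Newton-Raphson maximization of the Efron-tie-corrected partial likelihood
#' with step-halving, Wald confidence intervals from the observed
#' information, and a monotone-likelihood (perfect separation) guard that
#' caps runaway coefficients at +/- `cap` with a warning.
#'
#' @param x Design matrix (no constant columns) or numeric vector.
#' @param time,event Survival outcome vectors.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Maximum Newton iterations.
#' @param cap Absolute coefficient bound used to flag separation.
#' @return List with `coef`, `se`, `hr`, `ci_low`, `ci_high`, `p_value`
#'   (Wald), `loglik`, `loglik_null`, `iter`, `converged`, `flagged`.
#' @export
cox_fit <- function(x, time, event, tol = 1e-9, max_iter = 50, cap = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(apply(x, 2, sd) == 0)) stop("constant column in the design matrix")
  if (sum(event) < 1) stop("at least one event is required")
  p <- ncol(x)
  beta <- rep(0, p)
  l0 <- cox_efron_lgh(beta, x, time, event)
  ll_old <- l0$loglik
  flagged <- FALSE; converged <- FALSE; iter <- 0
  for (iter in seq_len(max_iter)) {
    lgh <- cox_efron_lgh(beta, x, time, event)
    step <- tryCatch(solve(lgh$hess, lgh$grad), error = function(e) NULL)
    if (is.null(step)) { flagged <- TRUE; break }
    halve <- 0
    repeat {
      cand <- beta + step
      ll_new <- cox_efron_lgh(cand, x, time, event)$loglik
      if (ll_new >= lgh$loglik - 1e-12 || halve >= 20) break
      step <- step / 2
      halve <- halve + 1
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (any(abs(beta) > cap)) {
      flagged <- TRUE
      beta <- pmin(pmax(beta, -cap), cap)
      warning("monotone likelihood suspected; coefficient capped at |",
              cap, "|")
      break
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  fin <- cox_efron_lgh(beta, x, time, event)
  se <- sqrt(pmax(diag(tryCatch(solve(fin$hess), error = function(e)
    matrix(NA_real_, p, p))), 0))
  z <- beta / se
  list(coef = stats::setNames(beta, colnames(x)),
       se = stats::setNames(se, colnames(x)),
       hr = exp(beta), ci_low = exp(beta - 1.959964 * se),
       ci_high = exp(beta + 1.959964 * se),
       p_value = 2 * pnorm(-abs(z)),
       loglik = fin$loglik, loglik_null = l0$loglik,
       iter = iter, converged = converged, flagged = flagged)
}

#' Outcome-oriented optimal cutpoint for one feature
#'
#' Scans candidate thresholds at the midpoints between consecutive sorted
#' unique feature values inside the quantile bounds, computes the two-group
#' log-rank statistic at each split (high = feature above threshold), and
#' returns the threshold maximizing the statistic together with the Cox
#' hazard ratio of high vs low at that split. The reported p-value is the
#' unadjusted log-rank p at the selected threshold; because the threshold is
#' chosen to maximize the statistic, this p-value is anti-conservative under
#' the null.
#'
#' @param feature Per-patient numeric values.
#' @param time,event Survival outcome vectors.
#' @param bounds Quantile pair restricting candidate thresholds (default
#'   10th-90th percentile).
#' @param min_group_size Minimum patients required on each side of a split.
#' @param name Feature label carried into the result.
#' @return data.frame (one row): `feature`, `threshold`, `chisq`, `p_value`,
#'   `hr`, `ci_low`, `ci_high`, `n_high`, `n_low`.
#' @export
optimal_cutpoint <- function(feature, time, event, bounds = c(0.1, 0.9),
                             min_group_size = 5, name = "feature") {
  if (length(unique(feature)) < 2) stop("constant feature")
  uv <- sort(unique(feature))
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  qb <- quantile(feature, bounds, names = FALSE)
  mids <- mids[mids >= qb[1] & mids <= qb[2]]
  ok <- vapply(mids, function(thr) {
    nh <- sum(feature > thr)
    nh >= min_group_size && (length(feature) - nh) >= min_group_size
  }, logical(1))
  mids <- mids[ok]
  if (!length(mids))
    stop("no admissible threshold inside the bounds with min_group_size = ",
         min_group_size)
  stats <- vapply(mids, function(thr) {
    logrank_test(time, event, feature > thr)$chisq
  }, numeric(1))
  best <- which.max(stats)
  thr <- mids[best]
  high <- as.integer(feature > thr)
  lr <- logrank_test(time, event, high)
  cx <- suppressWarnings(cox_fit(matrix(high, ncol = 1,
                                        dimnames = list(NULL, "high")),
                                 time, event))
  data.frame(feature = name, threshold = thr, chisq = lr$chisq,
             p_value = lr$p_value, hr = cx$hr[1], ci_low = cx$ci_low[1],
             ci_high = cx$ci_high[1], n_high = sum(high),
             n_low = sum(high == 0), stringsAsFactors = FALSE)
}

#' Optimal-cutpoint forest over many features
#'
#' Applies [optimal_cutpoint()] to every column of a per-patient feature
#' matrix (typically cell-type proportions), skipping features for which no
#' admissible split exists, and returns the results sorted by hazard ratio
#' (descending) for forest-plot display.
#'
#' @param features Numeric matrix, patients x features.
#' @param time,event Survival outcome vectors (aligned with rows).
#' @param ... Passed to [optimal_cutpoint()].
#' @return data.frame of cutpoint results sorted by `hr`.
#' @export
cutpoint_forest <- function(features, time, event, ...) {
  rows <- lapply(colnames(features), function(f) {
    tryCatch(optimal_cutpoint(features[, f], time, event, name = f, ...),
             error = function(e) {
               warning("skipping feature '", f, "': ", conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no feature yielded an admissible cutpoint")
  out[order(-out$hr), , drop = FALSE]
}
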