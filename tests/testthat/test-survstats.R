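test_that("product-limit estimator matches hand tabulation", {
  # times 1, 2 (censored), 3 with events at 1 and 3
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$curve$survival, c(2/3, 2/3, 0))
  expect_equal(km$median, 3)
  # all censored: flat at 1, median not reached
  km2 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km2$curve$survival == 1))
  expect_false(km2$median_reached)
  expect_true(is.na(km2$median))
  # single patient with an event
  km3 <- km_estimate(5, 1)
  expect_equal(km3$curve$survival, 0)
  expect_equal(km3$median, 5)
  # S is non-increasing and starts from 1
  set.seed(2)
  tm <- sample(1:30, 40, TRUE); ev <- rbinom(40, 1, 0.5)
  km4 <- km_estimate(tm, ev)
  expect_true(all(diff(km4$curve$survival) <= 1e-12))
  expect_lte(km4$curve$survival[1], 1)
})

test_that("log-rank statistic equals the hand-computed risk-table value", {
  # groups {1, 2} and {10, 11}, all events: four risk tables by hand
  # t=1: O1=1, E1=2/4, V=(1*3*2*2)/(16*3)=0.25
  # t=2: O1=1, E1=1/3, V=(1*2*1*2)/(9*2)=2/9
  # t=10: O1=0, E1=0, V=0 ; t=11: O1=0, E1=0, V=0
  tm <- c(1, 2, 10, 11); ev <- rep(1, 4); g <- c("a", "a", "b", "b")
  lr <- logrank_test(tm, ev, g)
  oe <- (1 - 0.5) + (1 - 1/3)
  v <- 0.25 + 2/9
  expect_equal(lr$chisq, oe^2 / v, tolerance = 1e-12)
  # label swap invariance and identical-group null
  expect_equal(logrank_test(tm, ev, rev(g))$chisq, lr$chisq)
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_lt(lr0$chisq, 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-6)
  expect_error(logrank_test(tm, ev, rep("a", 4)), "two groups")
})

test_that("log-rank detects a threefold hazard with high power", {
  rejections <- vapply(1:10, function(r) {
    s <- simulate_survival(log(3) * rep(c(1, 0), each = 250), 1, 500, 1e9,
                           seed = 700 + r)
    logrank_test(s$time, s$event, rep(c(1, 0), each = 250))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("Cox regression matches the reference implementation and oracles", {
  skip_if_not_installed("survival")
  set.seed(11)
  # identical survival in both groups: coefficient 0
  tm <- rep(c(3, 5, 8, 9), 2); ev <- rep(c(1, 0, 1, 1), 2)
  x <- matrix(rep(c(0, 1), each = 4), ncol = 1, dimnames = list(NULL, "g"))
  cf0 <- cox_fit(x, tm, ev)
  expect_lt(abs(cf0$coef), 1e-6)
  # simulated hazard ratio 2 recovered at n = 2000
  s <- simulate_survival(log(2) * rep(c(1, 0), 1000), 1, 300, 600, seed = 3)
  xb <- matrix(rep(c(1, 0), 1000), ncol = 1, dimnames = list(NULL, "g"))
  cf2 <- cox_fit(xb, s$time, s$event)
  expect_true(cf2$hr[1] > 1.8 && cf2$hr[1] < 2.2)
  # random datasets against coxph (Efron ties)
  for (i in 1:10) {
    n <- sample(30:80, 1); p <- sample(1:3, 1)
    xm <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    tmr <- sample(1:25, n, TRUE); evr <- rbinom(n, 1, 0.7)
    if (sum(evr) < 2) next
    ours <- cox_fit(xm, tmr, evr)
    ref <- survival::coxph(survival::Surv(tmr, evr) ~ xm, ties = "efron")
    expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-5)
  }
})

test_that("tiny-sample Cox solutions maximize the partial likelihood", {
  set.seed(21)
  for (i in 1:5) {
    n <- 6
    x <- matrix(round(rnorm(n), 2), ncol = 1, dimnames = list(NULL, "v"))
    tm <- sample(1:100, n); ev <- c(1, 1, 1, rbinom(3, 1, 0.5))
    cf <- tryCatch(cox_fit(x, tm, ev), warning = function(w) NULL)
    if (is.null(cf) || !cf$converged) next
    expect_equal(unname(cf$coef), grid_cox(x, tm, ev), tolerance = 1e-4)
    # local maximality at +/- 1e-3
    ll <- function(b) cox_loglik(drop(x * b), tm, ev)
    expect_gte(cf$loglik, ll(cf$coef + 1e-3) - 1e-10)
    expect_gte(cf$loglik, ll(cf$coef - 1e-3) - 1e-10)
  }
})

test_that("separation is flagged and capped rather than diverging", {
  tm <- c(1, 2, 3, 10, 11, 12); ev <- rep(1, 6)
  x <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1, dimnames = list(NULL, "sep"))
  expect_warning(cf <- cox_fit(x, tm, ev), "monotone likelihood")
  expect_true(cf$flagged)
  expect_lte(abs(cf$coef), 15)
})

test_that("optimal cutpoint equals exhaustive search and is transform-invariant", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:5) {
    n <- 50
    f <- round(runif(n), 2)
    s <- simulate_survival(1.5 * (f > 0.5), 1, 300, 600, seed = 800 + i)
    res <- optimal_cutpoint(f, s$time, s$event)
    # independent exhaustive scan using the reference log-rank statistic
    uv <- sort(unique(f)); mids <- (uv[-1] + uv[-length(uv)]) / 2
    qb <- quantile(f, c(0.1, 0.9), names = FALSE)
    mids <- mids[mids >= qb[1] & mids <= qb[2]]
    mids <- mids[vapply(mids, function(th) min(sum(f > th), sum(f <= th)) >= 5,
                        logical(1))]
    stats <- vapply(mids, function(th)
      survival::survdiff(survival::Surv(s$time, s$event) ~ (f > th))$chisq,
      numeric(1))
    expect_equal(res$threshold, mids[which.max(stats)])
    expect_equal(res$chisq, max(stats), tolerance = 1e-8)
    # rank-preserving transform yields the identical patient partition
    res2 <- optimal_cutpoint(qlogis((f + 1) / 3), s$time, s$event)
    expect_equal(f > res$threshold, qlogis((f + 1) / 3) > res2$threshold)
  }
  expect_error(optimal_cutpoint(rep(1, 20), 1:20, rep(1, 20)), "constant")
})

test_that("a perfectly prognostic feature yields a high-risk split with HR > 1", {
  set.seed(41)
  n <- 60
  tm <- sort(sample(1:500, n)); ev <- rep(1, n)
  f <- rank(-tm)  # high feature value = early event
  res <- optimal_cutpoint(f, tm, ev)
  expect_gt(res$hr, 1)
  expect_lt(res$p_value, 1e-4)
})

test_that("null cutpoint selection is anti-conservative, as documented", {
  set.seed(51)
  rej <- vapply(1:200, function(r) {
    n <- 60
    f <- rnorm(n)
    s <- simulate_survival(rep(0, n), 1, 300, 600)
    optimal_cutpoint(f, s$time, s$event)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.08)  # well above the nominal 5%
})

test_that("the cutpoint forest ranks a planted step effect first", {
  set.seed(61)
  wins <- 0
  for (r in 1:5) {
    n <- 200
    feats <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("f", 1:5)))
    feats[, "f1"] <- round(runif(n), 2)
    s <- simulate_survival(log(3) * (feats[, "f1"] > 0.5), 1, 300, 1e9)
    fo <- suppressWarnings(cutpoint_forest(feats, s$time, s$event))
    if (fo$feature[1] == "f1") wins <- wins + 1
  }
  expect_gte(wins, 4)
  # single feature input gives a single row
  f1 <- matrix(round(runif(40), 2), ncol = 1, dimnames = list(NULL, "only"))
  s1 <- simulate_survival(rep(0, 40), 1, 100, 200, seed = 9)
  expect_equal(nrow(suppressWarnings(
    cutpoint_forest(f1, s1$time, s1$event))), 1)
})
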