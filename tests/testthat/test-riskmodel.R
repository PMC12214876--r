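test_that("feature construction counts, names and standardizes correctly", {
  props <- toy_features(20, 3)
  fm <- build_features(props)
  expect_equal(length(fm$features), 3 + 3)           # m + C(m, 2)
  expect_true(all(c("ct1::ct2", "ct1::ct3", "ct2::ct3") %in% fm$features))
  expect_equal(unname(fm$x_raw[, "ct1::ct2"]),
               unname(props[, "ct1"] * props[, "ct2"]))
  expect_equal(unname(colMeans(fm$x)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(fm$x, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # raw product example: 0.2 * 0.5 = 0.1
  pm <- matrix(c(0.2, 0.4, 0.3, 0.5, 0.3, 0.2, 0.3, 0.3, 0.5), 3,
               dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  fm2 <- build_features(pm)
  expect_equal(unname(fm2$x_raw["a", "x::y"]), 0.1)
  # combinatorial count at the study's scale: 38 mains
  big <- matrix(runif(40 * 38, 0.1, 1), 40, 38,
                dimnames = list(sprintf("P%02d", 1:40), paste0("m", 1:38)))
  fmb <- build_features(big)
  expect_equal(length(fmb$features), 38 + 38 * 37 / 2)
  # missing extras drop the patient with a warning
  extras <- data.frame(patient_id = rownames(props)[-1],
                       age = rnorm(19, 60, 8))
  expect_warning(fme <- build_features(props, extras), "missing extras")
  expect_equal(length(fme$patients), 19)
  expect_true("age::ct1" %in% fme$features)
})

test_that("leave-one-out ensemble scores out-of-fold without leakage", {
  rep1 <- planted_replicate(1)
  ens <- rep1$ensemble
  n <- length(rep1$fm$patients)
  expect_equal(length(ens$models), n)
  expect_equal(length(ens$oof_scores), n)
  expect_false(anyNA(ens$oof_scores))
  expect_true(all(ens$summary$n_positive + ens$summary$n_negative <=
                    ens$summary$n_models))
  # no-leakage: perturbing a held-out patient's outcome leaves that fold's
  # model bit-identical (fit on a small cohort for speed)
  props <- toy_features(15, 3, seed = 3)
  set.seed(3)
  s <- simulate_survival(rnorm(15), 1, 300, 600)
  outc <- data.frame(patient_id = rownames(props), time = s$time,
                     event = s$event)
  fm <- build_features(props)
  e1 <- loocv_ensemble(fm, outc, seed = 9)
  outc2 <- outc
  outc2$time[4] <- outc2$time[4] + 77
  outc2$event[4] <- 1 - outc2$event[4]
  e2 <- loocv_ensemble(fm, outc2, seed = 9)
  expect_identical(e1$models[[4]], e2$models[[4]])
})

test_that("model selection maximizes the training pseudo-R2", {
  rep1 <- planted_replicate(1)
  model <- select_model(rep1$ensemble, rep1$fm, rep1$outcomes)
  expect_true(all(model$r2 >= model$all_r2 - 1e-12))
  expect_equal(model$r2_definition,
               "Cox-Snell on the Efron partial likelihood")
  # an all-zero model has pseudo-R2 exactly 0
  zero <- rep1$ensemble$models[[1]]
  zero$coef[] <- 0
  expect_equal(immprog:::model_r2(zero, rep1$fm,
                                  rep1$outcomes$time, rep1$outcomes$event), 0)
})

test_that("scoring is linear, standardized, and shift-invariant", {
  props <- toy_features(12, 3, seed = 5)
  fm <- build_features(props)
  model <- structure(list(coef = stats::setNames(c(1, 0, 0, 0, 0, 0.5),
                                                 fm$features),
                          center = fm$center, scale = fm$scale,
                          features = fm$features, mains = fm$mains),
                     class = "risk_model")
  sc <- score_patients(model, fm)
  expect_equal(unname(sc), unname(fm$x[, 1] * 1 + fm$x[, 6] * 0.5))
  # zero model scores zero
  model0 <- model; model0$coef[] <- 0
  expect_true(all(score_patients(model0, fm) == 0))
  # adding a constant to a raw feature pre-standardization changes nothing
  raw2 <- fm$x_raw
  raw2[, "ct1"] <- raw2[, "ct1"] + 10
  model2 <- model
  model2$center["ct1"] <- model2$center["ct1"] + 10
  expect_equal(score_patients(model2, raw2), sc)
  expect_error(score_patients(model, fm$x_raw[, -1]), "feature names")
})

test_that("harmonization round-trips, sums many-to-one, imputes at the mean", {
  rep1 <- planted_replicate(1)
  model <- select_model(rep1$ensemble, rep1$fm, rep1$outcomes)
  # identity map round trip: training scores reproduced bit-identically
  idmap <- data.frame(source_label = model$mains, target_label = model$mains)
  h <- harmonize(rep1$fm$x_raw[, model$mains], idmap, model)
  expect_identical(score_patients(model, h),
                   score_patients(model, rep1$fm))
  # many-to-one conserves mapped proportion mass
  src <- rep1$fm$x_raw[, model$mains]
  split1 <- src[, 1] * 0.4; split2 <- src[, 1] * 0.6
  ext <- cbind(`sub a` = split1, `sub b` = split2, src[, -1])
  map2 <- data.frame(
    source_label = c("sub a", "sub b", colnames(src)[-1]),
    target_label = c(colnames(src)[1], colnames(src)[1], colnames(src)[-1]))
  h2 <- harmonize(ext, map2, model)
  expect_equal(unname(h2[, colnames(src)[1]]), unname(src[, 1]),
               tolerance = 1e-12)
  # a missing main covariate: its features contribute exactly 0 to scores
  ext3 <- src[, -1]
  map3 <- data.frame(source_label = colnames(src)[-1],
                     target_label = colnames(src)[-1])
  h3 <- suppressMessages(harmonize(ext3, map3, model))
  imputed <- attr(h3, "imputed")
  expect_true(colnames(src)[1] %in% imputed)
  z <- immprog:::standardize_with(h3[, model$features, drop = FALSE],
                                  model$center, model$scale)
  expect_true(all(z[, imputed] == 0))
  # target absent from the model errors; unmapped source warns
  badmap <- data.frame(source_label = "x", target_label = "not a type")
  expect_error(harmonize(ext3, badmap, model), "absent from the model")
  map4 <- rbind(map3, data.frame(source_label = "extra", target_label = NA))
  map4 <- map3
  ext4 <- cbind(ext3, stray = runif(nrow(ext3)))
  expect_warning(suppressMessages(harmonize(ext4, map3, model)), "unmapped")
})

test_that("stratification reproduces the expected group sizes", {
  set.seed(6)
  sc35 <- rnorm(35)
  s <- simulate_survival(sc35, 1, 300, 600)
  st <- stratify_and_test(sc35, s$time, s$event, "median")
  expect_equal(sort(c(st$n_high, st$n_low)), c(17, 18))
  sc20 <- rnorm(20)
  s2 <- simulate_survival(rep(0, 20), 1, 300, 600, seed = 2)
  st2 <- stratify_and_test(sc20, s2$time, s2$event, 0.8)
  expect_equal(st2$n_high, 4)
  expect_equal(st2$n_low, 16)
  expect_error(stratify_and_test(rep(1, 10), s2$time[1:10], s2$event[1:10]),
               "identical")
})

test_that("rank-sum hazard comparisons are exact for small samples", {
  expect_equal(hazard_group_test(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))$p_value, 1)
  ht <- hazard_group_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_true(ht$exact)
  expect_equal(ht$p_value,
               ranksum_enumerate(c(1, 2, 3), c(4, 5, 6)))
  expect_error(hazard_group_test(1:4, rep("a", 4)), "two groups")
  # simulated MRD-sustained group carries lower hazard scores
  rep1 <- planted_replicate(1)
  model <- select_model(rep1$ensemble, rep1$fm, rep1$outcomes)
  sc <- score_patients(model, rep1$fm)
  # label the lowest-risk third as sustained-MRD-like
  grp <- ifelse(rank(sc) <= length(sc) / 3, "sustained", "not")
  expect_lt(hazard_group_test(sc, grp)$p_value, 0.01)
})

test_that("cd56 ratio applies a pseudocount only for zero denominators", {
  props <- matrix(c(0.3, 0.2, 0.1, 0, 0.6, 0.8), 2,
                  dimnames = list(c("s1", "s2"),
                                  c("NK CD56bright", "NK CD56dim", "rest")))
  expect_message(r <- cd56_ratio(props), "pseudocount")
  expect_equal(unname(r["s1"]), 3)
  expect_true(is.finite(r["s2"]))
})
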