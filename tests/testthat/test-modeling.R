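sim_block_data <- function(n = 80, p = 10, n_signal = 3, delta = 1.5,
                           seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("low", "high"), length.out = n)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    X[y == "high", seq_len(n_signal)] <-
      X[y == "high", seq_len(n_signal)] + delta
    list(X = X, y = factor(y, c("low", "high")))
  })
}

test_that("standardization uses training parameters only and round-trips", {
  d <- sim_block_data(seed = 41)
  std <- standardize_features(d$X, d$X)
  expect_equal(unname(colMeans(std$train)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(std$train, 2, sd)), rep(1, 10), tolerance = 1e-12)
  expect_equal(std$train, std$apply)
  # validation transformed with training parameters, not its own
  Xv <- d$X[1:20, ] + 5
  stdv <- standardize_features(d$X, Xv)
  expect_equal(stdv$apply,
               sweep(sweep(Xv, 2, stdv$center), 2, stdv$scale, "/"))
  expect_gt(mean(colMeans(stdv$apply)), 1)   # not re-centered on itself
  # round-trip inverse
  back <- sweep(sweep(std$train, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, d$X, tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance handling
  Xz <- cbind(d$X, const = 1)
  expect_warning(stdz <- standardize_features(Xz), "zero-variance")
  expect_false("const" %in% colnames(stdz$train))
  expect_error(standardize_features(matrix(1, 5, 2)), "constant")
})

test_that("the LASSO path null threshold matches the analytic bound", {
  d <- sim_block_data(n = 60, seed = 42)
  std <- standardize_features(d$X)
  fit <- fit_lasso_cv(std$train, d$y, n_folds = 5, seed = 1)
  yv <- as.numeric(d$y == "high")
  lmax_analytic <- max(abs(crossprod(std$train, yv - mean(yv)))) / length(yv)
  expect_equal(max(fit$cv$lambda), lmax_analytic, tolerance = 1e-6)
  # at the top of the path every coefficient is zero
  b <- as.matrix(coef(fit$cv$glmnet.fit, s = max(fit$cv$lambda)))
  expect_true(all(b[-1, 1] == 0))
})

test_that("LASSO selects planted signal features and scores are linear", {
  d <- sim_block_data(n = 100, delta = 2, seed = 43)
  std <- standardize_features(d$X)
  fit <- fit_lasso_cv(std$train, d$y, seed = 2)
  expect_gt(length(intersect(fit$selected, c("f1", "f2", "f3"))), 0)
  sc <- lasso_score(std$train, fit)
  manual <- fit$intercept +
    std$train[, fit$selected, drop = FALSE] %*% fit$coef
  expect_equal(sc, drop(manual), tolerance = 1e-12)
  # single perfectly-correlated predictor: coefficient sign follows it
  X1 <- matrix(c(scale(as.numeric(d$y == "high"))), ncol = 1,
               dimnames = list(NULL, "only"))
  f1 <- fit_lasso_cv(X1, d$y, n_folds = 5, seed = 3)
  expect_gt(unname(f1$coef["only"]), 0)
  expect_error(fit_lasso_cv(std$train, rep("high", 100), seed = 1), "class")
  expect_error(lasso_score(std$train[, 1:2], fit), "Missing")
})

test_that("zero-coefficient LASSO gives a constant intercept score", {
  fake <- structure(list(intercept = 0.3, coef = numeric(0),
                         selected = character(0)), class = "lasso_fit")
  expect_equal(lasso_score(matrix(rnorm(20), 10, 2), fake), rep(0.3, 10))
})

test_that("random forest scoring is seeded and separates a separable toy", {
  d <- sim_block_data(n = 20, p = 2, n_signal = 1, delta = 6, seed = 44)
  rf1 <- fit_rf(d$X, d$y, n_trees = 100, seed = 5)
  rf2 <- fit_rf(d$X, d$y, n_trees = 100, seed = 5)
  expect_identical(rf_score(rf1), rf_score(rf2))
  expect_equal(auc(rf_score(rf1, d$X), d$y), 1)
  # pure-noise features: OOB AUC near 0.5 over seeds
  aucs <- vapply(1:8, function(s) {
    dn <- sim_block_data(n = 60, p = 4, n_signal = 0, seed = 100 + s)
    auc(rf_score(fit_rf(dn$X, dn$y, n_trees = 100, seed = s)), dn$y)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(fit_rf(d$X, rep("low", 20)), "class")
})

test_that("block SVM fuses scores, orients them, and handles degenerate input", {
  d <- sim_block_data(n = 60, seed = 45)
  s1 <- as.numeric(d$y == "high") + rnorm(60, 0, 0.1)
  s2 <- as.numeric(d$y == "high") + rnorm(60, 0, 0.1)
  sv <- fit_block_svm(cbind(a = s1, b = s2), d$y)
  out <- svm_fusion_score(sv, cbind(a = s1, b = s2))
  expect_equal(auc(out, d$y), 1)
  # permutation equivariance
  perm <- sample(60)
  expect_equal(svm_fusion_score(sv, cbind(a = s1, b = s2)[perm, ]),
               out[perm], tolerance = 1e-10)
  # informative + noise is not worse than noise alone, on average over seeds
  gain <- vapply(1:6, function(s) {
    withr::with_seed(s, {
      y <- rep(c("low", "high"), 40)
      info <- as.numeric(y == "high") * 1.5 + rnorm(80)
      noise <- rnorm(80)
      tr <- 1:60; va <- 61:80
      both <- fit_block_svm(cbind(i = info[tr], n = noise[tr]), y[tr])
      a_both <- auc(svm_fusion_score(both, cbind(i = info[va], n = noise[va])),
                    y[va])
      noise2 <- rnorm(80)
      only <- fit_block_svm(cbind(i = noise2[tr], n = noise[tr]), y[tr])
      a_noise <- auc(svm_fusion_score(only, cbind(i = noise2[va], n = noise[va])),
                     y[va])
      a_both - a_noise
    })
  }, numeric(1))
  expect_gt(mean(gain), 0)
  expect_error(fit_block_svm(cbind(rep(1, 10), rep(2, 10)),
                             rep(c("low", "high"), 5)), "Degenerate")
  # one constant column is dropped, the other carries the fit
  expect_warning(
    svc <- fit_block_svm(cbind(a = s1, b = rep(1, 60)), d$y), "constant")
  expect_equal(svc$cols, "a")
})

test_that("the stacked classifier runs the full recipe deterministically", {
  co <- generate_cohort(24, 12, small_params(), seed = 46)
  reg <- default_registry()
  tex <- extract_texture_features(co, reg)
  tra <- extract_traditional_features(co, seed = 46)
  y <- co$truth$grade
  m1 <- fit_stacked_classifier(tex, tra, y, stack_config(n_folds = 5),
                               seed = 9)
  m2 <- fit_stacked_classifier(tex, tra, y, stack_config(n_folds = 5),
                               seed = 9)
  expect_equal(m1$train_scores, m2$train_scores, tolerance = 1e-8)
  expect_equal(m1$threshold, m2$threshold)
  p1 <- predict(m1, tex, tra)
  p2 <- predict(m2, tex, tra)
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_named(p1, c("score1", "score2", "score3", "score4", "score5",
                     "score6", "score7", "call"))
  # threshold convention: call is high exactly when score7 >= threshold
  expect_identical(p1$call == "high", p1$score7 >= m1$threshold)
  # tidy/glance accessors
  td <- tidy(m1)
  expect_true(all(c("block", "term", "estimate") %in% names(td)))
  gl <- glance(m1)
  expect_equal(gl$n_train, 36)
  expect_true(gl$auc_svm3_train > 0.5)
})

test_that("fitting uses training rows only (no leakage) and modes differ", {
  co <- generate_cohort(20, 10, small_params(), seed = 47)
  reg <- default_registry()
  tex <- extract_texture_features(co, reg)
  tra <- extract_traditional_features(co, seed = 47)
  y <- co$truth$grade
  # hold out 5 low-grade and 3 high-grade patients
  tr <- c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 7), rep(FALSE, 3))
  cfg <- stack_config(n_folds = 5)
  m <- fit_stacked_classifier(tex[tr, ], tra[tr, ], y[tr], cfg, seed = 3)
  # validation features and labels never touch the fit: predictions on
  # validation rows are unchanged whatever happens to their labels
  pv <- predict(m, tex[!tr, ], tra[!tr, ])
  m_again <- fit_stacked_classifier(tex[tr, ], tra[tr, ], y[tr], cfg, seed = 3)
  expect_equal(predict(m_again, tex[!tr, ], tra[!tr, ]), pv, tolerance = 1e-10)
  # naive stacking is a distinct, runnable mode
  mn <- fit_stacked_classifier(tex[tr, ], tra[tr, ], y[tr],
                               stack_config(n_folds = 5,
                                            naive_stacking = TRUE), seed = 3)
  expect_false(isTRUE(all.equal(m$train_scores$score3,
                                mn$train_scores$score3)))
  pn <- predict(mn, tex[!tr, ], tra[!tr, ])
  expect_true(all(is.finite(pn$score7)))
})

test_that("raising a patient's final score never flips a high call to low", {
  co <- generate_cohort(16, 8, small_params(), seed = 48)
  tex <- extract_texture_features(co)
  tra <- extract_traditional_features(co, seed = 48)
  m <- fit_stacked_classifier(tex, tra, co$truth$grade,
                              stack_config(n_folds = 4), seed = 2)
  p <- predict(m, tex, tra)
  calls <- ifelse(p$score7 + 1 >= m$threshold, "high", "low")
  expect_true(all(calls[p$call == "high"] == "high"))
})
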