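test_that("AUC matches enumeration examples and the pairwise oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)  # tie convention
  set.seed(51)
  for (rep in 1:120) {
    n <- sample(6:20, 1)
    y <- factor(sample(c("low", "high"), n, TRUE), c("low", "high"))
    if (nlevels(droplevels(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # discrete scores force ties
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(auc(1:4, rep(1, 4)), "Both classes")
})

test_that("ROC points form a valid staircase invariant to monotone transforms", {
  set.seed(52)
  s <- rnorm(40)
  y <- rep(c("low", "high"), 20)
  r <- roc_points(s, y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  r2 <- roc_points(exp(3 * s), y)           # strictly monotone transform
  expect_equal(r$fpr, r2$fpr)
  expect_equal(r$tpr, r2$tpr)
  expect_equal(attr(r, "auc"), attr(r2, "auc"))
})

test_that("AUC confidence intervals are seeded and behave sanely", {
  set.seed(53)
  y <- rep(c("low", "high"), c(150, 50))
  s <- c(rnorm(150), rnorm(50, 3))          # well separated
  ci <- auc_ci(s, y, B = 300, seed = 4)
  expect_equal(unname(ci["hi"]), 1, tolerance = 0.01)
  expect_identical(auc_ci(s, y, B = 300, seed = 4), ci)
  # width shrinks with n
  y2 <- rep(y, 4); s2 <- rep(s, 4) + rnorm(800, 0, 1e-6)
  ci2 <- auc_ci(s2, y2, B = 300, seed = 4)
  expect_lt(diff(ci2), diff(ci) + 1e-9)
  # DeLong interval brackets the point estimate
  cd <- auc_ci(s, y, method = "delong")
  a <- attr(cd, "auc")
  expect_true(cd["lo"] <= a && a <= cd["hi"])
  expect_error(auc_ci(s, y, B = 50), "at least 100")
})

test_that("Youden threshold follows the >= convention with low-tie break", {
  expect_equal(youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1)), 3)
  # perfect classifier at its optimal threshold
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(0, 0, 1, 1)
  thr <- youden_threshold(s, y)
  cm <- confusion_metrics(s, y, thr, B = 0)
  get <- function(m) cm$value[cm$metric == m]
  expect_equal(get("sensitivity"), 1)
  expect_equal(get("specificity"), 1)
  expect_equal(get("accuracy"), 1)
  expect_equal(get("fnr"), 0)
  expect_equal(get("fpr"), 0)
})

test_that("confusion metrics reproduce the printed 2x2 arithmetic", {
  # TP=36, FN=5, TN=66, FP=6 at threshold 0.5
  scores <- c(rep(0.9, 36), rep(0.1, 5), rep(0.2, 66), rep(0.8, 6))
  labels <- rep(c("high", "high", "low", "low"), c(36, 5, 66, 6))
  cm <- confusion_metrics(scores, labels, 0.5, B = 200, seed = 1)
  get <- function(m) cm$value[cm$metric == m]
  expect_equal(get("sensitivity"), 36 / 41, tolerance = 1e-12)  # 0.878049
  expect_equal(get("specificity"), 66 / 72, tolerance = 1e-12)  # 0.916667
  expect_equal(get("accuracy"), 102 / 113, tolerance = 1e-12)
  expect_equal(get("fnr"), 5 / 41, tolerance = 1e-12)
  expect_equal(get("fpr"), 6 / 72, tolerance = 1e-12)
  # whole-cohort denominator variants
  expect_equal(get("fnr_cohort"), 5 / 113, tolerance = 1e-12)
  expect_equal(get("fpr_cohort"), 6 / 113, tolerance = 1e-12)
  expect_true(all(cm$lo <= cm$value & cm$value <= cm$hi))
})

test_that("group comparison dispatches chi-square, t and Wilcoxon correctly", {
  # printed gender counts: low 140 M / 66 F, high 43 M / 15 F -> p ~ 0.368
  tab <- tibble::tibble(
    grade = rep(c("low", "high"), c(206, 58)),
    gender = c(rep(c("male", "female"), c(140, 66)),
               rep(c("male", "female"), c(43, 15))))
  res <- compare_groups(tab, "grade")
  expect_equal(res$test, "chi-square")
  expect_lt(abs(res$p_value - 0.368), 0.001)
  # identical proportions: p = 1
  tab2 <- tibble::tibble(g = rep(c("a", "b"), c(30, 15)),
                         x = c(rep(c("m", "f"), c(20, 10)),
                               rep(c("m", "f"), c(10, 5))))
  expect_equal(compare_groups(tab2, "g")$p_value, 1)
  # continuous dispatch
  d <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                      nrm = rnorm(40), skw = rexp(40))
  r <- compare_groups(d, "g", normal_vars = "nrm")
  expect_equal(r$test[r$variable == "nrm"], "t")
  expect_equal(r$test[r$variable == "skw"], "wilcoxon")
})

test_that("Wilcoxon p-values match hand-built oracles", {
  # exact enumeration on the untied example
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), x = c(1, 2, 3, 4, 5, 6))
  p_exact <- compare_groups(d, "g", exact = TRUE)$p_value
  expect_equal(p_exact, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(p_exact, 0.1)
  # normal approximation with tie correction, random instances
  set.seed(54)
  for (rep in 1:120) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    x <- sample.int(6, n1, TRUE); y <- sample.int(6, n2, TRUE)
    if (length(unique(c(x, y))) < 2) next
    d <- tibble::tibble(g = rep(c("a", "b"), c(n1, n2)), v = c(x, y))
    expect_equal(compare_groups(d, "g")$p_value, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("correlation matrix is symmetric with flagged degenerate features", {
  set.seed(55)
  df <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  df$c <- -df$a
  cm <- correlation_matrix(df)
  expect_equal(unname(diag(unclass(cm))), rep(1, 3))
  expect_equal(cm["a", "c"], -1)
  expect_equal(attr(cm, "abs")["a", "c"], 1)
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  # brute-force Spearman oracle on a small table
  df2 <- tibble::tibble(w = c(3, 1, 4, 1, 5), x = c(2, 7, 1, 8, 2),
                        y = c(1, 2, 3, 4, 5), z = c(2, 1, 3, 5, 4))
  cm2 <- correlation_matrix(df2)
  for (i in 1:3) for (j in (i + 1):4) {
    r_oracle <- cor(rank(df2[[i]]), rank(df2[[j]]))   # Spearman = Pearson on ranks
    expect_equal(unclass(cm2)[i, j], r_oracle, tolerance = 1e-12)
  }
  dfz <- tibble::tibble(a = rnorm(10), z = rep(1, 10))
  cmz <- correlation_matrix(dfz)
  expect_equal(cmz["a", "z"], 0)
  expect_equal(attr(cmz, "flagged"), "z")
  expect_error(correlation_matrix(tibble::tibble(a = 1:10)), "at least 2")
})

test_that("AUC and DeLong agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(56)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    y <- rep(c("low", "high"), length.out = n)
    s <- round(rnorm(n, ifelse(y == "high", 1, 0)), 1)
    ref <- suppressMessages(pROC::roc(y, s, levels = c("low", "high"),
                                      direction = "<"))
    expect_equal(auc(s, y), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
  y <- rep(c("low", "high"), c(60, 40))
  s <- rnorm(100, ifelse(y == "high", 1, 0))
  ref <- suppressMessages(pROC::roc(y, s, levels = c("low", "high"),
                                    direction = "<"))
  ci_ref <- suppressMessages(as.numeric(pROC::ci.auc(ref, method = "delong")))
  ci <- auc_ci(s, y, method = "delong")
  expect_equal(unname(ci[["lo"]]), ci_ref[1], tolerance = 1e-6)
  expect_equal(unname(ci[["hi"]]), ci_ref[3], tolerance = 1e-6)
})

test_that("plot methods return ggplot objects", {
  s <- rnorm(30); y <- rep(c("low", "high"), 15)
  expect_s3_class(ggplot2::autoplot(roc_points(s, y)), "ggplot")
  df <- tibble::tibble(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_s3_class(ggplot2::autoplot(correlation_matrix(df)), "ggplot")
  ph <- generate_phantom("high", small_params(), seed = 1)
  expect_s3_class(ggplot2::autoplot(ph), "ggplot")
})
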