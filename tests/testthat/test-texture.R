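test_that("histogram features match hand arithmetic and the rank oracle", {
  d <- make_di(matrix(1:4, 1, 4), n_bins = 4)
  h <- histogram_features(d)
  expect_equal(unname(h["Mean"]), 2.5)
  expect_equal(unname(h["Variance"]), 1.25)   # population variance
  dc <- make_di(matrix(3L, 4, 4), n_bins = 8)
  hc <- histogram_features(dc)
  expect_equal(unname(hc[c("Variance", "Skewness", "Kurtosis")]), c(0, 0, 0))
  du <- make_di(matrix(1:100, 10, 10), n_bins = 100)
  hu <- histogram_features(du)
  expect_equal(unname(hu["Perc_01"]), 1)
  expect_equal(unname(hu["Perc_99"]), 99)     # nearest-rank
})

test_that("gradient features match closed forms", {
  dc <- make_di(matrix(7L, 6, 6), n_bins = 8)
  g <- gradient_features(dc)
  expect_equal(unname(g["GrMean"]), 0)
  expect_equal(unname(g["GrNonZeros"]), 0)
  ramp <- make_di(matrix(rep(1:8, each = 8), 8, 8, byrow = TRUE), n_bins = 8)
  gr <- gradient_features(ramp)
  expect_equal(unname(gr["GrMean"]), 1)       # central difference of a ramp
  expect_equal(unname(gr["GrVariance"]), 0)
  expect_equal(unname(gr["GrNonZeros"]), 1)
  expect_error(gradient_features(make_di(matrix(1L, 1, 5), 2)), "interior")
})

test_that("co-occurrence matrix matches the hand-enumerated example", {
  d <- make_di(matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 2, 3), n_bins = 2)
  # rows [1,1,2],[1,2,2]: 4 ordered pairs at 0 deg distance 1, symmetric
  m <- glcm_compute(d, 0, 1)
  expect_equal(unclass(m), matrix(0.25, 2, 2), ignore_attr = TRUE)
  f <- glcm_features(m)
  expect_equal(unname(f["AngScMom"]), 0.25)
  expect_equal(unname(f["Contrast"]), 0.5)
  expect_equal(unname(f["Entropy"]), 2.0)

  dsingle <- make_di(matrix(2L, 3, 3), n_bins = 3)
  ms <- glcm_compute(dsingle, 90, 1)
  expect_equal(sum(ms), 1)
  expect_equal(ms[2, 2], 1)
  fs <- glcm_features(ms)
  expect_equal(unname(fs[c("AngScMom", "Contrast", "Entropy")]), c(1, 0, 0))

  expect_error(glcm_features(matrix(c(1, 1, 1, 1), 2)), "not normalized")
})

test_that("co-occurrence computation and features match brute-force oracles", {
  set.seed(42)
  for (rep in 1:120) {
    d <- random_di(sample(3:8, 1), sample(3:8, 1), n_bins = sample(2:6, 1))
    ang <- sample(c(0, 45, 90, 135), 1)
    dst <- sample(1:2, 1)
    m <- glcm_compute(d, ang, dst)
    om <- oracle_glcm(d, ang, dst)
    if (is.null(om)) {
      expect_null(m)
      next
    }
    expect_equal(unclass(m), om, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)  # symmetry
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_equal(glcm_features(m), oracle_glcm_features(om), tolerance = 1e-12)
  }
})

test_that("direction averaging is the arithmetic mean with sentinel handling", {
  f <- setNames(as.numeric(1:11), glcm_feature_names)
  expect_equal(glcm_direction_average(list(f, f, f, f)), f)
  f2 <- f + 1
  avg <- glcm_direction_average(list(f, f2, f, f2))
  expect_equal(unname(avg["AngScMom"]), 1.5)
  expect_equal(glcm_direction_average(list(f, NULL, f, NULL)), f)
  expect_null(glcm_direction_average(list(NULL, NULL)))
})

test_that("run-length features match the hand example and closed forms", {
  d <- make_di(matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 1, 6), n_bins = 3)
  m <- glrlm_compute(d, 0)
  expect_equal(attr(m, "n_runs"), 3)
  f <- glrlm_features(m)
  expect_equal(unname(f["ShrtREmp"]), (1 / 9 + 1 / 4 + 1) / 3, tolerance = 1e-12)
  expect_equal(unname(f["Fraction"]), 0.5)
  expect_equal(unname(f["GLevNonUni"]), 1.0)

  n <- 7
  dc <- make_di(matrix(2L, 1, n), n_bins = 2)
  fc <- glrlm_features(glrlm_compute(dc, 0))
  expect_equal(unname(fc["LngREmph"]), n^2)
  expect_equal(unname(fc["Fraction"]), 1 / n)
})

test_that("run-length features match a brute-force scanning oracle", {
  set.seed(7)
  for (rep in 1:120) {
    d <- random_di(sample(3:8, 1), sample(3:8, 1), n_bins = sample(2:5, 1))
    ang <- sample(c(0, 45, 90, 135), 1)
    f <- glrlm_features(glrlm_compute(d, ang))
    expect_equal(f, oracle_glrlm_features(d, ang), tolerance = 1e-12)
  }
})

test_that("run-length pixel conservation holds", {
  set.seed(8)
  for (rep in 1:25) {
    d <- random_di(7, 7, n_bins = 4)
    for (ang in c(0, 45, 90, 135)) {
      m <- glrlm_compute(d, ang)
      lens <- seq_len(ncol(m))
      expect_equal(sum(t(m) * lens), sum(d$mask))
    }
  }
})

test_that("autoregressive parameters are recovered from noise-free fields", {
  # field built by the exact causal recursion; theta sums to 1 so the
  # mean-centered design satisfies the same recursion exactly
  theta <- c(0.4, 0.45, -0.05, 0.2)
  set.seed(10)
  n <- 40
  L <- matrix(0, n, n)
  L[1, ] <- rnorm(n); L[, 1] <- rnorm(n); L[, n] <- rnorm(n)
  for (i in 2:n) for (j in 2:(n - 1)) {
    L[i, j] <- theta[1] * L[i - 1, j] + theta[2] * L[i, j - 1] +
      theta[3] * L[i - 1, j - 1] + theta[4] * L[i - 1, j + 1]
  }
  d <- make_di(L, n_bins = 256)
  f <- ar_features(d)
  expect_equal(unname(f[1:4]), theta, tolerance = 1e-6)
  expect_lt(unname(f["Sigma"]), 1e-8)
})

test_that("white noise yields near-zero AR coefficients and Sigma near the SD", {
  set.seed(11)
  L <- matrix(rnorm(100 * 100, 0, 2), 100, 100)
  f <- ar_features(make_di(L, 256))
  expect_lt(max(abs(f[1:4])), 0.05)
  s <- sd(L) * sqrt((length(L) - 1) / length(L))
  expect_equal(unname(f["Sigma"]), s, tolerance = 0.05)
})

test_that("constant images fall back to the ridge AR solution", {
  f <- ar_features(make_di(matrix(5L, 10, 10), 8))
  expect_equal(unname(f[1:4]), rep(0, 4))
  expect_equal(unname(f["Sigma"]), 0)
  expect_error(ar_features(make_di(matrix(1L, 2, 2), 2)), "Too few")
})

test_that("wavelet energies follow the scaling law and match the Haar oracle", {
  d1 <- make_di(matrix(1, 4, 4), 4)
  d2 <- make_di(matrix(2, 4, 4), 4)
  w1 <- wavelet_features(d1)
  w2 <- wavelet_features(d2)
  detail <- grep("LH|HL|HH", names(w1))
  expect_true(all(w1[detail] == 0))
  ll <- grep("WavEnLL", names(w1))
  expect_equal(unname(w2[ll] / w1[ll]), rep(4, 6))

  set.seed(12)
  M <- matrix(rnorm(64), 8, 8)
  w <- wavelet_features(make_di(M, 256), n_scales = 3)
  # oracle on the same mean-padded 64x64 patch the implementation analyzes
  side <- 64
  P <- matrix(mean(M), side, side)
  P[1:8, 1:8] <- M
  expect_equal(as.numeric(w), as.numeric(oracle_haar_energies(P, 3)),
               tolerance = 1e-10)
  expect_error(wavelet_features(make_di(matrix(1, 1, 5), 2)), "bounding box")
})

test_that("wavelet oracle equivalence holds across random patches", {
  set.seed(13)
  for (rep in 1:100) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    L <- matrix(sample.int(16, nr * nc, TRUE), nr, nc)
    L[sample(length(L), round(length(L) * 0.1))] <- NA
    if (all(is.na(L))) L[1, 1] <- 1L
    d <- make_di(L, 16)
    idx <- which(d$mask, arr.ind = TRUE)
    if (diff(range(idx[, 1])) < 1 || diff(range(idx[, 2])) < 1) next
    w <- wavelet_features(d, n_scales = 2)
    mu <- mean(L[d$mask])
    rr <- range(idx[, 1]); cr <- range(idx[, 2])
    patch <- L[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    patch[is.na(patch)] <- mu
    P <- matrix(mu, 64, 64)
    P[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
    expect_equal(as.numeric(w), as.numeric(oracle_haar_energies(P, 2)),
                 tolerance = 1e-10)
  }
})

test_that("histogram and gradient match oracles on random masked images", {
  set.seed(14)
  n_grad <- 0
  for (rep in 1:120) {
    d <- random_di(sample(4:9, 1), sample(4:9, 1), n_bins = sample(3:8, 1))
    expect_equal(histogram_features(d), oracle_histogram(d), tolerance = 1e-12)
    og <- oracle_gradient(d)
    if (!is.null(og)) {
      n_grad <- n_grad + 1
      expect_equal(gradient_features(d), og, tolerance = 1e-12)
    }
  }
  expect_gte(n_grad, 50)
})
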