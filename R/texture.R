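# Six MaZda-style texture feature families computed on the discretized
# in-mask gray levels. Conventions (documented in the methods vignette):
# population moments, log2 entropies with 0*log0 = 0, symmetric GLCM
# accumulation, 1-based levels, image-coordinate directions
# (0 deg = +col, 90 deg = +row, 45/135 deg diagonals).

in_mask_levels <- function(d) d$levels[d$mask]

pop_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    c(mean = m, var = 0, skew = 0, kurt = 0)  # degenerate convention
  } else {
    c(mean = m, var = v,
      skew = mean((x - m)^3) / v^1.5,
      kurt = mean((x - m)^4) / v^2 - 3)
  }
}

nearest_rank <- function(sorted_x, p) {
  n <- length(sorted_x)
  sorted_x[pmax(1L, ceiling(p * n))]
}

#' Gray-level histogram features
#'
#' First-order statistics of the in-mask discretized levels: population mean,
#' variance, skewness, excess kurtosis, and nearest-rank percentiles 1, 10,
#' 25, 50, 75, 90, 99.
#'
#' @param d A [normalize_gray_levels()] object.
#' @return Named numeric vector of 11 values.
#' @export
histogram_features <- function(d) {
  x <- in_mask_levels(d)
  if (length(x) == 0) abort("Empty mask.")
  mo <- pop_moments(x)
  xs <- sort(x)
  pc <- nearest_rank(xs, c(0.01, 0.10, 0.25, 0.50, 0.75, 0.90, 0.99))
  c(Mean = unname(mo["mean"]), Variance = unname(mo["var"]),
    Skewness = unname(mo["skew"]), Kurtosis = unname(mo["kurt"]),
    Perc_01 = pc[1], Perc_10 = pc[2], Perc_25 = pc[3], Perc_50 = pc[4],
    Perc_75 = pc[5], Perc_90 = pc[6], Perc_99 = pc[7])
}

#' Gradient features
#'
#' Absolute gradient magnitude `sqrt(gx^2 + gy^2)` by central differences,
#' evaluated at in-mask pixels whose four 4-neighbors are in-mask. Returns
#' population moments of the magnitude plus the fraction of interior pixels
#' with nonzero gradient.
#'
#' @param d A [normalize_gray_levels()] object.
#' @return Named numeric vector: GrMean, GrVariance, GrSkewness, GrKurtosis,
#'   GrNonZeros.
#' @export
gradient_features <- function(d) {
  L <- d$levels; m <- d$mask
  interior <- m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
  if (!any(interior)) abort("Mask has no interior pixels.")
  gx <- (shift_mat(L, 0, -1) - shift_mat(L, 0, 1)) / 2  # d/dcol
  gy <- (shift_mat(L, -1, 0) - shift_mat(L, 1, 0)) / 2  # d/drow
  mag <- sqrt(gx[interior]^2 + gy[interior]^2)
  mo <- pop_moments(mag)
  c(GrMean = unname(mo["mean"]), GrVariance = unname(mo["var"]),
    GrSkewness = unname(mo["skew"]), GrKurtosis = unname(mo["kurt"]),
    GrNonZeros = mean(mag > 0))
}

glcm_offset <- function(direction, distance) {
  d <- as.integer(distance)
  switch(as.character(direction),
    "0"   = c(0L, d),
    "45"  = c(d, d),
    "90"  = c(d, 0L),
    "135" = c(d, -d),
    abort("`direction` must be one of 0, 45, 90, 135 (degrees).")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered in-mask level pairs at the given displacement, accumulated
#' symmetrically (each pair and its reverse), normalized to sum 1.
#'
#' @param d A [normalize_gray_levels()] object.
#' @param direction One of 0, 45, 90, 135 (degrees; 0 = +col, 90 = +row).
#' @param distance Displacement length in pixels (1..5 by default registry).
#' @return `Ng x Ng` probability matrix of class `glc_matrix` with attribute
#'   `n_pairs`, or `NULL` if no valid pixel pair exists at this displacement.
#' @export
glcm_compute <- function(d, direction = 0, distance = 1L) {
  off <- glcm_offset(direction, distance)
  ng <- d$n_bins
  L <- d$levels
  A <- L
  B <- shift_mat(L, -off[1], -off[2], fill = NA_integer_)  # neighbor at +off
  ok <- !is.na(A) & !is.na(B)
  if (!any(ok)) return(NULL)
  a <- A[ok]; b <- B[ok]
  cnt <- tabulate((b - 1L) * ng + a, ng * ng) +
    tabulate((a - 1L) * ng + b, ng * ng)
  P <- matrix(cnt / sum(cnt), ng, ng)   # column-major: P[i, j]
  structure(P, class = c("glc_matrix", "matrix"), n_pairs = sum(ok))
}

glcm_feature_names <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs",
                        "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                        "Entropy", "DifVarnc", "DifEntrp")

#' Co-occurrence (Haralick) features
#'
#' The standard 11-feature Haralick subset: angular second moment, contrast,
#' correlation, sum of squares (variance), inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy. Entropies are in log2 with `0*log(0) = 0`; correlation
#' is defined as 0 when a marginal variance vanishes.
#'
#' @param m A normalized co-occurrence matrix ([glcm_compute()]).
#' @return Named numeric vector of 11 values.
#' @export
glcm_features <- function(m) {
  if (is.null(m)) abort("NULL co-occurrence matrix.")
  p <- as.numeric(m)              # column-major: index i + (j-1)*ng
  if (abs(sum(p) - 1) > 1e-8) abort("Co-occurrence matrix is not normalized.")
  ng <- nrow(m)
  nz <- which(p > 0)
  pn <- p[nz]
  iv <- (nz - 1L) %% ng + 1L
  jv <- (nz - 1L) %/% ng + 1L

  mux <- sum(iv * pn); muy <- sum(jv * pn)
  vx <- sum((iv - mux)^2 * pn); vy <- sum((jv - muy)^2 * pn)
  correlat <- if (vx == 0 || vy == 0) 0 else
    (sum(iv * jv * pn) - mux * muy) / sqrt(vx * vy)

  k <- iv + jv
  ps <- rowsum(pn, k)[, 1]
  sum_avg <- sum(k * pn)
  dk <- abs(iv - jv)
  pd <- rowsum(pn, dk)[, 1]
  dif_avg <- sum(dk * pn)

  c(AngScMom = sum(pn^2),
    Contrast = sum((iv - jv)^2 * pn),
    Correlat = correlat,
    SumOfSqs = vx,
    InvDfMom = sum(pn / (1 + (iv - jv)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((k - sum_avg)^2 * pn),
    SumEntrp = -sum(ps * log2(ps)),
    Entropy = -sum(pn * log2(pn)),
    DifVarnc = sum((dk - dif_avg)^2 * pn),
    DifEntrp = -sum(pd * log2(pd)))
}

#' Average co-occurrence features over the four directions
#'
#' @param feature_list List of 4 named vectors from [glcm_features()] (one
#'   per direction at a fixed distance). `NULL` entries (no valid pair) are
#'   dropped; if all are `NULL` the result is `NULL`.
#' @return Named numeric vector of 11 direction-averaged values.
#' @export
glcm_direction_average <- function(feature_list) {
  feature_list <- feature_list[!vapply(feature_list, is.null, logical(1))]
  if (length(feature_list) == 0) return(NULL)
  Reduce(`+`, feature_list) / length(feature_list)
}

# All maximal runs of equal level along in-mask collinear segments for one
# direction. Returns a list of integer vectors: levels and lengths.
glrlm_runs <- function(d, direction) {
  L <- d$levels
  L[is.na(L)] <- 0L    # run breaker
  nr <- nrow(L); nc <- ncol(L)
  lines <- switch(as.character(direction),
    "0"   = lapply(seq_len(nr), function(i) L[i, ]),
    "90"  = lapply(seq_len(nc), function(j) L[, j]),
    "45"  = {idx <- row(L) - col(L); split(L[order(idx, col(L))], sort(idx))},
    "135" = {idx <- row(L) + col(L); split(L[order(idx, col(L))], sort(idx))},
    abort("`direction` must be one of 0, 45, 90, 135 (degrees).")
  )
  levels <- integer(0); lengths <- integer(0)
  for (v in lines) {
    r <- rle(as.integer(v))
    keep <- r$values > 0L
    levels <- c(levels, r$values[keep])
    lengths <- c(lengths, r$lengths[keep])
  }
  list(levels = levels, lengths = lengths)
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal level along in-mask collinear segments in one
#' direction (the mask boundary breaks a run).
#'
#' @inheritParams glcm_compute
#' @return `Ng x Lmax` integer matrix of run counts, class `glrl_matrix`,
#'   with attributes `n_runs` and `n_pixels` (in-mask pixel count).
#' @export
glrlm_compute <- function(d, direction = 0) {
  runs <- glrlm_runs(d, direction)
  if (length(runs$levels) == 0) abort("Empty mask.")
  lmax <- max(runs$lengths)
  m <- matrix(0L, d$n_bins, lmax)
  for (k in seq_along(runs$levels)) {
    m[runs$levels[k], runs$lengths[k]] <- m[runs$levels[k], runs$lengths[k]] + 1L
  }
  structure(m, class = c("glrl_matrix", "matrix"),
            n_runs = length(runs$levels), n_pixels = sum(d$mask))
}

#' Run-length features
#'
#' Short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity and fraction of image in runs:
#' `SRE = (1/Nr) sum r(g,l)/l^2`, `LRE = (1/Nr) sum r(g,l) l^2`,
#' `GLN = (1/Nr) sum_g (sum_l r)^2`, `RLN = (1/Nr) sum_l (sum_g r)^2`,
#' `Fraction = Nr/Np`.
#'
#' @param m A [glrlm_compute()] matrix.
#' @return Named numeric vector: ShrtREmp, LngREmph, GLevNonUni, RLNonUni,
#'   Fraction.
#' @export
glrlm_features <- function(m) {
  n_runs <- attr(m, "n_runs")
  n_px <- attr(m, "n_pixels")
  lens <- seq_len(ncol(m))
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  c(ShrtREmp = sum(t(m) / lens^2) / n_runs,
    LngREmph = sum(t(m) * lens^2) / n_runs,
    GLevNonUni = sum(row_tot^2) / n_runs,
    RLNonUni = sum(col_tot^2) / n_runs,
    Fraction = n_runs / n_px)
}

#' Autoregressive model features
#'
#' Least-squares fit of the mean-centered level at `(i, j)` on its four
#' causal neighbors `(i-1, j)`, `(i, j-1)`, `(i-1, j-1)`, `(i-1, j+1)` (no
#' intercept), over in-mask pixels whose neighbors are all in-mask. `Sigma`
#' is the residual SD (root mean squared residual). A rank-deficient design
#' falls back to a tiny-ridge solution (regularizer `1e-8` on the scaled
#' normal equations).
#'
#' @param d A [normalize_gray_levels()] object.
#' @param min_pixels Minimum number of valid pixels (default 20).
#' @return Named numeric vector: Teta1..Teta4, Sigma.
#' @export
ar_features <- function(d, min_pixels = 20L) {
  L <- d$levels; m <- d$mask
  mu <- mean(L[m])
  X0 <- L - mu
  nb <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))   # (i-1,j),(i,j-1),(i-1,j-1),(i-1,j+1)
  ok <- m
  cols <- vector("list", 4)
  for (k in 1:4) {
    ok <- ok & shift_mat(m, nb[[k]][1], nb[[k]][2])
  }
  if (sum(ok) < min_pixels)
    abort(sprintf("Too few valid pixels for the AR fit (%d < %d).", sum(ok), min_pixels))
  for (k in 1:4) cols[[k]] <- shift_mat(X0, nb[[k]][1], nb[[k]][2])[ok]
  X <- do.call(cbind, cols)
  y <- X0[ok]
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  theta <- tryCatch({
    if (rcond_sym(XtX) < 1e-10) stop("near-singular")
    solve(XtX, Xty)
  }, error = function(e) {
    lambda <- 1e-8 * max(1, mean(diag(XtX)))
    solve(XtX + diag(lambda, 4), Xty)
  })
  res <- y - X %*% theta
  c(Teta1 = theta[1], Teta2 = theta[2], Teta3 = theta[3], Teta4 = theta[4],
    Sigma = sqrt(mean(res^2)))
}

rcond_sym <- function(A) {
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
}

# One 2D Haar analysis step with 1/sqrt(2) normalization. Input must have
# even dimensions. Returns LL, LH, HL, HH (L/H order: rows then columns).
haar_step <- function(M) {
  ro <- seq(1, nrow(M), 2); re <- ro + 1
  Lr <- (M[ro, , drop = FALSE] + M[re, , drop = FALSE]) / sqrt(2)
  Hr <- (M[ro, , drop = FALSE] - M[re, , drop = FALSE]) / sqrt(2)
  co <- seq(1, ncol(M), 2); ce <- co + 1
  list(
    LL = (Lr[, co, drop = FALSE] + Lr[, ce, drop = FALSE]) / sqrt(2),
    LH = (Lr[, co, drop = FALSE] - Lr[, ce, drop = FALSE]) / sqrt(2),
    HL = (Hr[, co, drop = FALSE] + Hr[, ce, drop = FALSE]) / sqrt(2),
    HH = (Hr[, co, drop = FALSE] - Hr[, ce, drop = FALSE]) / sqrt(2)
  )
}

#' Haar wavelet subband energies
#'
#' Multiresolution Haar transform of the mask-bounding-box level patch
#' (out-of-mask pixels filled with the in-mask mean, patch padded with the
#' same value to a square power of two, at least 64). The energy of each
#' subband (LL, LH, HL, HH) at each scale is the mean of its squared
#' coefficients. Scales infeasible for the patch emit 0 with a validity flag.
#'
#' @param d A [normalize_gray_levels()] object.
#' @param n_scales Number of dyadic scales (default 6).
#' @return Named numeric vector of `4 * n_scales` energies (named
#'   `s<scale>.WavEn<band>`) with attribute `valid` (logical vector marking
#'   feasible scales).
#' @export
wavelet_features <- function(d, n_scales = 6L) {
  idx <- which(d$mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  if (diff(rr) + 1 < 2 || diff(cr) + 1 < 2)
    abort("Mask bounding box smaller than 2 px per side.")
  mu <- mean(d$levels[d$mask])
  patch <- d$levels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  patch[is.na(patch)] <- mu
  side <- 2^ceiling(log2(max(dim(patch), 64)))
  M <- matrix(mu, side, side)
  M[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch

  out <- numeric(0); valid <- logical(0)
  for (s in seq_len(n_scales)) {
    feasible <- nrow(M) >= 2 && ncol(M) >= 2
    if (feasible) {
      h <- haar_step(M)
      e <- vapply(h, function(b) mean(b^2), numeric(1))
      M <- h$LL
    } else {
      e <- c(LL = 0, LH = 0, HL = 0, HH = 0)
    }
    names(e) <- sprintf("s%d.WavEn%s", s, c("LL", "LH", "HL", "HH"))
    out <- c(out, e)
    valid <- c(valid, rep(feasible, 4))
  }
  attr(out, "valid") <- valid
  out
}
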