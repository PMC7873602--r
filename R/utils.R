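#' @importFrom rlang .data abort warn inform
#' @importFrom stats rnorm runif qnorm rlnorm sd var quantile rbinom
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic 31-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + as.double(salt) * 69621)
  as.integer(s %% 2147483562) + 1L
}

# Round half away from zero (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical matrices of identical dimension.
#' @return The Dice coefficient `2|A∩B| / (|A|+|B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

assert_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    abort("`mask` must be a logical matrix.")
  if (!any(mask)) abort("ROI mask is empty.")
  if (!is.null(image) && !identical(dim(image), dim(mask)))
    abort("`image` and `mask` dimensions differ.")
  invisible(mask)
}

# Binary erosion / dilation with a 4-connected structuring element,
# iterated `k` times. Used by the mask perturbation and ROI placement code.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  r0 <- max(1, 1 + dr); r1 <- min(n, n + dr)
  c0 <- max(1, 1 + dc); c1 <- min(p, p + dc)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

erode4 <- function(mask, k = 1L) {
  for (i in seq_len(k)) {
    mask <- mask &
      shift_mat(mask, 1L, 0L) & shift_mat(mask, -1L, 0L) &
      shift_mat(mask, 0L, 1L) & shift_mat(mask, 0L, -1L)
  }
  mask
}

dilate4 <- function(mask, k = 1L) {
  for (i in seq_len(k)) {
    mask <- mask |
      shift_mat(mask, 1L, 0L) | shift_mat(mask, -1L, 0L) |
      shift_mat(mask, 0L, 1L) | shift_mat(mask, 0L, -1L)
  }
  mask
}

# Erode a mask by a Euclidean disk of radius r (pixels): pixels whose whole
# disk neighbourhood lies inside the mask.
erode_disk <- function(mask, r) {
  offs <- disk_offsets(r)
  out <- mask
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_mat(mask, offs[k, 1], offs[k, 2])
  }
  out
}

disk_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# Stationary unit-variance Gaussian random field: white noise smoothed by a
# separable Gaussian kernel with the given correlation length (pixels).
# Row-wise kernel normalization keeps the variance exactly 1 at the edges.
gaussian_field <- function(nr, nc, corr_length) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_length <= 0) return(noise)
  hw <- max(1L, ceiling(3 * corr_length))
  k <- exp(-0.5 * ((-hw:hw) / corr_length)^2)
  bandmat <- function(n) {
    A <- matrix(0, n, n)
    for (d in -hw:hw) {
      idx <- which((1:n) + d >= 1 & (1:n) + d <= n)
      A[cbind(idx, idx + d)] <- k[d + hw + 1]
    }
    A / sqrt(rowSums(A^2))
  }
  bandmat(nr) %*% noise %*% t(bandmat(nc))
}
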