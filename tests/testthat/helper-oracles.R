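# Independent brute-force oracles. Each reimplements the target quantity by
# direct enumeration (explicit loops, no shared code with the package
# internals) so the fast implementations can be checked against them.

# Build a discretized_image by hand from an integer level matrix (NA = out
# of mask).
make_di <- function(levels, n_bins = max(levels, na.rm = TRUE)) {
  structure(list(levels = levels, mask = !is.na(levels),
                 n_bins = as.integer(n_bins),
                 window = c(NA_real_, NA_real_)),
            class = "discretized_image")
}

random_di <- function(nr = 6, nc = 6, n_bins = 5, p_na = 0.2) {
  L <- matrix(sample.int(n_bins, nr * nc, replace = TRUE), nr, nc)
  L[runif(nr * nc) < p_na] <- NA_integer_
  if (all(is.na(L))) L[1, 1] <- 1L
  make_di(L, n_bins)
}

oracle_moments <- function(x) {
  n <- length(x); m <- sum(x) / n
  v <- sum((x - m)^2) / n
  if (v == 0) return(c(mean = m, var = 0, skew = 0, kurt = 0))
  c(mean = m, var = v,
    skew = (sum((x - m)^3) / n) / sqrt(v)^3,
    kurt = (sum((x - m)^4) / n) / v^2 - 3)
}

oracle_percentile <- function(x, p) {
  xs <- sort(x)
  k <- ceiling(p * length(x))
  if (k < 1) k <- 1
  xs[k]
}

oracle_histogram <- function(di) {
  x <- di$levels[di$mask]
  mo <- oracle_moments(x)
  ps <- c(0.01, 0.10, 0.25, 0.50, 0.75, 0.90, 0.99)
  out <- c(mo[["mean"]], mo[["var"]], mo[["skew"]], mo[["kurt"]],
           vapply(ps, function(p) oracle_percentile(x, p), numeric(1)))
  names(out) <- c("Mean", "Variance", "Skewness", "Kurtosis", "Perc_01",
                  "Perc_10", "Perc_25", "Perc_50", "Perc_75", "Perc_90",
                  "Perc_99")
  out
}

oracle_gradient <- function(di) {
  L <- di$levels; m <- di$mask
  nr <- nrow(L); nc <- ncol(L)
  mags <- c()
  inb <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && isTRUE(m[i, j])
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!isTRUE(m[i, j])) next
    if (inb(i - 1, j) && inb(i + 1, j) && inb(i, j - 1) && inb(i, j + 1)) {
      gx <- (L[i, j + 1] - L[i, j - 1]) / 2
      gy <- (L[i + 1, j] - L[i - 1, j]) / 2
      mags <- c(mags, sqrt(gx^2 + gy^2))
    }
  }
  if (length(mags) == 0) return(NULL)
  mo <- oracle_moments(mags)
  c(GrMean = mo[["mean"]], GrVariance = mo[["var"]],
    GrSkewness = mo[["skew"]], GrKurtosis = mo[["kurt"]],
    GrNonZeros = sum(mags > 0) / length(mags))
}

oracle_glcm <- function(di, direction, distance) {
  off <- switch(as.character(direction),
                "0" = c(0, 1), "45" = c(1, 1), "90" = c(1, 0), "135" = c(1, -1))
  off <- off * distance
  L <- di$levels; m <- di$mask
  ng <- di$n_bins
  M <- matrix(0, ng, ng)
  nr <- nrow(L); nc <- ncol(L)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (isTRUE(m[i, j]) && i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
        isTRUE(m[i2, j2])) {
      a <- L[i, j]; b <- L[i2, j2]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) for (j in 1:ng) { mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j] }
  vx <- 0; vy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    vx <- vx + (i - mux)^2 * P[i, j]; vy <- vy + (j - muy)^2 * P[i, j]
  }
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  xlog2 <- function(p) if (p > 0) p * log2(p) else 0
  asm <- 0; con <- 0; cor_num <- 0; idm <- 0; ent <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - xlog2(p)
  }
  savg <- 0; for (k in 2:(2 * ng)) savg <- savg + k * psum[k]
  svar <- 0; for (k in 2:(2 * ng)) svar <- svar + (k - savg)^2 * psum[k]
  sent <- 0; for (k in 2:(2 * ng)) sent <- sent - xlog2(psum[k])
  davg <- 0; for (k in 0:(ng - 1)) davg <- davg + k * pdiff[k + 1]
  dvar <- 0; for (k in 0:(ng - 1)) dvar <- dvar + (k - davg)^2 * pdiff[k + 1]
  dent <- 0; for (k in 0:(ng - 1)) dent <- dent - xlog2(pdiff[k + 1])
  correlat <- if (vx == 0 || vy == 0) 0 else (cor_num - mux * muy) / sqrt(vx * vy)
  c(AngScMom = asm, Contrast = con, Correlat = correlat, SumOfSqs = vx,
    InvDfMom = idm, SumAverg = savg, SumVarnc = svar, SumEntrp = sent,
    Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# Run scanning by explicit walk along each line of the direction.
oracle_glrlm_features <- function(di, direction) {
  L <- di$levels; m <- di$mask
  nr <- nrow(L); nc <- ncol(L)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "45" = c(1, 1), "90" = c(1, 0), "135" = c(1, -1))
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pi <- i - step[1]; pj <- j - step[2]
    if (pi < 1 || pi > nr || pj < 1 || pj > nc)
      starts[[length(starts) + 1]] <- c(i, j)
  }
  runs_lv <- c(); runs_ln <- c()
  for (s in starts) {
    i <- s[1]; j <- s[2]
    cur <- NA; len <- 0
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      v <- if (isTRUE(m[i, j])) L[i, j] else NA
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) { runs_lv <- c(runs_lv, cur); runs_ln <- c(runs_ln, len) }
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (!is.na(cur)) { runs_lv <- c(runs_lv, cur); runs_ln <- c(runs_ln, len) }
  }
  nrn <- length(runs_lv); np <- sum(m)
  sre <- sum(1 / runs_ln^2) / nrn
  lre <- sum(runs_ln^2) / nrn
  gln <- sum(tapply(rep(1, nrn), runs_lv, sum)^2) / nrn
  rln <- sum(tapply(rep(1, nrn), runs_ln, sum)^2) / nrn
  c(ShrtREmp = sre, LngREmph = lre, GLevNonUni = gln, RLNonUni = rln,
    Fraction = nrn / np)
}

# Haar subband energies via explicit analysis matrices.
oracle_haar_energies <- function(M, n_scales) {
  haar_ops <- function(n) {
    Lo <- matrix(0, n / 2, n); Hi <- matrix(0, n / 2, n)
    for (k in seq_len(n / 2)) {
      Lo[k, 2 * k - 1] <- 1 / sqrt(2); Lo[k, 2 * k] <- 1 / sqrt(2)
      Hi[k, 2 * k - 1] <- 1 / sqrt(2); Hi[k, 2 * k] <- -1 / sqrt(2)
    }
    list(Lo = Lo, Hi = Hi)
  }
  out <- c()
  for (s in seq_len(n_scales)) {
    if (nrow(M) < 2 || ncol(M) < 2) {
      e <- c(0, 0, 0, 0)
    } else {
      R <- haar_ops(nrow(M)); C <- haar_ops(ncol(M))
      LL <- R$Lo %*% M %*% t(C$Lo); LH <- R$Lo %*% M %*% t(C$Hi)
      HL <- R$Hi %*% M %*% t(C$Lo); HH <- R$Hi %*% M %*% t(C$Hi)
      e <- c(mean(LL^2), mean(LH^2), mean(HL^2), mean(HH^2))
      M <- LL
    }
    names(e) <- sprintf("s%d.WavEn%s", s, c("LL", "LH", "HL", "HH"))
    out <- c(out, e)
  }
  out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ssr <- 0; for (i in 1:n) ssr <- ssr + k * (sum(m[i, ]) / k - g)^2
  ssc <- 0; for (j in 1:k) ssc <- ssc + n * (sum(m[, j]) / n - g)^2
  sst <- 0; for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - g)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Normal-approximation Wilcoxon rank-sum p-value with tie correction,
# assembled from first principles.
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments
# (small untied samples only).
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
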