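# ROC/AUC with confidence intervals, threshold metrics, group comparison
# statistics and the feature correlation matrix. Positive class: "high".

#' Area under the ROC curve
#'
#' Mann-Whitney pairwise formulation with ties counted 1/2, computed from
#' mid-ranks. Scores orient so that larger values indicate the positive
#' ("high") class; a training-side AUC below 0.5 is reported with a warning,
#' never silently flipped.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (`"low"`/`"high"`, factor, or 0/1).
#' @param warn_orientation Warn when AUC < 0.5 (default FALSE).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, warn_orientation = FALSE) {
  y <- as_grade(labels)
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  pos <- y == "high"
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (warn_orientation && a < 0.5)
    warn(sprintf("AUC = %.3f < 0.5: score orientation looks inverted.", a))
  a
}

#' ROC curve points
#'
#' Threshold sweep over the unique scores (call = "high" when score >=
#' threshold), yielding a monotone staircase from (0,0) to (1,1).
#'
#' @inheritParams auc
#' @return A tibble of class `renotex_roc` with `threshold`, `fpr`, `tpr`
#'   and attributes `auc`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_grade(labels)
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- y == "high"
  pts <- purrr::map_dfr(thr, function(t) {
    call_high <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(call_high & !pos) / sum(!pos),
                   tpr = sum(call_high & pos) / sum(pos))
  })
  structure(pts, auc = auc(scores, labels), n_pos = sum(pos),
            n_neg = sum(!pos), class = c("renotex_roc", class(pts)))
}

#' Confidence interval for the AUC
#'
#' Default: stratified bootstrap percentile interval (cases and controls
#' resampled separately, so every resample keeps both classes). Optional:
#' DeLong asymptotic interval from the placement-value variance.
#'
#' @inheritParams auc
#' @param method `"bootstrap"` or `"delong"`.
#' @param B Bootstrap replicates (default 2000, minimum 100).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)` with attribute `auc`.
#' @export
auc_ci <- function(scores, labels, method = c("bootstrap", "delong"),
                   B = 2000L, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  y <- as_grade(labels)
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  a <- auc(scores, y)
  alpha <- (1 - conf) / 2
  if (method == "bootstrap") {
    if (B < 100) abort("Use at least 100 bootstrap replicates.")
    ip <- which(y == "high"); im <- which(y == "low")
    stats <- with_seed(seed, vapply(seq_len(B), function(b) {
      idx <- c(resample(ip, replace = TRUE), resample(im, replace = TRUE))
      auc(scores[idx], y[idx])
    }, numeric(1)))
    ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha), type = 7))
  } else {
    sp <- scores[y == "high"]; sn <- scores[y == "low"]
    # placement values: P(negative below this positive) and vice versa
    v10 <- vapply(sp, function(s) mean((sn < s) + 0.5 * (sn == s)), numeric(1))
    v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
    se <- sqrt(stats::var(v10) / length(sp) + stats::var(v01) / length(sn))
    z <- qnorm(1 - alpha)
    ci <- c(max(0, a - z * se), min(1, a + z * se))
  }
  structure(stats::setNames(ci, c("lo", "hi")), auc = a)
}

#' Youden-optimal binarization threshold
#'
#' Maximizes sensitivity + specificity - 1 over the observed scores with the
#' `call = high when score >= threshold` convention; ties are broken toward
#' the lower threshold.
#'
#' @inheritParams auc
#' @return The threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_grade(labels)
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  cand <- sort(unique(scores))
  pos <- y == "high"
  j <- vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, numeric(1))
  cand[which.max(j)]   # which.max takes the first (lowest) maximizer
}

#' Threshold classification metrics
#'
#' Metrics of the 2x2 table at a threshold (call = "high" when score >=
#' threshold): sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, the
#' textbook FNR = FN/(TP+FN) and FPR = FP/(TN+FP), and the whole-cohort
#' variants FN/n and FP/n (labelled `fnr_cohort`/`fpr_cohort`; some published
#' tables report these). 95% CIs by stratified bootstrap.
#'
#' @inheritParams auc
#' @param threshold Binarization threshold.
#' @param B Bootstrap replicates for the CIs (0 disables CIs).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Tibble with `metric`, `value`, `lo`, `hi`.
#' @export
confusion_metrics <- function(scores, labels, threshold, B = 2000L,
                              seed = 1L, conf = 0.95) {
  y <- as_grade(labels)
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  if (threshold < min(scores) || threshold > max(scores))
    inform("Threshold outside the score range: degenerate 2x2 table.")
  one <- function(s, yy) {
    call_high <- s >= threshold
    pos <- yy == "high"
    tp <- sum(call_high & pos); fn <- sum(!call_high & pos)
    tn <- sum(!call_high & !pos); fp <- sum(call_high & !pos)
    n <- length(yy)
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      accuracy = (tp + tn) / n,
      fnr = fn / (tp + fn), fpr = fp / (tn + fp),
      fnr_cohort = fn / n, fpr_cohort = fp / n)
  }
  est <- one(scores, y)
  lo <- hi <- rep(NA_real_, length(est))
  if (B > 0) {
    ip <- which(y == "high"); im <- which(y == "low")
    boots <- with_seed(seed, vapply(seq_len(B), function(b) {
      idx <- c(resample(ip, replace = TRUE), resample(im, replace = TRUE))
      one(scores[idx], y[idx])
    }, numeric(length(est))))
    alpha <- (1 - conf) / 2
    lo <- apply(boots, 1, stats::quantile, alpha, na.rm = TRUE)
    hi <- apply(boots, 1, stats::quantile, 1 - alpha, na.rm = TRUE)
  }
  tibble::tibble(metric = names(est), value = unname(est),
                 lo = unname(lo), hi = unname(hi))
}

#' Group comparison tests for a characteristics table
#'
#' For each variable: Pearson chi-square without continuity correction
#' (categorical), two-sample t-test (continuous variables listed in
#' `normal_vars`), or Wilcoxon rank-sum with normal approximation and tie
#' correction (other continuous variables).
#'
#' @param data Data frame of per-patient characteristics.
#' @param group Name of the two-level grouping column.
#' @param normal_vars Character vector of variables to treat as normal.
#' @param vars Variables to test (default: all except `group` and
#'   `patient_id`).
#' @param exact Use the exact rank-sum distribution for the Wilcoxon p-value
#'   (small untied samples) instead of the default normal approximation.
#' @return Tibble with `variable`, `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(data, group, normal_vars = character(),
                           vars = NULL, exact = FALSE) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  if (any(table(g) == 0)) abort("Empty group.")
  if (is.null(vars))
    vars <- setdiff(names(data), c(group, "patient_id"))
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (v %in% normal_vars) {
        tt <- stats::t.test(x ~ g)
        tibble::tibble(variable = v, test = "t",
                       statistic = unname(tt$statistic), p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(
          stats::wilcox.test(x ~ g, exact = exact, correct = FALSE))
        tibble::tibble(variable = v, test = "wilcoxon",
                       statistic = unname(wt$statistic), p_value = wt$p.value)
      }
    } else {
      tab <- table(factor(x), g)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = v, test = "chi-square",
                     statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  })
}

#' Feature correlation matrix
#'
#' Pairwise Spearman (default) or Pearson correlations between feature
#' columns, with unit diagonal. Zero-variance features get correlation 0 and
#' are listed in the `flagged` attribute. The magnitude matrix is attached
#' as attribute `abs`.
#'
#' @param data Data frame; non-numeric columns and `patient_id` are ignored.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation matrix of class `renotex_cormat`.
#' @export
correlation_matrix <- function(data, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  df <- as.data.frame(data)
  df$patient_id <- NULL
  df <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 2 || nrow(df) < 3)
    abort("Need at least 2 features and 3 patients.")
  sds <- vapply(df, stats::sd, numeric(1))
  flagged <- names(df)[sds == 0]
  cm <- suppressWarnings(stats::cor(df, method = method))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  structure(cm, abs = abs(cm), flagged = flagged,
            class = c("renotex_cormat", "matrix"))
}
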