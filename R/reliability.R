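#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the two-way
#' ANOVA decomposition of an `n x k` subjects-by-raters matrix. The
#' consistency variant ICC(3,1) `(MSR - MSE)/(MSR + (k-1) MSE)` is available
#' via `model = "icc3"`. A matrix with zero total variance returns 1 (perfect
#' trivial agreement) with attribute `degenerate = TRUE`.
#'
#' @param m Numeric matrix, subjects in rows (n >= 2), raters in columns
#'   (k >= 2).
#' @param model `"icc2"` (default, absolute agreement) or `"icc3"`
#'   (consistency).
#' @return ICC value in `[-1, 1]`.
#' @export
icc <- function(m, model = c("icc2", "icc3")) {
  model <- match.arg(model)
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("RatingsMatrix needs n >= 2 subjects and k >= 2 raters.")
  if (any(!is.finite(m))) abort("Non-finite ratings.")
  g <- mean(m)
  sst <- sum((m - g)^2)
  if (sst == 0) return(structure(1, degenerate = TRUE))
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (model == "icc2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Qualitative ICC agreement band
#'
#' Bands: poor (< 0.21), fair (0.21-0.40), moderate (0.40-0.60], good
#' (0.60-0.80], excellent (0.80-1.00]. The published banding leaves
#' [0.20, 0.21) unassigned; it is resolved to poor. `passes_0_75` flags
#' ICC > 0.75 ("good agreement" rule of thumb).
#'
#' @param x ICC value(s).
#' @return For [icc_category()], a factor with levels poor/fair/moderate/
#'   good/excellent. For [icc_result()], a tibble with `icc`, `category`,
#'   `passes_0_75`.
#' @export
icc_category <- function(x) {
  lv <- c("poor", "fair", "moderate", "good", "excellent")
  out <- ifelse(x > 0.80, "excellent",
         ifelse(x > 0.60, "good",
         ifelse(x > 0.40, "moderate",
         ifelse(x >= 0.21, "fair", "poor"))))
  factor(out, levels = lv)
}

#' @rdname icc_category
#' @export
icc_result <- function(x) {
  tibble::tibble(icc = x, category = icc_category(x), passes_0_75 = x > 0.75)
}

#' Per-feature reproducibility report
#'
#' Computes the intra-observer ICC (Reader 1 first vs second extraction) and
#' the inter-observer ICC (Reader 1 first extraction vs Reader 2) for every
#' feature column, with qualitative bands. Following the study protocol the
#' Reader-1 first-pass features are always returned as the analysis set; the
#' optional retention filter (`retain_threshold`, default `NULL` = off)
#' additionally flags features whose both ICCs exceed the threshold.
#'
#' @param features_reader1a,features_reader1b,features_reader2 Feature
#'   tibbles with a `patient_id` column and identical feature columns.
#' @param retain_threshold Optional ICC retention threshold (e.g. 0.75).
#' @return List of class `repro_report`: `table` (per-feature tibble),
#'   `retained` (character vector of feature names), `analysis_features`
#'   (the Reader-1a tibble).
#' @export
reproducibility_report <- function(features_reader1a, features_reader1b,
                                   features_reader2, retain_threshold = NULL) {
  tabs <- list(features_reader1a, features_reader1b, features_reader2)
  ids <- features_reader1a$patient_id
  for (t in tabs) {
    if (!identical(sort(t$patient_id), sort(ids)))
      abort("Patient ids differ across extractions.")
  }
  tabs <- lapply(tabs, function(t) t[match(ids, t$patient_id), ])
  feats <- setdiff(names(features_reader1a), "patient_id")
  icc_intra <- vapply(feats, function(f)
    as.numeric(icc(cbind(tabs[[1]][[f]], tabs[[2]][[f]]))), numeric(1))
  icc_inter <- vapply(feats, function(f)
    as.numeric(icc(cbind(tabs[[1]][[f]], tabs[[3]][[f]]))), numeric(1))
  tab <- tibble::tibble(
    feature = feats,
    icc_intra = icc_intra,
    icc_inter = icc_inter,
    category_intra = icc_category(icc_intra),
    category_inter = icc_category(icc_inter),
    retained = if (is.null(retain_threshold)) TRUE
               else icc_intra > retain_threshold & icc_inter > retain_threshold
  )
  structure(list(table = tab,
                 retained = tab$feature[tab$retained],
                 analysis_features = features_reader1a),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> %d features; intra ICC [%.3f, %.3f]; inter ICC [%.3f, %.3f]; %d retained\n",
              nrow(x$table),
              min(x$table$icc_intra), max(x$table$icc_intra),
              min(x$table$icc_inter), max(x$table$icc_inter),
              length(x$retained)))
  invisible(x)
}
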