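# Stacked classifier: per feature block (texture, traditional) a LASSO
# logistic score and a random-forest score are fused by a linear SVM; a
# second-level linear SVM fuses the two block scores. The positive class is
# "high" grade throughout.

as_grade <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y)) y <- ifelse(y > 0, "high", "low")
  if (!all(y %in% c("low", "high"))) abort("Labels must be 'low'/'high' (or 0/1).")
  factor(y, levels = c("low", "high"))
}

as_feature_matrix <- function(x) {
  x <- as.data.frame(x)
  x$patient_id <- NULL
  for (j in seq_along(x)) if (is.factor(x[[j]])) x[[j]] <- as.numeric(x[[j]]) - 1
  as.matrix(x)
}

#' Z-score standardization with training-derived parameters
#'
#' Centers and scales with the training means/SDs only; the same transform is
#' applied to `X_apply`. Zero-variance training columns are dropped with a
#' warning.
#'
#' @param X_train Training feature matrix (or data frame).
#' @param X_apply Optional matrix to transform with the training parameters.
#' @return List: `train`, `apply` (or `NULL`), `center`, `scale`.
#' @export
standardize_features <- function(X_train, X_apply = NULL) {
  X_train <- as_feature_matrix(X_train)
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) abort("All training columns are constant.")
  if (any(!keep))
    warn(sprintf("Dropping %d zero-variance column(s): %s",
                 sum(!keep), paste(colnames(X_train)[!keep], collapse = ", ")))
  ctr <- ctr[keep]; scl <- scl[keep]
  tr <- sweep(sweep(X_train[, keep, drop = FALSE], 2, ctr), 2, scl, "/")
  ap <- NULL
  if (!is.null(X_apply)) {
    X_apply <- as_feature_matrix(X_apply)[, names(ctr), drop = FALSE]
    ap <- sweep(sweep(X_apply, 2, ctr), 2, scl, "/")
  }
  list(train = tr, apply = ap, center = ctr, scale = scl)
}

apply_standardization <- function(std, X) {
  X <- as_feature_matrix(X)
  missing <- setdiff(names(std$center), colnames(X))
  if (length(missing) > 0)
    abort(paste("Missing feature columns:", paste(missing, collapse = ", ")))
  sweep(sweep(X[, names(std$center), drop = FALSE], 2, std$center), 2,
        std$scale, "/")
}

stratified_folds <- function(y, n_folds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- resample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

#' L1-penalized logistic feature selection with cross-validated lambda
#'
#' Fits the LASSO path (`glmnet`) on the training block and picks lambda by
#' seeded stratified K-fold CV at minimum binomial deviance (`"min"`, the
#' default) or the one-standard-error rule (`"1se"`). If the chosen lambda
#' selects no feature, the minimum-deviance lambda is used as fallback; if
#' that still selects none, an empty selection is returned (the score is the
#' intercept).
#'
#' @param X Standardized feature matrix.
#' @param y Binary labels (`"low"`/`"high"` or 0/1; positive class "high").
#' @param n_folds CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param seed Integer seed for the fold assignment.
#' @return List of class `lasso_fit`: `intercept`, `coef` (named, selected
#'   features only), `selected`, `lambda`, `cv` (the `cv.glmnet` object).
#' @export
fit_lasso_cv <- function(X, y, n_folds = 10L, lambda_rule = c("min", "1se"),
                         seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as_grade(y)
  if (nlevels(droplevels(y)) < 2) abort("Single-class labels.")
  X <- as.matrix(X)
  if (nrow(X) < n_folds) abort("Fewer observations than folds.")
  foldid <- stratified_folds(y, n_folds, seed)
  # glmnet requires >= 2 columns; pad a single-feature block with a zero
  # dummy whose coefficient is structurally 0
  Xfit <- if (ncol(X) == 1) cbind(X, `..dummy` = 0) else X
  cv <- glmnet::cv.glmnet(Xfit, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  pick <- function(lam) {
    b <- as.matrix(stats::coef(cv, s = lam))
    sel <- rownames(b)[-1][b[-1, 1] != 0]
    list(intercept = b[1, 1], coef = stats::setNames(b[-1, 1][b[-1, 1] != 0], sel),
         selected = sel, lambda = lam)
  }
  res <- pick(lambda)
  if (length(res$selected) == 0 && lambda_rule == "1se") res <- pick(cv$lambda.min)
  res$selected <- setdiff(res$selected, "..dummy")
  res$coef <- res$coef[res$selected]
  structure(c(res, list(cv = cv, feature_names = colnames(X))),
            class = "lasso_fit")
}

#' Linear predictor of a LASSO fit (Rad-score)
#'
#' @param X Standardized feature matrix containing the selected columns.
#' @param fit A [fit_lasso_cv()] object.
#' @return Numeric score per row: `intercept + sum beta_i x_i`.
#' @export
lasso_score <- function(X, fit) {
  X <- as.matrix(X)
  if (length(fit$selected) == 0) return(rep(fit$intercept, nrow(X)))
  missing <- setdiff(fit$selected, colnames(X))
  if (length(missing) > 0)
    abort(paste("Missing feature columns:", paste(missing, collapse = ", ")))
  drop(fit$intercept + X[, fit$selected, drop = FALSE] %*% fit$coef)
}

# K-fold cross-fitted LASSO linear predictor at a fixed lambda: each training
# row is scored by a model fitted without its fold (prevents optimistic
# stacking inputs).
crossfit_lasso_score <- function(X, y, lambda, n_folds = 5L, seed = 1L) {
  y <- as_grade(y)
  foldid <- stratified_folds(y, n_folds, seed)
  out <- numeric(nrow(X))
  if (ncol(X) == 1) X <- cbind(X, `..dummy` = 0)
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, standardize = FALSE)
    out[!tr] <- drop(stats::predict(fit, X[!tr, , drop = FALSE], s = lambda))
  }
  out
}

#' Random forest block model
#'
#' Seeded random forest on the LASSO-selected features. Training-row scores
#' use the out-of-bag class votes (so stacking inputs are not optimistically
#' biased); new rows get the plain forest probability. The in-sample
#' probability is available with `oob = FALSE` for the naive-stacking mode.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A `randomForest` fit.
#' @export
fit_rf <- function(X, y, n_trees = 500L, seed = 1L) {
  y <- as_grade(y)
  if (nlevels(droplevels(y)) < 2) abort("Single-class labels.")
  with_seed(seed, randomForest::randomForest(as.matrix(X), y, ntree = n_trees))
}

#' @rdname fit_rf
#' @param fit A [fit_rf()] object.
#' @param newdata Feature matrix to score; if `NULL`, training rows are
#'   scored.
#' @param oob Use out-of-bag votes for training rows (default TRUE).
#' @return Probability of the "high" class per row.
#' @export
rf_score <- function(fit, newdata = NULL, oob = TRUE) {
  if (is.null(newdata)) {
    if (!oob) abort("In-sample scoring requires `newdata` (the training matrix).")
    return(unname(fit$votes[, "high"]))
  }
  unname(stats::predict(fit, as.matrix(newdata), type = "prob")[, "high"])
}

#' Linear SVM fusing two block scores
#'
#' Fits a linear-kernel SVM on the (standardized) 2D score space and emits a
#' continuous decision score oriented so that larger means "high" grade (the
#' orientation is fixed from the training class means of the decision value,
#' making the score deterministic — no Platt scaling). Zero-variance score
#' columns are dropped; if both are constant an error is raised.
#'
#' @param scores Matrix or data frame of block scores (columns = component
#'   scores).
#' @param y Binary labels.
#' @param cost SVM cost parameter (default 1).
#' @return List of class `svm_fusion`: `svm`, `std`, `orientation`, `cols`.
#' @export
fit_block_svm <- function(scores, y, cost = 1) {
  y <- as_grade(y)
  S <- as.matrix(as.data.frame(scores))
  keep <- apply(S, 2, stats::sd) > 0
  if (!any(keep)) abort("Degenerate constant scores: nothing to fuse.")
  if (any(!keep)) warn("Dropping constant score column(s) from the SVM input.")
  std <- standardize_features(S[, keep, drop = FALSE])
  fit <- e1071::svm(std$train, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- drop(attr(stats::predict(fit, std$train, decision.values = TRUE),
                  "decision.values"))
  orientation <- if (mean(dv[y == "high"]) >= mean(dv[y == "low"])) 1 else -1
  structure(list(svm = fit, std = std, orientation = orientation,
                 cols = colnames(S)[keep]),
            class = "svm_fusion")
}

#' @rdname fit_block_svm
#' @param fit A fitted `svm_fusion` object.
#' @param newscores Score matrix to evaluate.
#' @return Continuous decision score per row (larger = more likely high
#'   grade).
#' @export
svm_fusion_score <- function(fit, newscores) {
  S <- as.matrix(as.data.frame(newscores))[, fit$cols, drop = FALSE]
  Z <- apply_standardization(fit$std, S)
  dv <- drop(attr(stats::predict(fit$svm, Z, decision.values = TRUE),
                  "decision.values"))
  unname(fit$orientation * dv)
}

#' Stacking configuration
#'
#' @param n_folds LASSO CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param n_trees Random forest size (default 500).
#' @param naive_stacking If `TRUE`, the block SVMs are fitted on in-sample
#'   LASSO and RF scores (the literal recipe); default `FALSE` uses
#'   cross-fitted LASSO and out-of-bag RF scores for the training rows.
#' @param crossfit_folds Folds for the cross-fitted LASSO score (default 5).
#' @param svm_cost Cost parameter of the linear SVMs.
#' @return A list of class `stack_config`.
#' @export
stack_config <- function(n_folds = 10L, lambda_rule = "min", n_trees = 500L,
                         naive_stacking = FALSE, crossfit_folds = 5L,
                         svm_cost = 1) {
  structure(list(n_folds = n_folds, lambda_rule = lambda_rule,
                 n_trees = n_trees, naive_stacking = naive_stacking,
                 crossfit_folds = crossfit_folds, svm_cost = svm_cost),
            class = "stack_config")
}

fit_block <- function(X, y, config, seed) {
  std <- standardize_features(X)
  lasso <- fit_lasso_cv(std$train, y, config$n_folds, config$lambda_rule, seed)
  s_lasso_in <- lasso_score(std$train, lasso)
  s_lasso <- if (config$naive_stacking) s_lasso_in else {
    if (length(lasso$selected) == 0) s_lasso_in
    else crossfit_lasso_score(std$train, y, lasso$lambda,
                              config$crossfit_folds, derive_seed(seed, 2L))
  }
  rf_cols <- if (length(lasso$selected) > 0) lasso$selected
             else colnames(std$train)
  rf <- fit_rf(std$train[, rf_cols, drop = FALSE], y, config$n_trees,
               derive_seed(seed, 3L))
  s_rf <- if (config$naive_stacking)
    rf_score(rf, std$train[, rf_cols, drop = FALSE], oob = FALSE)
  else rf_score(rf)
  svm <- fit_block_svm(cbind(lasso = s_lasso, rf = s_rf), y,
                       cost = config$svm_cost)
  s_svm <- svm_fusion_score(svm, cbind(lasso = s_lasso, rf = s_rf))
  list(std = std, lasso = lasso, rf = rf, rf_cols = rf_cols, svm = svm,
       scores = list(lasso = s_lasso, rf = s_rf, svm = s_svm))
}

predict_block <- function(block, X) {
  Z <- apply_standardization(block$std, X)
  s_lasso <- lasso_score(Z, block$lasso)
  s_rf <- rf_score(block$rf, Z[, block$rf_cols, drop = FALSE])
  s_svm <- svm_fusion_score(block$svm, cbind(lasso = s_lasso, rf = s_rf))
  list(lasso = s_lasso, rf = s_rf, svm = s_svm)
}

#' Fit the stacked texture + traditional classifier
#'
#' The full recipe: for the texture block a LASSO score (Score 1, the
#' Rad-score) and a random-forest score (Score 2) are fused by SVM1
#' (Score 3); the traditional block analogously gives Scores 4-6 (SVM2);
#' SVM3 (Score 7) fuses the two block SVM scores. The binarization threshold
#' is set by the Youden index on the training ROC of Score 7. All fitted
#' statistics derive from the training rows only.
#'
#' @param X_texture,X_traditional Training feature tables (matrix/data
#'   frame; a `patient_id` column is ignored), aligned row-wise.
#' @param y Binary grade labels (`"low"`/`"high"`, positive class "high").
#' @param config A [stack_config()].
#' @param seed Integer master seed.
#' @return An object of class `stacked_model`.
#' @export
fit_stacked_classifier <- function(X_texture, X_traditional, y,
                                   config = stack_config(), seed = 1L) {
  y <- as_grade(y)
  if (nrow(as.data.frame(X_texture)) != length(y) ||
      nrow(as.data.frame(X_traditional)) != length(y))
    abort("Blocks and labels are not aligned.")
  texture <- fit_block(X_texture, y, config, derive_seed(seed, 10L))
  traditional <- fit_block(X_traditional, y, config, derive_seed(seed, 20L))
  svm3_in <- cbind(svm1 = texture$scores$svm, svm2 = traditional$scores$svm)
  svm3 <- fit_block_svm(svm3_in, y, cost = config$svm_cost)
  score7 <- svm_fusion_score(svm3, svm3_in)
  thr <- youden_threshold(score7, y)
  structure(list(
    texture = texture, traditional = traditional, svm3 = svm3,
    threshold = thr, config = config, seed = as.integer(seed),
    y_train = y,
    train_scores = tibble::tibble(
      score1 = texture$scores$lasso, score2 = texture$scores$rf,
      score3 = texture$scores$svm,
      score4 = traditional$scores$lasso, score5 = traditional$scores$rf,
      score6 = traditional$scores$svm, score7 = score7)
  ), class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d training patients (%d high grade)\n",
              length(x$y_train), sum(x$y_train == "high")))
  cat(sprintf("  texture block: %d LASSO-selected features; traditional block: %d\n",
              length(x$texture$lasso$selected),
              length(x$traditional$lasso$selected)))
  cat(sprintf("  threshold (Youden, training Score 7): %.4f\n", x$threshold))
  invisible(x)
}

#' Predict grade with a stacked model
#'
#' @param object A [fit_stacked_classifier()] model.
#' @param X_texture,X_traditional Feature tables for the patients to score.
#' @param patient_id Optional id column for the output.
#' @param ... Unused.
#' @return Tibble with `score1`..`score7` and the binary `call` (`"high"`
#'   when Score 7 is at or above the training threshold).
#' @export
predict.stacked_model <- function(object, X_texture, X_traditional,
                                  patient_id = NULL, ...) {
  tex <- predict_block(object$texture, X_texture)
  tra <- predict_block(object$traditional, X_traditional)
  s7 <- svm_fusion_score(object$svm3, cbind(svm1 = tex$svm, svm2 = tra$svm))
  out <- tibble::tibble(
    score1 = tex$lasso, score2 = tex$rf, score3 = tex$svm,
    score4 = tra$lasso, score5 = tra$rf, score6 = tra$svm,
    score7 = s7,
    call = factor(ifelse(s7 >= object$threshold, "high", "low"),
                  levels = c("low", "high")))
  if (!is.null(patient_id)) out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id), out)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the LASSO signatures of a stacked model
#'
#' @param x A `stacked_model`.
#' @param ... Unused.
#' @return Tibble with `block`, `term`, `estimate` (nonzero LASSO
#'   coefficients plus intercepts).
#' @method tidy stacked_model
#' @export
tidy.stacked_model <- function(x, ...) {
  one <- function(blk, name) {
    terms <- c("(Intercept)", blk$lasso$selected)
    est <- c(blk$lasso$intercept, unname(blk$lasso$coef))
    tibble::tibble(block = name, term = terms, estimate = est)
  }
  dplyr::bind_rows(one(x$texture, "texture"), one(x$traditional, "traditional"))
}

#' Glance at a stacked model
#'
#' @param x A `stacked_model`.
#' @param ... Unused.
#' @return One-row tibble: training size, class balance, selected-feature
#'   counts, threshold, and training AUCs of Scores 3, 6, 7.
#' @method glance stacked_model
#' @export
glance.stacked_model <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$y_train),
    n_high = sum(x$y_train == "high"),
    n_selected_texture = length(x$texture$lasso$selected),
    n_selected_traditional = length(x$traditional$lasso$selected),
    threshold = x$threshold,
    auc_svm1_train = auc(x$train_scores$score3, x$y_train),
    auc_svm2_train = auc(x$train_scores$score6, x$y_train),
    auc_svm3_train = auc(x$train_scores$score7, x$y_train))
}
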