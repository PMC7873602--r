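# End-to-end orchestration: simulate -> extract -> reliability -> train ->
# evaluate, with plain-file handoff (CSV/JSON) between stages and a manifest
# of per-file checksums so every number of a run is reproducible from its
# config and seed.

#' Pipeline run configuration
#'
#' @param n_low,n_high Cohort sizes per grade (defaults 206/58).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param params [default_cohort_params()] generator parameters.
#' @param registry Feature registry (default 340-feature manifest).
#' @param ratio_train,stratified Split parameters (default 3:1, stratified).
#' @param n_repro Patients in the reproducibility subsample (default 50).
#' @param perturb_intra,perturb_inter Mask perturbation magnitudes (px)
#'   emulating the intra-observer repeat and the second reader.
#' @param stacking A [stack_config()].
#' @param ci_B Bootstrap replicates for the evaluation CIs.
#' @param write_images Also write phantom images (NIfTI) during simulate.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_low = 206L, n_high = 58L, seed = 7L,
                       params = default_cohort_params(),
                       registry = default_registry(),
                       ratio_train = 0.75, stratified = TRUE,
                       n_repro = 50L, perturb_intra = 1, perturb_inter = 2,
                       stacking = stack_config(), ci_B = 500L,
                       write_images = FALSE, out_dir = tempfile("renotex_run_")) {
  structure(list(n_low = n_low, n_high = n_high, seed = as.integer(seed),
                 params = params, registry = registry,
                 ratio_train = ratio_train, stratified = stratified,
                 n_repro = n_repro, perturb_intra = perturb_intra,
                 perturb_inter = perturb_inter, stacking = stacking,
                 ci_B = ci_B, write_images = write_images, out_dir = out_dir),
            class = "run_config")
}

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (!file.exists(p)) return(list(files = list()))
  jsonlite::read_json(p, simplifyVector = TRUE)
}

record_files <- function(dir, stage, files) {
  man <- read_manifest(dir)
  if (is.null(man$files) || length(man$files) == 0) man$files <- list()
  for (f in files) {
    man$files[[basename(f)]] <- list(stage = stage,
                                     md5 = unname(tools::md5sum(f)))
  }
  jsonlite::write_json(man, manifest_path(dir), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

verify_inputs <- function(dir, files) {
  man <- read_manifest(dir)
  for (f in files) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("Missing upstream file '%s'.", f))
    rec <- man$files[[f]]
    if (!is.null(rec) && !identical(unname(tools::md5sum(p)), rec$md5))
      abort(sprintf("Checksum mismatch for '%s': upstream output changed; re-run its stage.", f))
  }
  invisible(TRUE)
}

#' Pipeline stages
#'
#' Each stage consumes the previous stage's files from `config$out_dir`
#' (verifying their manifest checksums) and writes its own outputs:
#' `stage_simulate` the cohort truth table, `stage_extract` the texture and
#' traditional feature tables, `stage_reliability` the per-feature ICC
#' report, `stage_train` the split assignment and the fitted model archive,
#' `stage_evaluate` per-model scores, ROC points and metrics.
#'
#' @param config A [run_config()].
#' @return Each stage returns its primary in-memory product, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$n_low, config$n_high, config$params,
                            derive_seed(config$seed, 1L))
  truth_csv <- file.path(config$out_dir, "truth.csv")
  utils::write.csv(cohort$truth, truth_csv, row.names = FALSE)
  files <- truth_csv
  if (config$write_images) {
    img_dir <- file.path(config$out_dir, "images")
    for (ph in cohort$phantoms) files <- c(files, write_phantom(ph, img_dir))
  }
  record_files(config$out_dir, "simulate", files)
  saveRDS(cohort, file.path(config$out_dir, "cohort.rds"))
  invisible(cohort)
}

#' @rdname pipeline_stages
#' @export
stage_extract <- function(config) {
  verify_inputs(config$out_dir, "truth.csv")
  cohort <- readRDS(file.path(config$out_dir, "cohort.rds"))
  texture <- extract_texture_features(cohort, config$registry)
  traditional <- extract_traditional_features(cohort,
                                              derive_seed(config$seed, 2L))
  tex_csv <- file.path(config$out_dir, "features_texture.csv")
  tra_csv <- file.path(config$out_dir, "features_traditional.csv")
  write_feature_table(texture, tex_csv)
  write_feature_table(traditional, tra_csv)
  reg_json <- file.path(config$out_dir, "registry.json")
  write_registry_manifest(config$registry, reg_json)
  record_files(config$out_dir, "extract",
               c(tex_csv, sub("\\.csv$", "_validity.csv", tex_csv), tra_csv,
                 reg_json))
  invisible(list(texture = texture, traditional = traditional))
}

#' @rdname pipeline_stages
#' @export
stage_reliability <- function(config) {
  verify_inputs(config$out_dir, "features_texture.csv")
  cohort <- readRDS(file.path(config$out_dir, "cohort.rds"))
  n_sub <- min(config$n_repro, length(cohort$phantoms))
  sub_ids <- with_seed(derive_seed(config$seed, 3L),
                       sample(names(cohort$phantoms), n_sub))
  sub <- cohort$phantoms[sub_ids]
  masks_of <- function(magnitude, salt) {
    stats::setNames(lapply(seq_along(sub), function(i) {
      perturb_mask(sub[[i]]$mask, magnitude,
                   derive_seed(config$seed, i, salt))
    }), sub_ids)
  }
  f1a <- extract_texture_features(sub, config$registry)
  f1b <- extract_texture_features(sub, config$registry,
                                  masks = masks_of(config$perturb_intra, 31L))
  f2 <- extract_texture_features(sub, config$registry,
                                 masks = masks_of(config$perturb_inter, 32L))
  rep <- reproducibility_report(f1a, f1b, f2)
  rel_csv <- file.path(config$out_dir, "reliability.csv")
  utils::write.csv(rep$table, rel_csv, row.names = FALSE)
  record_files(config$out_dir, "reliability", rel_csv)
  invisible(rep)
}

#' @rdname pipeline_stages
#' @export
stage_train <- function(config) {
  verify_inputs(config$out_dir,
                c("truth.csv", "features_texture.csv",
                  "features_traditional.csv"))
  truth <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "truth.csv")))
  texture <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "features_texture.csv")))
  traditional <- tibble::as_tibble(utils::read.csv(
    file.path(config$out_dir, "features_traditional.csv"),
    stringsAsFactors = TRUE))
  split <- split_cohort(truth, config$ratio_train,
                        derive_seed(config$seed, 4L), config$stratified)
  split_csv <- file.path(config$out_dir, "split.csv")
  utils::write.csv(split[, c("patient_id", "grade", "cohort", "seed")],
                   split_csv, row.names = FALSE)
  tr <- split$cohort == "training"
  model <- fit_stacked_classifier(
    texture[tr, ], traditional[tr, ], split$grade[tr],
    config$stacking, derive_seed(config$seed, 5L))
  saveRDS(model, file.path(config$out_dir, "model.rds"))
  coef_json <- file.path(config$out_dir, "model_coefficients.json")
  jsonlite::write_json(list(coefficients = tidy(model),
                            summary = glance(model),
                            threshold = model$threshold),
                       coef_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  record_files(config$out_dir, "train", c(split_csv, coef_json))
  invisible(model)
}

#' @rdname pipeline_stages
#' @export
stage_evaluate <- function(config) {
  verify_inputs(config$out_dir,
                c("split.csv", "features_texture.csv",
                  "features_traditional.csv"))
  split <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "split.csv")))
  texture <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "features_texture.csv")))
  traditional <- tibble::as_tibble(utils::read.csv(
    file.path(config$out_dir, "features_traditional.csv"),
    stringsAsFactors = TRUE))
  model <- readRDS(file.path(config$out_dir, "model.rds"))

  scores <- predict(model, texture, traditional,
                    patient_id = split$patient_id)
  scores$grade <- split$grade
  scores$cohort <- split$cohort
  scores_csv <- file.path(config$out_dir, "scores.csv")
  utils::write.csv(scores, scores_csv, row.names = FALSE)

  models <- c(SVM1 = "score3", SVM2 = "score6", SVM3 = "score7")
  tr <- scores$cohort == "training"
  metrics <- list()
  files <- scores_csv
  for (m in names(models)) {
    s <- scores[[models[[m]]]]
    thr <- youden_threshold(s[tr], scores$grade[tr])
    for (coh in c("training", "validation")) {
      i <- scores$cohort == coh
      ci <- auc_ci(s[i], scores$grade[i], B = config$ci_B,
                   seed = derive_seed(config$seed, 6L))
      cm <- confusion_metrics(s[i], scores$grade[i], thr, B = config$ci_B,
                              seed = derive_seed(config$seed, 7L))
      metrics[[m]][[coh]] <- list(
        auc = attr(ci, "auc"), auc_ci95 = as.list(ci),
        threshold = thr,
        metrics = cm)
      roc <- roc_points(s[i], scores$grade[i])
      roc_csv <- file.path(config$out_dir,
                           sprintf("roc_%s_%s.csv", m, coh))
      utils::write.csv(as.data.frame(roc), roc_csv, row.names = FALSE)
      files <- c(files, roc_csv)
    }
  }
  metrics_json <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)

  # correlation among the features entering the final model
  sel <- c(model$texture$lasso$selected, model$traditional$lasso$selected)
  sel_tab <- dplyr::bind_cols(texture[setdiff(names(texture), "patient_id")],
                              as.data.frame(as_feature_matrix(traditional)))
  sel <- intersect(sel, names(sel_tab))
  cor_csv <- file.path(config$out_dir, "correlation_selected.csv")
  if (length(sel) >= 2) {
    cm <- correlation_matrix(sel_tab[sel])
    utils::write.csv(as.data.frame(unclass(cm)), cor_csv)
    files <- c(files, cor_csv)
  }
  record_files(config$out_dir, "evaluate", c(files, metrics_json))
  invisible(metrics)
}

#' Run the whole pipeline
#'
#' Executes simulate, extract, reliability, train and evaluate in order and
#' writes a manifest of every emitted file with its checksum. A run is a
#' pure function of its configuration (all randomness derives from
#' `config$seed`).
#'
#' @param config A [run_config()].
#' @param reliability Include the reproducibility stage (default TRUE).
#' @return Invisibly, a list with the evaluation metrics, the fitted model,
#'   and the output directory.
#' @export
run_end_to_end <- function(config = run_config(), reliability = TRUE) {
  t0 <- Sys.time()
  stage_simulate(config)
  stage_extract(config)
  rep <- if (reliability) stage_reliability(config) else NULL
  model <- stage_train(config)
  metrics <- stage_evaluate(config)
  man <- read_manifest(config$out_dir)
  man$run <- list(seed = config$seed,
                  n_low = config$n_low, n_high = config$n_high,
                  elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(man, manifest_path(config$out_dir), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(metrics = metrics, model = model, reliability = rep,
                 out_dir = config$out_dir))
}
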