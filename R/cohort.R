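#' Group-conditional distribution parameters for the synthetic cohort
#'
#' Defaults reproduce the published cohort statistics of a 264-patient ccRCC
#' series: tumor sizes and contrast enhancement are log-normal (parameterized
#' by their reported median and truncated to the reported range, matching the
#' skewed median-range reporting), pre-contrast attenuation is normal
#' (reported as mean +/- SD). Heterogeneity parameters (texture correlation
#' length, texture SD, necrosis) are the generator's own calibration: high
#' grade tumors carry finer, stronger texture and necrotic foci, the imaging
#' correlates of the aggressive phenotype.
#'
#' @param low,high Named lists overriding individual per-grade parameters.
#'   Per-grade fields: `size_transverse`, `size_anteroposterior`,
#'   `size_craniocaudal` (each `c(median, min, max)` in cm), `ct_pre`
#'   (`c(mean, sd)` in HU), `enhancement` (`c(median, min, max)` in HU),
#'   `corr_length_px`, `texture_sd_hu`, `necrosis_n`, `necrosis_fraction`.
#' @param background_hu Uniform parenchyma background density (HU).
#' @param necrosis_offset_hu Density reduction inside necrotic foci (HU).
#' @param canvas_px Side of the square image canvas (pixels).
#' @param spacing_mm Isotropic pixel spacing in mm (1.0 emulates 1x1x1 mm
#'   resampled CT).
#' @return A list of class `cohort_params`.
#' @export
default_cohort_params <- function(low = list(), high = list(),
                                  background_hu = 30,
                                  necrosis_offset_hu = 25,
                                  canvas_px = 128L,
                                  spacing_mm = 1.0) {
  base_low <- list(
    size_transverse = c(median = 4.12, min = 1.36, max = 11.55),
    size_anteroposterior = c(median = 4.32, min = 0.88, max = 11.05),
    size_craniocaudal = c(median = 4.23, min = 1.13, max = 12.23),
    ct_pre = c(mean = 31.26, sd = 7.93),
    enhancement = c(median = 49.66, min = 9.39, max = 221.28),
    corr_length_px = 3,
    texture_sd_hu = 5,
    necrosis_n = 0L,
    necrosis_fraction = 0
  )
  base_high <- list(
    size_transverse = c(median = 5.98, min = 1.87, max = 10.44),
    size_anteroposterior = c(median = 6.02, min = 1.54, max = 12.36),
    size_craniocaudal = c(median = 6.30, min = 1.91, max = 18.74),
    ct_pre = c(mean = 36.41, sd = 6.51),
    enhancement = c(median = 38.76, min = 10.58, max = 117.40),
    corr_length_px = 2,
    texture_sd_hu = 8,
    necrosis_n = 3L,
    necrosis_fraction = 0.10
  )
  p <- list(
    low = utils::modifyList(base_low, low),
    high = utils::modifyList(base_high, high),
    background_hu = background_hu,
    necrosis_offset_hu = necrosis_offset_hu,
    canvas_px = as.integer(canvas_px),
    spacing_mm = spacing_mm
  )
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  for (g in c("low", "high")) {
    gp <- p[[g]]
    for (f in c("size_transverse", "size_anteroposterior", "size_craniocaudal",
                "enhancement")) {
      v <- gp[[f]]
      if (any(v <= 0) || !(v["min"] <= v["median"] && v["median"] <= v["max"]))
        abort(sprintf("Invalid %s parameters for grade '%s': need 0 < min <= median <= max.", f, g))
    }
    if (gp$ct_pre["sd"] < 0) abort("ct_pre sd must be >= 0.")
    if (gp$necrosis_fraction < 0 || gp$necrosis_fraction >= 1)
      abort("necrosis_fraction must be in [0, 1).")
  }
  if (p$spacing_mm <= 0) abort("spacing_mm must be positive.")
  invisible(p)
}

# Log-normal draw parameterized by its median, with sigma set so the reported
# min-max range spans the central 99% of the distribution, then truncated to
# the range by rejection.
rlnorm_median_range <- function(n, median, min, max) {
  mu <- log(median)
  sigma <- (log(max) - log(min)) / (2 * qnorm(0.995))
  if (sigma <= 0) return(rep(median, n))
  out <- rlnorm(n, mu, sigma)
  bad <- which(out < min | out > max)
  while (length(bad) > 0) {
    out[bad] <- rlnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < min | out[bad] > max]
  }
  out
}

#' Generate one synthetic tumor phantom
#'
#' Draws patient-level traditional characteristics from the group-conditional
#' distributions, then renders a 2D elliptical tumor (random orientation) on a
#' uniform parenchyma background. The pre-contrast field inside the tumor is
#' the sampled patient CTpre plus a zero-mean Gaussian random field with
#' grade-dependent correlation length and SD; high-grade phantoms additionally
#' carry necrotic foci with reduced density. The in-mask field is recentred so
#' its mean equals the sampled CTpre exactly: the sampled value is, by
#' convention, the tumor's mean pre-contrast attenuation. The post-contrast
#' image adds the sampled enhancement on solid (non-necrotic) tumor pixels.
#'
#' @param grade `"low"` or `"high"`.
#' @param params A [default_cohort_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param patient_id Identifier stored in the phantom.
#' @return A list of class `tumor_phantom` with elements `patient_id`, `pre`,
#'   `post` (HU matrices), `mask`, `necrosis` (logical matrices), `spacing_mm`,
#'   `grade`, `sizes_true` (transverse/anteroposterior/craniocaudal, cm),
#'   `ct_pre_true`, `enhancement_true`, `orientation_rad`.
#' @export
generate_phantom <- function(grade = c("low", "high"),
                             params = default_cohort_params(),
                             seed = 1L,
                             patient_id = "P001") {
  grade <- match.arg(grade)
  validate_cohort_params(params)
  gp <- params[[grade]]
  n <- params$canvas_px
  px_per_cm <- 10 / params$spacing_mm

  with_seed(seed, {
    tr <- rlnorm_median_range(1, gp$size_transverse["median"],
                              gp$size_transverse["min"], gp$size_transverse["max"])
    ap <- rlnorm_median_range(1, gp$size_anteroposterior["median"],
                              gp$size_anteroposterior["min"], gp$size_anteroposterior["max"])
    cc <- rlnorm_median_range(1, gp$size_craniocaudal["median"],
                              gp$size_craniocaudal["min"], gp$size_craniocaudal["max"])
    ct_pre <- rnorm(1, gp$ct_pre["mean"], gp$ct_pre["sd"])
    enh <- rlnorm_median_range(1, gp$enhancement["median"],
                               gp$enhancement["min"], gp$enhancement["max"])
    theta <- runif(1, 0, pi)

    a <- tr * px_per_cm / 2   # semi-axis along the transverse (column) axis
    b <- ap * px_per_cm / 2   # semi-axis along the anteroposterior (row) axis
    if (2 * max(a, b) > n - 2)
      abort(sprintf("Tumor (%.1f px) exceeds the %d px canvas.", 2 * max(a, b), n))

    ctr <- (n + 1) / 2
    row <- matrix(seq_len(n) - ctr, n, n)
    col <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
    u <- col * cos(theta) + row * sin(theta)
    v <- -col * sin(theta) + row * cos(theta)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(mask)) abort("Degenerate tumor: empty mask.")

    field <- gp$texture_sd_hu * gaussian_field(n, n, gp$corr_length_px)

    necrosis <- matrix(FALSE, n, n)
    if (gp$necrosis_n > 0 && gp$necrosis_fraction > 0) {
      idx <- which(mask)
      r_blob <- sqrt(gp$necrosis_fraction * length(idx) / (gp$necrosis_n * pi))
      centers <- resample(idx, gp$necrosis_n, replace = length(idx) < gp$necrosis_n)
      for (cidx in centers) {
        cr <- (cidx - 1) %% n + 1
        cc_ <- (cidx - 1) %/% n + 1
        d2 <- (row - (cr - ctr))^2 + (col - (cc_ - ctr))^2
        necrosis <- necrosis | (d2 <= r_blob^2 & mask)
      }
    }

    pre <- matrix(params$background_hu, n, n)
    tumor_vals <- field[mask]
    tumor_vals[necrosis[mask]] <- tumor_vals[necrosis[mask]] - params$necrosis_offset_hu
    # calibration convention: sampled CTpre == mean in-mask attenuation
    tumor_vals <- tumor_vals - mean(tumor_vals) + ct_pre
    pre[mask] <- tumor_vals

    post <- pre
    solid <- mask & !necrosis
    post[solid] <- post[solid] + enh

    structure(list(
      patient_id = patient_id,
      pre = pre, post = post, mask = mask, necrosis = necrosis,
      spacing_mm = params$spacing_mm,
      grade = grade,
      sizes_true = c(transverse = unname(tr), anteroposterior = unname(ap),
                     craniocaudal = unname(cc)),
      ct_pre_true = unname(ct_pre),
      enhancement_true = unname(enh),
      orientation_rad = unname(theta),
      seed = as.integer(seed)
    ), class = "tumor_phantom")
  })
}

#' @export
print.tumor_phantom <- function(x, ...) {
  cat(sprintf("<tumor_phantom %s> grade=%s, %dx%d px @ %.2g mm, %d mask px\n",
              x$patient_id, x$grade, nrow(x$pre), ncol(x$pre), x$spacing_mm,
              sum(x$mask)))
  cat(sprintf("  sizes (cm): %.2f x %.2f x %.2f; CTpre %.1f HU; enhancement %.1f HU\n",
              x$sizes_true[1], x$sizes_true[2], x$sizes_true[3],
              x$ct_pre_true, x$enhancement_true))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Default sizes emulate the published series: 206 low-grade and 58 high-grade
#' patients. Per-patient sub-seeds are derived deterministically from the
#' master seed, so the whole cohort is a pure function of `(params, seed)`.
#'
#' @param n_low,n_high Patients per grade group.
#' @param params [default_cohort_params()] object.
#' @param seed Master integer seed.
#' @return A list of class `phantom_cohort`: `phantoms` (named list of
#'   [generate_phantom()] objects) and `truth` (tibble with patient_id, grade,
#'   true sizes, CTpre, enhancement, and the per-patient seed).
#' @export
generate_cohort <- function(n_low = 206L, n_high = 58L,
                            params = default_cohort_params(),
                            seed = 1L) {
  if (n_low < 0 || n_high < 0) abort("Group sizes must be non-negative.")
  n <- n_low + n_high
  grades <- rep(c("low", "high"), c(n_low, n_high))
  ids <- sprintf("P%04d", seq_len(n))
  phantoms <- vector("list", n)
  names(phantoms) <- ids
  for (i in seq_len(n)) {
    phantoms[[i]] <- generate_phantom(grades[i], params,
                                      seed = derive_seed(seed, i),
                                      patient_id = ids[i])
  }
  truth <- purrr::map_dfr(phantoms, function(ph) {
    tibble::tibble(
      patient_id = ph$patient_id,
      grade = ph$grade,
      transverse_cm = ph$sizes_true[["transverse"]],
      anteroposterior_cm = ph$sizes_true[["anteroposterior"]],
      craniocaudal_cm = ph$sizes_true[["craniocaudal"]],
      ct_pre_hu = ph$ct_pre_true,
      enhancement_hu = ph$enhancement_true,
      seed = ph$seed
    )
  })
  structure(list(phantoms = phantoms, truth = truth,
                 params = params, seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients (%d low, %d high), seed %d\n",
              nrow(x$truth), sum(x$truth$grade == "low"),
              sum(x$truth$grade == "high"), x$seed))
  invisible(x)
}

#' Split a cohort into training and validation sets
#'
#' Implements the 3:1 random split. With `stratified = TRUE` (default) the
#' split is drawn per grade stratum so the grade mix is preserved; per-stratum
#' training counts use round-half-up (e.g. 206/58 at 0.75 gives 155 + 44
#' training patients).
#'
#' @param truth A data frame with `patient_id` and `grade` columns (the
#'   cohort truth table), or a `phantom_cohort`.
#' @param ratio_train Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed for the permutation draw.
#' @param stratified Draw per grade stratum (default TRUE).
#' @return The input truth tibble with an added `cohort` column
#'   (`"training"`/`"validation"`).
#' @export
split_cohort <- function(truth, ratio_train = 0.75, seed = 1L,
                         stratified = TRUE) {
  if (inherits(truth, "phantom_cohort")) truth <- truth$truth
  truth <- tibble::as_tibble(truth)
  if (anyDuplicated(truth$patient_id)) abort("Duplicate patient ids.")
  if (!(ratio_train > 0 && ratio_train < 1))
    abort("`ratio_train` must be strictly inside (0, 1).")
  n <- nrow(truth)
  cohort <- rep(NA_character_, n)
  with_seed(seed, {
    strata <- if (stratified) split(seq_len(n), truth$grade) else list(all = seq_len(n))
    for (idx in strata) {
      if (length(idx) < 2) {
        warn("Stratum smaller than 2: assigning all to training.")
        cohort[idx] <- "training"
        next
      }
      n_train <- round_half_up(ratio_train * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- resample(idx, n_train)
      cohort[idx] <- ifelse(idx %in% train_idx, "training", "validation")
    }
  })
  dplyr::mutate(truth, cohort = factor(cohort, c("training", "validation")))
}

#' Perturb an ROI mask (second-reader simulation)
#'
#' Displaces the mask boundary by a seeded smooth random field scaled by
#' `magnitude` (pixels): the new mask is `{signed boundary distance +
#' magnitude * field > 0}`. Magnitude 0 returns the input unchanged, and for a
#' fixed seed the Dice overlap with the input is non-increasing in magnitude.
#'
#' @param mask Logical matrix.
#' @param magnitude Boundary displacement scale in pixels (>= 0).
#' @param seed Integer seed.
#' @return A perturbed logical mask of the same dimension.
#' @export
perturb_mask <- function(mask, magnitude = 1, seed = 1L) {
  assert_mask(mask)
  if (magnitude < 0) abort("`magnitude` must be >= 0.")
  if (magnitude == 0) return(mask)
  depth <- ceiling(magnitude) + 4L

  # signed band distance: +k-0.5 for pixels removed at the k-th erosion,
  # -(k-0.5) for pixels added at the k-th dilation, +/-Inf beyond the band
  d <- matrix(-Inf, nrow(mask), ncol(mask))
  d[mask] <- Inf
  inner <- mask
  outer <- mask
  for (k in seq_len(depth)) {
    inner2 <- erode4(inner)
    d[inner & !inner2] <- k - 0.5
    inner <- inner2
    outer2 <- dilate4(outer)
    d[outer2 & !outer] <- -(k - 0.5)
    outer <- outer2
  }

  eta <- with_seed(seed, gaussian_field(nrow(mask), ncol(mask), corr_length = 3))
  out <- (d + magnitude * eta) > 0
  if (!any(out)) abort("Perturbation emptied the mask.")
  out
}
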