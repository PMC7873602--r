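#' Normalize gray levels to a fixed bin count
#'
#' Gray-scale discretization used before texture extraction: with `mu`, `sigma`
#' the in-mask mean and SD, the window `[mu - sigma_mult*sigma,
#' mu + sigma_mult*sigma]` is mapped linearly onto integer levels
#' `1..n_bins` (values clipped to the window; half-open bins, top edge
#' closed). A constant ROI (`sigma = 0`) maps every pixel to the mid level
#' `ceiling(n_bins/2)` rather than erroring.
#'
#' @param image Numeric matrix in HU.
#' @param mask Logical matrix, same dimension, nonempty.
#' @param n_bins Number of gray levels (default 256).
#' @param sigma_mult Window half-width in SDs (default 3).
#' @return An object of class `discretized_image`: list with `levels`
#'   (integer matrix, `NA` outside the mask), `mask`, `n_bins`, `window`.
#' @export
normalize_gray_levels <- function(image, mask, n_bins = 256L, sigma_mult = 3) {
  assert_mask(mask, image)
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  if (any(!is.finite(image[mask]))) abort("Non-finite in-mask values.")
  x <- image[mask]
  mu <- mean(x); s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (length(x) == 1) s <- 0
  levels <- matrix(NA_integer_, nrow(image), ncol(image))
  if (s == 0) {
    levels[mask] <- as.integer(ceiling(n_bins / 2))
    window <- c(mu, mu)
  } else {
    lo <- mu - sigma_mult * s
    hi <- mu + sigma_mult * s
    xc <- pmin(pmax(x, lo), hi)
    lev <- 1L + as.integer(floor((xc - lo) / (hi - lo) * n_bins))
    lev[lev > n_bins] <- as.integer(n_bins)   # top edge closed
    levels[mask] <- lev
    window <- c(lo, hi)
  }
  structure(list(levels = levels, mask = mask,
                 n_bins = as.integer(n_bins), window = window),
            class = "discretized_image")
}

#' @export
print.discretized_image <- function(x, ...) {
  cat(sprintf("<discretized_image> %dx%d, Ng=%d, window [%.2f, %.2f], %d ROI px\n",
              nrow(x$levels), ncol(x$levels), x$n_bins,
              x$window[1], x$window[2], sum(x$mask)))
  invisible(x)
}

#' Select the representative axial slice from a 3D volume
#'
#' Returns the axial slice with the largest in-slice mask area (the slice
#' with the largest cross-sectional tumor measurement); ties are broken by
#' the lowest slice index.
#'
#' @param volume 3D numeric array (row, col, slice).
#' @param mask3d 3D logical array of the same dimension.
#' @return List with `image` (matrix), `mask` (matrix), `slice` (index).
#' @export
select_representative_slice <- function(volume, mask3d) {
  stopifnot(length(dim(volume)) == 3, identical(dim(volume), dim(mask3d)))
  if (!any(mask3d)) abort("Empty 3D mask.")
  areas <- apply(mask3d, 3, sum)
  k <- which.max(areas)  # which.max returns the first (lowest) maximizer
  list(image = volume[, , k], mask = mask3d[, , k], slice = k)
}

#' Measure tumor size from an ROI mask
#'
#' Transverse size is the horizontal (column) extent of the mask bounding box
#' and anteroposterior the vertical (row) extent, both scaled by pixel
#' spacing; the craniocaudal dimension of a 2D phantom is carried as
#' metadata. Mirroring the triplicate-measurement protocol, the measurement
#' is taken three times and averaged (identical for a deterministic mask).
#'
#' @param mask Logical matrix.
#' @param spacing_mm Pixel spacing in mm.
#' @param craniocaudal_cm Craniocaudal size metadata (cm), `NA` if unknown.
#' @return Tibble with `transverse_cm`, `anteroposterior_cm`,
#'   `craniocaudal_cm`.
#' @export
measure_tumor_size <- function(mask, spacing_mm = 1.0, craniocaudal_cm = NA_real_) {
  assert_mask(mask)
  one <- function() {
    idx <- which(mask, arr.ind = TRUE)
    c(tr = (diff(range(idx[, 2])) + 1) * spacing_mm / 10,
      ap = (diff(range(idx[, 1])) + 1) * spacing_mm / 10)
  }
  reps <- vapply(1:3, function(i) one(), numeric(2))
  tibble::tibble(
    transverse_cm = mean(reps["tr", ]),
    anteroposterior_cm = mean(reps["ap", ]),
    craniocaudal_cm = craniocaudal_cm
  )
}

#' Measure mean CT density with small circular ROIs
#'
#' Emulates the clinical protocol: a circular ROI of 0.2-1 cm^2 is placed on
#' the solid part of the tumor three times and the per-ROI mean attenuations
#' are averaged. ROI radii and centers are drawn with the given seed, and
#' each disk must lie fully inside the solid (necrosis-free) region.
#'
#' @param image HU matrix.
#' @param mask Tumor ROI (logical matrix).
#' @param solid_mask Necrosis-free region within which disks are placed
#'   (defaults to `mask`).
#' @param roi_area_cm2 Range of the circular ROI area (cm^2).
#' @param n_repeats Number of ROI placements averaged (default 3).
#' @param seed Integer seed.
#' @param spacing_mm Pixel spacing in mm.
#' @return Mean HU over the repeated ROIs (scalar).
#' @export
measure_density <- function(image, mask, solid_mask = mask,
                            roi_area_cm2 = c(0.2, 1.0), n_repeats = 3L,
                            seed = 1L, spacing_mm = 1.0) {
  assert_mask(mask, image)
  assert_mask(solid_mask, image)
  r_of_area <- function(a) sqrt(a / pi) * 10 / spacing_mm
  r_min <- r_of_area(roi_area_cm2[1])
  r_max <- r_of_area(roi_area_cm2[2])
  # work on the solid bounding box (padded by the largest disk) for speed
  idx <- which(solid_mask, arr.ind = TRUE)
  pad <- ceiling(r_max) + 1L
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(image), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(image), max(idx[, 2]) + pad)
  img <- image[r0:r1, c0:c1]
  solid <- solid_mask[r0:r1, c0:c1]
  if (!any(erode_disk(solid, r_min)))
    abort("Solid region too small for the minimum ROI disk.")
  with_seed(seed, {
    vals <- vapply(seq_len(n_repeats), function(i) {
      r <- r_of_area(runif(1, roi_area_cm2[1], roi_area_cm2[2]))
      centers <- which(erode_disk(solid, r))
      while (length(centers) == 0) {      # shrink toward the minimum disk
        r <- max(r_min, r * 0.8)
        centers <- which(erode_disk(solid, r))
      }
      ctr <- resample(centers, 1)
      cr <- (ctr - 1) %% nrow(img) + 1
      cc <- (ctr - 1) %/% nrow(img) + 1
      offs <- disk_offsets(r)
      mean(img[cbind(cr + offs[, 1], cc + offs[, 2])])
    }, numeric(1))
    mean(vals)
  })
}

#' Contrast enhancement
#'
#' @param ct_pre,ct_post Pre- and post-contrast densities (HU).
#' @return `ct_post - ct_pre`.
#' @export
compute_enhancement <- function(ct_pre, ct_post) ct_post - ct_pre

#' Derive T stage from tumor size
#'
#' T1 if the maximal dimension is at most 7 cm, else T2 (standard size
#' cutoff; only T1/T2 occur in this series).
#'
#' @param transverse_cm,anteroposterior_cm,craniocaudal_cm Sizes in cm.
#' @return Factor with levels `T1`, `T2`.
#' @export
t_stage <- function(transverse_cm, anteroposterior_cm, craniocaudal_cm) {
  mx <- pmax(transverse_cm, anteroposterior_cm, craniocaudal_cm, na.rm = TRUE)
  factor(ifelse(mx <= 7, "T1", "T2"), levels = c("T1", "T2"))
}

#' Traditional radiological feature table for a cohort
#'
#' Measures, per phantom, the tri-axial tumor size (bounding box + metadata),
#' the pre- and post-contrast densities via the circular-ROI protocol on the
#' solid part of the tumor, the enhancement, and the derived T stage.
#'
#' @param cohort A [generate_cohort()] object (or plain list of phantoms).
#' @param seed Integer seed for ROI placement.
#' @return Tibble with one row per patient: `patient_id`, sizes (cm),
#'   `ct_pre_hu`, `ct_post_hu`, `enhancement_hu`, `t_stage`.
#' @export
extract_traditional_features <- function(cohort, seed = 1L) {
  phantoms <- if (inherits(cohort, "phantom_cohort")) cohort$phantoms else cohort
  purrr::imap_dfr(phantoms, function(ph, i) {
    sizes <- measure_tumor_size(ph$mask, ph$spacing_mm,
                                ph$sizes_true[["craniocaudal"]])
    solid <- ph$mask & !ph$necrosis
    s <- derive_seed(seed, match(ph$patient_id, names(phantoms)), salt = 7L)
    pre <- measure_density(ph$pre, ph$mask, solid, seed = s,
                           spacing_mm = ph$spacing_mm)
    post <- measure_density(ph$post, ph$mask, solid, seed = s,
                            spacing_mm = ph$spacing_mm)
    dplyr::mutate(sizes,
      patient_id = ph$patient_id, .before = 1) |>
      dplyr::mutate(
        ct_pre_hu = pre,
        ct_post_hu = post,
        enhancement_hu = compute_enhancement(pre, post),
        t_stage = t_stage(sizes$transverse_cm, sizes$anteroposterior_cm,
                          sizes$craniocaudal_cm)
      )
  })
}
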