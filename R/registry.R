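#' Default texture feature registry
#'
#' The ordered manifest of the 340-feature default vector: 11 histogram +
#' 5 gradient + 5 autoregressive + 275 co-occurrence (11 features x (4
#' directions x 5 distances + 5 direction-averaged)) + 20 run-length (5
#' features x 4 directions) + 24 wavelet (4 subbands x 6 scales). Feature
#' names encode family, feature, direction and distance
#' (e.g. `glcm.d2.a45.Contrast`, `glrlm.a90.RLNonUni`, `wav.s3.WavEnHH`).
#'
#' @param distances Co-occurrence displacement lengths (default 1:5).
#' @param directions Directions in degrees (default `c(0, 45, 90, 135)`).
#' @param n_scales Wavelet scales (default 6).
#' @return A tibble of class `feature_registry` with columns `name`,
#'   `family`, `feature`, `direction`, `distance`.
#' @export
default_registry <- function(distances = 1:5,
                             directions = c(0, 45, 90, 135),
                             n_scales = 6L) {
  key <- paste(c(distances, "|", directions, "|", n_scales), collapse = ",")
  cached <- .registry_cache[[key]]
  if (!is.null(cached)) return(cached)
  rows <- list()
  add <- function(name, family, feature, direction = NA_real_, distance = NA_integer_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, family = family, feature = feature,
      direction = direction, distance = as.integer(distance))
  }
  hist_names <- c("Mean", "Variance", "Skewness", "Kurtosis", "Perc_01",
                  "Perc_10", "Perc_25", "Perc_50", "Perc_75", "Perc_90",
                  "Perc_99")
  for (f in hist_names) add(paste0("hist.", f), "histogram", f)
  for (f in c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros"))
    add(paste0("grad.", f), "gradient", f)
  for (f in c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma"))
    add(paste0("ar.", f), "autoregressive", f)
  for (dst in distances) {
    for (ang in directions) {
      for (f in glcm_feature_names)
        add(sprintf("glcm.d%d.a%d.%s", dst, ang, f), "glcm", f, ang, dst)
    }
    for (f in glcm_feature_names)
      add(sprintf("glcm.d%d.avg.%s", dst, f), "glcm", f, NA_real_, dst)
  }
  for (ang in directions) {
    for (f in c("ShrtREmp", "LngREmph", "GLevNonUni", "RLNonUni", "Fraction"))
      add(sprintf("glrlm.a%d.%s", ang, f), "glrlm", f, ang)
  }
  for (s in seq_len(n_scales)) {
    for (b in c("LL", "LH", "HL", "HH"))
      add(sprintf("wav.s%d.WavEn%s", s, b), "wavelet", paste0("WavEn", b), NA_real_, s)
  }
  reg <- dplyr::bind_rows(rows)
  if (anyDuplicated(reg$name)) abort("Registry names are not unique.")
  class(reg) <- c("feature_registry", class(reg))
  .registry_cache[[key]] <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Write / read the registry manifest (JSON)
#'
#' The manifest pins the exact feature composition of a run so every value in
#' a feature table is auditable.
#'
#' @param registry A [default_registry()] tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly (writer); the registry tibble (reader).
#' @export
write_registry_manifest <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_registry_manifest
#' @export
read_registry_manifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- tibble::as_tibble(df)
  reg$distance <- as.integer(reg$distance)
  class(reg) <- c("feature_registry", class(reg))
  reg
}

#' Extract the full texture feature vector for one ROI
#'
#' Discretizes the image over the mask ([normalize_gray_levels()]) and
#' evaluates every registry entry in manifest order. Infeasible cells (a
#' co-occurrence displacement with no in-mask pixel pair, an infeasible
#' wavelet scale) emit the sentinel value 0 with a `FALSE` validity flag, so
#' the vector length is stable for modeling. Family-level errors (e.g. an
#' ROI too small for the gradient or autoregressive fit) propagate.
#'
#' @param image HU matrix.
#' @param mask Logical ROI matrix.
#' @param registry Feature registry (default [default_registry()]).
#' @param n_bins Gray levels for discretization (default 256).
#' @param sigma_mult Discretization window half-width in SDs.
#' @return Named numeric vector ordered as the registry, with attribute
#'   `valid` (named logical vector).
#' @export
extract_all <- function(image, mask, registry = default_registry(),
                        n_bins = 256L, sigma_mult = 3) {
  d <- normalize_gray_levels(image, mask, n_bins, sigma_mult)
  fams <- unique(registry$family)
  values <- stats::setNames(numeric(nrow(registry)), registry$name)
  valid <- stats::setNames(rep(TRUE, nrow(registry)), registry$name)

  put <- function(prefix, vec, ok = NULL) {
    nm <- paste0(prefix, names(vec))
    present <- nm %in% names(values)
    values[nm[present]] <<- vec[present]
    if (!is.null(ok)) valid[nm[present]] <<- ok[present]
  }

  if ("histogram" %in% fams) put("hist.", histogram_features(d))
  if ("gradient" %in% fams) put("grad.", gradient_features(d))
  if ("autoregressive" %in% fams) put("ar.", ar_features(d))

  if ("glcm" %in% fams) {
    sub <- registry[registry$family == "glcm", ]
    for (dst in unique(stats::na.omit(sub$distance))) {
      dirs <- sort(unique(stats::na.omit(sub$direction[sub$distance == dst])))
      if (length(dirs) == 0) dirs <- c(0, 45, 90, 135)
      per_dir <- vector("list", length(dirs))
      for (k in seq_along(dirs)) {
        m <- glcm_compute(d, dirs[k], dst)
        fv <- if (is.null(m)) NULL else glcm_features(m)
        per_dir[[k]] <- fv
        pre <- sprintf("glcm.d%d.a%d.", dst, dirs[k])
        if (is.null(fv)) {
          zero <- stats::setNames(numeric(11), glcm_feature_names)
          put(pre, zero, ok = rep(FALSE, 11))
        } else {
          put(pre, fv)
        }
      }
      avg <- glcm_direction_average(per_dir)
      pre <- sprintf("glcm.d%d.avg.", dst)
      if (is.null(avg)) {
        put(pre, stats::setNames(numeric(11), glcm_feature_names),
            ok = rep(FALSE, 11))
      } else {
        put(pre, avg)
      }
    }
  }

  if ("glrlm" %in% fams) {
    sub <- registry[registry$family == "glrlm", ]
    for (ang in sort(unique(stats::na.omit(sub$direction)))) {
      put(sprintf("glrlm.a%d.", ang), glrlm_features(glrlm_compute(d, ang)))
    }
  }

  if ("wavelet" %in% fams) {
    n_scales <- max(registry$distance[registry$family == "wavelet"], na.rm = TRUE)
    wv <- wavelet_features(d, n_scales)
    put("wav.", wv, ok = attr(wv, "valid"))
  }

  attr(values, "valid") <- valid
  values
}

#' Texture feature table for a cohort
#'
#' Applies [extract_all()] to every phantom (pre-contrast image + mask) and
#' assembles the per-patient feature table.
#'
#' @param cohort A [generate_cohort()] object or named list of phantoms.
#' @param registry Feature registry.
#' @param n_bins,sigma_mult Discretization parameters.
#' @param masks Optional named list of replacement masks (e.g. perturbed
#'   second-reader masks), keyed by patient id.
#' @return Tibble: `patient_id` plus one column per registry feature;
#'   attribute `validity` holds the matching logical tibble.
#' @export
extract_texture_features <- function(cohort, registry = default_registry(),
                                     n_bins = 256L, sigma_mult = 3,
                                     masks = NULL) {
  phantoms <- if (inherits(cohort, "phantom_cohort")) cohort$phantoms else cohort
  res <- purrr::map(phantoms, function(ph) {
    m <- if (!is.null(masks)) masks[[ph$patient_id]] else ph$mask
    extract_all(ph$pre, m, registry, n_bins, sigma_mult)
  })
  tab <- tibble::as_tibble(do.call(rbind, res))
  tab <- dplyr::bind_cols(
    tibble::tibble(patient_id = unname(vapply(phantoms, `[[`, "", "patient_id"))),
    tab)
  validity <- tibble::as_tibble(do.call(rbind, purrr::map(res, attr, "valid")))
  attr(tab, "validity") <- dplyr::bind_cols(
    tibble::tibble(patient_id = tab$patient_id), validity)
  tab
}
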