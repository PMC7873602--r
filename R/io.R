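# Phantom image/mask writers and readers. NIfTI via RNifti (spacing carried
# in the header); 16-bit PNG with a JSON sidecar {spacing_mm, intercept} as
# a portable alternative. Both are optional dependencies.

#' Write a phantom's images and mask to disk
#'
#' @param phantom A [generate_phantom()] object.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` (`.nii.gz`, spacing in header) or `"png"` (16-bit
#'   PNG with JSON sidecar holding `spacing_mm` and the HU intercept).
#' @return The vector of files written, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, phantom$patient_id)
  files <- character(0)
  if (format == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      abort("The RNifti package is required for NIfTI output.")
    wr <- function(x, suffix) {
      path <- paste0(base, suffix, ".nii.gz")
      img <- RNifti::asNifti(x, pixdim = rep(phantom$spacing_mm, 2))
      RNifti::writeNifti(img, path)
      path
    }
    files <- c(wr(phantom$pre, "_pre"), wr(phantom$post, "_post"),
               wr(phantom$mask * 1L, "_mask"))
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      abort("The png package is required for PNG output.")
    # PNG stores [0,1]; HU are windowed to the joint range of both phases,
    # with intercept/slope recorded in the sidecar for exact rescaling
    lo <- min(phantom$pre, phantom$post)
    hi <- max(phantom$pre, phantom$post)
    slope <- max(hi - lo, 1)
    wr <- function(x, suffix, scale = TRUE) {
      path <- paste0(base, suffix, ".png")
      v <- if (scale) (x - lo) / slope else x
      png::writePNG(pmin(pmax(v, 0), 1), path)
      path
    }
    files <- c(wr(phantom$pre, "_pre"), wr(phantom$post, "_post"),
               wr(phantom$mask * 1, "_mask", scale = FALSE))
    sidecar <- paste0(base, ".json")
    jsonlite::write_json(list(patient_id = phantom$patient_id,
                              spacing_mm = phantom$spacing_mm,
                              intercept = lo, slope = slope),
                         sidecar, auto_unbox = TRUE)
    files <- c(files, sidecar)
  }
  invisible(files)
}

#' Read an image written by [write_phantom()]
#'
#' @param path `.nii`/`.nii.gz` or `.png` file.
#' @param sidecar JSON sidecar path for PNG input (defaults to
#'   `<patient>.json` next to the image).
#' @return List with `values` (matrix) and `spacing_mm`.
#' @export
read_image <- function(path, sidecar = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      abort("The RNifti package is required for NIfTI input.")
    img <- RNifti::readNifti(path)
    list(values = as.matrix(img), spacing_mm = RNifti::pixdim(img)[1])
  } else if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE))
      abort("The png package is required for PNG input.")
    if (is.null(sidecar))
      sidecar <- paste0(sub("_(pre|post|mask)\\.png$", "", path), ".json")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    v <- png::readPNG(path)
    if (grepl("_mask\\.png$", path)) {
      list(values = round(v), spacing_mm = meta$spacing_mm)
    } else {
      list(values = v * meta$slope + meta$intercept, spacing_mm = meta$spacing_mm)
    }
  } else {
    abort("Unsupported image format (use .nii/.nii.gz or .png).")
  }
}

#' Write a feature table (with validity flags) to CSV
#'
#' @param features A feature tibble from [extract_texture_features()] or
#'   [extract_traditional_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly. The validity table, when present, is written
#'   next to it as `<path>_validity.csv`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  v <- attr(features, "validity")
  if (!is.null(v))
    utils::write.csv(v, sub("\\.csv$", "_validity.csv", path), row.names = FALSE)
  invisible(path)
}
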