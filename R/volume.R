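#' 3D scalar volume container
#'
#' A light container for a 3D scalar image: the voxel grid, its spacing in
#' millimetres and a modality tag. All pipeline functions accept and return
#' `volume3d` objects so that grids and spacings travel together.
#'
#' @param data 3D numeric array of voxel intensities (finite values only).
#' @param spacing_mm Numeric length-3 voxel spacing in mm (per axis).
#' @param modality One of `"GRE"`, `"BB"`, `"SYNTH_BB"`, `"DL_BB"`, `"OTHER"`.
#' @return An object of class `volume3d` with fields `data`, `spacing_mm`,
#'   `intensity_range` and `modality`.
#' @export
volume3d <- function(data, spacing_mm = c(1, 1, 1), modality = "OTHER") {
  stop_if_not_3d(data)
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxels", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  modality <- match.arg(modality, c("GRE", "BB", "SYNTH_BB", "DL_BB", "OTHER"))
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         intensity_range = range(data), modality = modality),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

as_volume3d <- function(x, modality = "OTHER") {
  if (inherits(x, "volume3d")) x else volume3d(x, modality = modality)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param modality Modality tag to attach (see [volume3d()]).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = "OTHER") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  # tolerate trailing singleton dimensions, reject true 4D data
  d <- dim(a)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(a) <- d[1:3]
    } else {
      stop("expected a 3D image, got ", length(d), "D: ", path, call. = FALSE)
    }
  }
  stop_if_not_3d(a)
  if (!all(is.finite(a)))
    stop("volume contains non-finite voxels: ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  volume3d(a, spacing_mm = sp, modality = modality)
}

#' Write a 3D volume to a NIfTI file
#'
#' @param vol A [volume3d()] (or plain 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize volume intensities to the unit range
#'
#' Divides every voxel by the volume maximum so the output lies in `[0, 1]`
#' with maximum exactly 1, preserving the ordering of voxel values. An
#' optional robust mode divides by an upper percentile instead (then clips
#' to 1), for real data whose maximum may be a noise spike.
#'
#' @param vol A [volume3d()].
#' @param robust_percentile Either `NULL` (default: divide by the literal
#'   maximum) or a probability such as 0.999.
#' @return A [volume3d()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, robust_percentile = NULL) {
  vol <- as_volume3d(vol)
  if (is.null(robust_percentile)) {
    m <- max(vol$data)
    if (m <= 0)
      stop("degenerate input: volume maximum is not positive", call. = FALSE)
    out <- vol$data / m
  } else {
    stopifnot(robust_percentile > 0, robust_percentile <= 1)
    m <- quantile(vol$data, robust_percentile, names = FALSE)
    if (m <= 0)
      stop("degenerate input: normalization reference is not positive",
           call. = FALSE)
    out <- pmin(vol$data / m, 1)
    dim(out) <- dim(vol$data)
  }
  volume3d(out, spacing_mm = vol$spacing_mm, modality = vol$modality)
}
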