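#' Construct an intensity volume
#'
#' A 3D scalar image grid together with its physical geometry. The array is
#' indexed `(H, W, D)` with the depth (slice) axis last; `spacing` gives the
#' physical voxel size in millimetres along each axis and `origin` the world
#' position of the first voxel's corner.
#'
#' @param data Numeric 3D array (H x W x D).
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world offset in mm.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  data <- array(as.numeric(data), dim = dim(data))  # drop foreign attributes
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3L) stop("origin must have length 3")
  if (anyNA(data)) stop("volume contains NA/NaN values")
  structure(list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "intensity_volume")
}

#' Construct a label volume
#'
#' Integer segmentation labels on the same grid as a paired intensity volume:
#' 0 = background, 1 = tumor (meningioma core), 2 = surrounding FLAIR
#' hyperintensity (SNFH).
#'
#' @param labels Integer 3D array with values in {0, 1, 2}.
#' @inheritParams intensity_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (anyNA(labels)) stop("labels contain NA")
  lv <- as.integer(round(labels))
  if (max(abs(as.numeric(labels) - lv)) > 1e-6) stop("labels must be integral")
  if (!all(lv %in% 0:2)) {
    bad <- sort(unique(lv[!(lv %in% 0:2)]))
    stop("label volume contains values outside {0,1,2}: ", paste(bad, collapse = ", "))
  }
  arr <- array(lv, dim = dim(labels))
  structure(list(labels = arr, spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<label_volume> %s voxels (bg %d, tumor %d, snfh %d)\n",
              paste(dim(x$labels), collapse = "x"), tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/2 file (`.nii` or `.nii.gz`). Geometry (spacing, origin) is
#' taken from the header's xform. Label files are validated to contain only
#' the label set {0, 1, 2}.
#'
#' @param path Path to an existing NIfTI file.
#' @param type `"intensity"` (default) or `"label"`.
#' @return An [intensity_volume()] or [label_volume()].
#' @export
read_nifti <- function(path, type = c("intensity", "label")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) < 3L) stop("expected a 3D NIfTI volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  org <- if (!is.null(xf)) xf[1:3, 4] else c(0, 0, 0)
  if (type == "intensity") {
    if (anyNA(arr)) stop("NIfTI volume contains NaN: ", path)
    intensity_volume(arr, spacing = sp, origin = org)
  } else {
    label_volume(arr, spacing = sp, origin = org)
  }
}

#' Write a volume to NIfTI
#'
#' Writes an [intensity_volume()] or [label_volume()] so that [read_nifti()]
#' recovers identical data, spacing and origin.
#'
#' @param volume Volume object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(volume, path) {
  if (inherits(volume, "intensity_volume")) {
    arr <- volume$data
  } else if (inherits(volume, "label_volume")) {
    arr <- volume$labels
  } else stop("volume must be an intensity_volume or label_volume")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  xf <- diag(c(volume$spacing, 1))
  xf[1:3, 4] <- volume$origin
  RNifti::`sform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize a volume to zero mean and unit variance
#'
#' Statistics are computed over all voxels of the volume (background air
#' included), matching the preprocessing applied before segmentation
#' training. The standard deviation uses the population (1/N) convention so
#' that the output sd is exactly 1.
#'
#' @param vol An [intensity_volume()].
#' @return A normalized [intensity_volume()]; mean 0 and sd 1 within 1e-6.
#' @export
normalize_zmuv <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  x <- vol$data
  if (length(x) < 2L) stop("need at least 2 voxels to normalize")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("constant volume: zero variance, cannot normalize")
  intensity_volume((x - m) / s, spacing = vol$spacing, origin = vol$origin)
}

#' Pair an intensity volume with a segmentation mask
#'
#' Builds the renderer's non-scalar input: each voxel carries a 2-vector
#' (normalized intensity, mask value). The mask value in \[0, 1\] is obtained by
#' mapping each discrete label through `label_importance` (the g value fed to
#' the importance transfer function).
#'
#' @param intensity Normalized [intensity_volume()].
#' @param labels [label_volume()] on the same grid.
#' @param label_importance Named numeric: g for labels "0", "1", "2".
#' @return An object of class `non_scalar_volume` with fields `intensity`
#'   (the volume) and `mask` (numeric array of g values in \[0, 1\]).
#' @export
non_scalar_volume <- function(intensity, labels,
                              label_importance = c(`0` = 0.15, `1` = 1.0, `2` = 0.6)) {
  stopifnot(inherits(intensity, "intensity_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(intensity$data), dim(labels$labels)))
    stop("intensity and label shapes differ")
  if (any(label_importance < 0) || any(label_importance > 1))
    stop("label importance values must lie in [0,1]")
  key <- as.character(labels$labels)
  g <- label_importance[key]
  if (anyNA(g)) stop("label value missing from label_importance map")
  mask <- array(as.numeric(g), dim = dim(labels$labels))
  structure(list(intensity = intensity, mask = mask,
                 label_importance = label_importance),
            class = "non_scalar_volume")
}
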