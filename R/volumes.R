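#' Image volume and VOI mask containers
#'
#' `image_volume()` wraps a 3-D numeric array together with its voxel spacing
#' (mm) and world origin (mm, position of the centre of voxel `[1,1,1]`).
#' PET volumes are expected in SUV units (g/mL), CT volumes in HU.
#' `voi_mask()` is the binary counterpart used for volumes of interest; it
#' carries a `provenance` list recording how the mask was produced (e.g. the
#' segmentation threshold).
#'
#' @param data 3-D numeric (or logical for masks) array.
#' @param spacing Numeric length-3, voxel spacing in mm, all `> 0`.
#' @param origin Numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @param provenance Named list of free-form provenance for masks.
#' @return An object of class `image_volume` or `voi_mask`.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(vol$data)
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @export
voi_mask <- function(data, spacing, origin = c(0, 0, 0), provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) stop("mask must be binary", call. = FALSE)
  vol <- image_volume(data, spacing, origin)
  vol$provenance <- provenance
  class(vol) <- c("voi_mask", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
    class(x)[1], paste(dim(x$data), collapse = " x "),
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(signif(x$origin, 4), collapse = ", ")
  ))
  rng <- range(x$data)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param x An `image_volume` or `voi_mask`.
#' @param units `"mm3"` or `"ml"`.
#' @return Scalar voxel volume.
#' @export
voxel_volume <- function(x, units = c("mm3", "ml")) {
  units <- match.arg(units)
  v <- prod(x$spacing)
  if (units == "ml") v / 1000 else v
}

#' World coordinates of voxel centres
#'
#' Converts array indices (1-based `[i, j, k]`) to world mm coordinates.
#'
#' @param x An `image_volume`.
#' @param idx Integer matrix with 3 columns of voxel indices; defaults to all
#'   voxels in array order.
#' @return Numeric matrix (n x 3) of mm coordinates of voxel centres.
#' @export
voxel_world <- function(x, idx = NULL) {
  if (is.null(idx)) {
    d <- dim(x$data)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  }
  sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
}

#' Number of voxels inside a mask
#' @param mask A `voi_mask`.
#' @return Integer voxel count.
#' @export
mask_voxel_count <- function(mask) sum(mask$data != 0L)

#' Indices of in-mask voxels
#' @keywords internal
#' @noRd
mask_indices <- function(mask) {
  which(mask$data != 0L, arr.ind = TRUE)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(vol, mask) {
  if (!same_grid(vol, mask)) {
    stop("volume and mask are defined on different grids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' preserve the voxel spacing. Origins are stored in the NIfTI sform.
#'
#' @param x An `image_volume` or `voi_mask`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an `image_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  mat <- diag(4)
  diag(mat)[1:3] <- x$spacing
  mat[1:3, 4] <- x$origin
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3-D volume", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  image_volume(arr, spacing = sp, origin = orig)
}
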