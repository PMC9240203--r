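#' @importFrom stats coef cor dchisq dnorm dt lm median pchisq pt qt quantile
#'   rbinom rnorm runif sd var setNames
#' @importFrom utils head read.table write.table
NULL

#' 4-D BOLD time-series image
#'
#' A light container for a 4-D scalar field (x, y, z, t) together with the
#' grid-to-world affine and the repetition time (TR). World coordinates follow
#' the NIfTI convention: `world = affine %*% c(i, j, k, 1)` with zero-based
#' voxel indices.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param affine 4x4 grid-to-world matrix (mm). Defaults to 3 mm isotropic
#'   voxels centred on the grid.
#' @param tr Repetition time in seconds.
#' @return An object of class `ts_image`.
#' @export
ts_image <- function(data, affine = NULL, tr = 2) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4-D array (x, y, z, t)")
  if (is.null(affine)) affine <- default_affine(dim(data)[1:3], c(3, 3, 3))
  check_affine(affine)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive scalar (seconds)")
  structure(list(data = data, affine = affine, tr = tr), class = "ts_image")
}

#' 3-D brain mask
#'
#' @param data logical 3-D array.
#' @param affine 4x4 grid-to-world matrix shared with the images it masks.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  storage.mode(data) <- "logical"
  if (is.null(affine)) affine <- default_affine(dim(data), c(3, 3, 3))
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "brain_mask")
}

#' Per-voxel network-homogeneity map
#'
#' A 3-D scalar field defined on mask voxels; out-of-mask voxels carry `NA`.
#' The `stage` tag records how far along the NH transform chain the values
#' are: raw mean correlations (`raw_r`), Fisher z (`fisher_z`), or
#' subject-standardized (`standardized`).
#'
#' @param data 3-D numeric array, `NA` outside the mask.
#' @param affine 4x4 grid-to-world matrix.
#' @param stage one of `"raw_r"`, `"fisher_z"`, `"standardized"`.
#' @param subject_id optional subject identifier.
#' @return An object of class `nh_map`.
#' @export
nh_map <- function(data, affine, stage, subject_id = NA_character_) {
  stage <- match.arg(stage, c("raw_r", "fisher_z", "standardized"))
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  check_affine(affine)
  structure(list(data = data, affine = affine, stage = stage,
                 subject_id = subject_id), class = "nh_map")
}

default_affine <- function(shape, voxel_size) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  # centre the grid on the world origin, MNI-style
  aff[1:3, 4] <- -voxel_size * (shape - 1) / 2
  aff
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row of 'affine' must be (0, 0, 0, 1)")
  invisible(affine)
}

#' Voxel sizes implied by an affine
#'
#' @param affine 4x4 grid-to-world matrix.
#' @return length-3 numeric vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(affine) {
  check_affine(affine)
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Convert zero-based voxel indices to world (mm) coordinates
#'
#' @param ijk numeric vector of length 3 (zero-based voxel index) or an
#'   n x 3 matrix of indices.
#' @param affine 4x4 grid-to-world matrix.
#' @return world coordinates, same shape as the input.
#' @export
voxel_to_world <- function(ijk, affine) {
  check_affine(affine)
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  xyz <- ijk %*% t(affine[1:3, 1:3])
  xyz <- sweep(xyz, 2L, affine[1:3, 4], "+")
  if (nrow(xyz) == 1L) drop(xyz) else xyz
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_image> %d x %d x %d voxels, %d volumes, TR = %g s, voxels %s mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(signif(voxel_sizes(x$affine), 3), collapse = " x ")))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d voxels in mask\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' @export
print.nh_map <- function(x, ...) {
  cat(sprintf("<nh_map> stage '%s', %d mask voxels, subject %s\n",
              x$stage, sum(!is.na(x$data)), x$subject_id))
  invisible(x)
}

#' Read a 4-D NIfTI file as a `ts_image`
#'
#' The affine is taken from the sform/qform and the TR from `pixdim[4]`
#' (seconds). A TR stored elsewhere can be overridden with `tr`.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr optional TR override in seconds.
#' @return a [ts_image].
#' @export
read_ts_image <- function(path, tr = NULL) {
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) != 4L) stop("expected a 4-D image: ", path)
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (is.null(tr)) {
    pd <- RNifti::pixdim(nii)
    tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 2
  }
  ts_image(array(as.numeric(nii), dim = d), affine = aff, tr = tr)
}

#' Write a `ts_image` to NIfTI-1
#'
#' @param img a [ts_image].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_ts_image <- function(img, path) {
  stopifnot(inherits(img, "ts_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  RNifti::pixdim(nii) <- c(1, 1, 1, img$tr)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a 3-D NIfTI file as a `brain_mask`
#'
#' Voxels with values greater than `threshold` enter the mask.
#'
#' @param path NIfTI file.
#' @param threshold inclusion threshold (default 0.5 for 0/1 volumes).
#' @return a [brain_mask].
#' @export
read_brain_mask <- function(path, threshold = 0.5) {
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("expected a 3-D image: ", path)
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = c(4L, 4L))
  brain_mask(array(as.numeric(nii) > threshold, dim = d), affine = aff)
}

#' Write a `brain_mask` (as 0/1) or an `nh_map` to NIfTI-1
#'
#' For `nh_map`s the out-of-mask `NA` voxels are written as 0; the mask must
#' be shipped alongside for a lossless round trip.
#'
#' @param x a [brain_mask] or [nh_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "brain_mask")) {
    dat <- array(as.numeric(x$data), dim = dim(x$data))
  } else if (inherits(x, "nh_map")) {
    dat <- x$data
    dat[is.na(dat)] <- 0
  } else stop("unsupported volume type")
  nii <- RNifti::asNifti(dat)
  RNifti::sform(nii) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}
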