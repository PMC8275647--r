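#' 4-D BOLD image container
#'
#' Wraps a 4-D array (x, y, z, t) with its repetition time, a voxel-to-mm
#' affine (MNI RAS+ convention; the affine is authoritative for voxel/mm
#' mapping) and an in-brain mask. Volume timestamps are
#' `start_time + (k - 1) * tr` at volume onset.
#'
#' @param data 4-D numeric array.
#' @param tr Repetition time in seconds.
#' @param affine 4x4 voxel-to-mm matrix; default scales by `voxel_size` and
#'   centres the grid on the origin.
#' @param mask Logical 3-D array of in-brain voxels; default all TRUE.
#' @param voxel_size Isotropic voxel size in mm used for the default affine.
#' @param start_time Onset of the first retained volume in seconds.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, tr, affine = NULL, mask = NULL,
                       voxel_size = 2.5, start_time = 0) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("data must be a 4-D array")
  if (dim(data)[4] < 2L) stop("need at least 2 volumes")
  if (tr <= 0) stop("tr must be positive")
  d <- dim(data)[1:3]
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (d - 1) / 2
  }
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask dimensions must match the grid")
  structure(
    list(data = data, tr = tr, affine = affine, mask = mask,
         start_time = start_time),
    class = "bold_image"
  )
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %dx%dx%d grid, %d volumes, TR %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Volume onset times of a BOLD image
#' @param bold A [bold_image()].
#' @return Numeric vector of onsets in seconds.
#' @export
volume_times <- function(bold) {
  bold$start_time + (seq_len(dim(bold$data)[4]) - 1L) * bold$tr
}

# n_masked x t matrix of voxel time series (rows follow which(mask))
mask_matrix <- function(bold) {
  d <- dim(bold$data)
  m <- matrix(bold$data, prod(d[1:3]), d[4])
  m[which(bold$mask), , drop = FALSE]
}

# write a n_masked x t matrix back into the 4-D array
unmask_matrix <- function(m, bold) {
  d <- dim(bold$data)
  full <- matrix(0, prod(d[1:3]), d[4])
  full[which(bold$mask), ] <- m
  array(full, d)
}

# mm coordinates of all voxel centers, nvox x 3, in grid order
voxel_coords_mm <- function(dim3, affine) {
  g <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1,
                             j = seq_len(dim3[2]) - 1,
                             k = seq_len(dim3[3]) - 1))
  sweep(g %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' Read a 4-D NIfTI file as a BOLD image
#'
#' TR is taken from the NIfTI header (`pixdim[4]`) unless overridden.
#'
#' @param path NIfTI file path.
#' @param tr Optional TR override in seconds.
#' @param mask Optional logical 3-D mask.
#' @return A [bold_image()].
#' @export
read_bold <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  affine <- structure(RNifti::xform(img), class = "matrix")
  bold_image(as.array(img), tr = tr, affine = unclass(affine), mask = mask)
}

#' Write a BOLD image as NIfTI
#'
#' @param bold A [bold_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_bold <- function(bold, path) {
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(bold$data)
  img <- RNifti::`pixdim<-`(img, c(vs, bold$tr))
  img <- RNifti::`sform<-`(img, structure(bold$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Discard initial non-steady-state volumes
#'
#' Drops the first `n` volumes, allowing longitudinal magnetization to reach
#' a steady state, and shifts the volume clock accordingly.
#'
#' @param bold A [bold_image()].
#' @param n Number of volumes to discard (default 20).
#' @return A [bold_image()] with `t - n` volumes.
#' @export
discard_initial_volumes <- function(bold, n = 20L) {
  nt <- dim(bold$data)[4]
  if (nt <= n) stop("recording too short: ", nt, " volumes <= ", n)
  bold_image(bold$data[, , , (n + 1L):nt, drop = FALSE], tr = bold$tr,
             affine = bold$affine, mask = bold$mask,
             start_time = bold$start_time + n * bold$tr)
}
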