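#' Generate a binary tube volume
#'
#' Builds a segmented 3-D volume containing a solid cylinder of the stated
#' diameter running through the full z-extent of the array, standing in for a
#' segmented chromatin fiber from electron tomography. Optional salt-and-pepper
#' noise flips a fraction of voxels.
#'
#' @param diameter Cylinder diameter in nm (> 0).
#' @param length Cylinder length in nm (> 0); sets the z-extent.
#' @param voxel_size Voxel edge length in nm (> 0, < diameter).
#' @param noise_fraction Fraction of voxels flipped at random, in `[0, 1]`.
#' @param margin Voxels of background padding around the cylinder in x/y.
#' @param seed Integer seed (used only when `noise_fraction > 0`).
#' @return An object of class `binary_volume`: an integer 0/1 3-D array with
#'   attribute `voxel_size` (nm).
#' @export
generate_tube_volume <- function(diameter, length, voxel_size,
                                 noise_fraction = 0, margin = 4L, seed = 1L) {
  if (diameter <= 0) stop("diameter must be positive")
  if (length <= 0) stop("length must be positive")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (voxel_size >= diameter)
    stop("voxel_size must be smaller than the diameter (unresolvable tube)")
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must be in [0, 1]")
  r_vox <- diameter / 2 / voxel_size
  nxy <- ceiling(2 * r_vox) + 2L * margin
  nz <- max(1L, round(length / voxel_size))
  cx <- (nxy + 1) / 2
  x <- seq_len(nxy) - cx
  in_disc <- outer(x^2, x^2, `+`) <= r_vox^2
  vol <- array(0L, dim = c(nxy, nxy, nz))
  vol[rep(in_disc, nz)] <- 1L
  if (noise_fraction > 0) {
    rng <- local_rng(seed)
    flip <- rng$unif(length(vol)) < noise_fraction
    vol[flip] <- 1L - vol[flip]
  }
  binary_volume(vol, voxel_size)
}

#' Construct a binary volume object
#'
#' @param arr A 3-D array; nonzero entries are foreground.
#' @param voxel_size Voxel edge length in nm.
#' @return The array, as class `binary_volume` with a `voxel_size` attribute.
#' @export
binary_volume <- function(arr, voxel_size) {
  stopifnot(length(dim(arr)) == 3, voxel_size > 0)
  out <- array(as.integer(arr != 0), dim = dim(arr))
  attr(out, "voxel_size") <- voxel_size
  class(out) <- "binary_volume"
  out
}

#' Read/write binary volumes as NIfTI
#'
#' Uses the RNifti package (if installed) to persist a volume with its voxel
#' size in the image header.
#' @param vol A `binary_volume`.
#' @param path Output `.nii` path.
#' @export
write_volume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for volume I/O")
  v <- attr(vol, "voxel_size")
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- c(v, v, v)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for volume I/O")
  img <- RNifti::readNifti(path)
  binary_volume(array(img > 0.5, dim = dim(img)), RNifti::pixdim(img)[1])
}
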