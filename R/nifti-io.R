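# NIfTI-1 I/O. RNifti handles the format; here we only reconcile its
# spatial-first layout with the package's channel-first convention and
# carry the voxel-to-world affine through.

#' Read a NIfTI file as a meta_image
#'
#' 3D volumes gain a singleton leading channel dimension; 4D volumes are
#' reordered so the 4th (time/channel) axis comes first. The stored
#' voxel-to-world affine and pixel dimensions are kept; no orientation
#' harmonisation is attempted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param dtype Optional dtype tag override (e.g. `"int32"` for labels
#'   stored as floats).
#' @return A `meta_image`.
#' @export
read_meta_image <- function(path, dtype = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  nd <- length(dim(arr))
  if (nd == 2L) {
    data <- array(arr, dim = c(1L, dim(arr)))
    spatial_nd <- 2L
  } else if (nd == 3L) {
    data <- array(arr, dim = c(1L, dim(arr)))
    spatial_nd <- 3L
  } else if (nd == 4L) {
    data <- aperm(arr, c(4L, 1L, 2L, 3L))
    spatial_nd <- 3L
  } else {
    stop("unsupported NIfTI dimensionality: ", nd, call. = FALSE)
  }
  xf <- structure(RNifti::xform(nii), class = NULL)
  world <- diag(spatial_nd + 1)
  if (spatial_nd == 3L) {
    world <- matrix(as.numeric(xf), 4L, 4L)
  } else {
    world[1:2, 1:2] <- matrix(as.numeric(xf), 4L, 4L)[1:2, 1:2]
    world[1:2, 3L] <- matrix(as.numeric(xf), 4L, 4L)[1:2, 4L]
  }
  make_meta_image(data, world_affine = world, dtype = dtype)
}

#' Write a meta_image to NIfTI
#'
#' Singleton channels are dropped; multi-channel 3D images are written as
#' 4D volumes with channels in the 4th axis. The world affine is stored as
#' both sform and qform. Pending operations are applied first so the file
#' matches what the metadata describes.
#'
#' @param img A `meta_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_meta_image <- function(img, path) {
  stopifnot(is_meta_image(img))
  img <- apply_all(img)
  nchan <- n_channels(img)
  nd <- img_ndim(img)
  arr <- if (nchan == 1L) {
    array(img$data, dim = spatial_shape(img))
  } else {
    aperm(img$data, c(seq_len(nd) + 1L, 1L))
  }
  world <- img$world_affine
  xf <- diag(4)
  if (nd == 3L) {
    xf <- world
  } else {
    xf[1:2, 1:2] <- spatial_block(world)
    xf[1:2, 4L] <- translation_part(world)
  }
  nii <- RNifti::asNifti(arr)
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
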