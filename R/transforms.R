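# The transform vocabulary. Every spatial transform shares one contract:
# describe the operation as a pending_op (pull-convention matrix over
# centred coordinates); if lazy, just append it; if eager, append it and
# immediately apply everything pending. Interpolation defaults to linear
# for float images and nearest for integer (label) images.

default_interp <- function(img, interpolation) {
  if (!is.null(interpolation)) return(interpolation)
  if (is_integer_dtype(img$dtype)) "nearest" else "linear"
}

finish_op <- function(img, matrix_or_grid, out_shape, lazy, interpolation,
                      padding, name) {
  op <- pending_op(matrix_or_grid,
                   input_shape = effective_shape(img),
                   output_shape = out_shape,
                   input_dtype = img$dtype,
                   output_dtype = img$dtype,
                   interpolation_mode = default_interp(img, interpolation),
                   padding_mode = padding,
                   source_name = name)
  img <- push_pending(img, op)
  if (!lazy) img <- apply_all(img)
  img
}

#' Rotate an image about its centre
#'
#' Appends a pending rotation (pull matrix = inverse of the content
#' rotation; with centred coordinates the centre-shift conjugation is
#' implicit). The output extents equal the input extents, so corners may
#' leave the field of view and are filled per `padding`.
#'
#' @param img A `meta_image`.
#' @param angles Radians: one angle for 2D images, three for 3D (angle `i`
#'   rotates the plane orthogonal to spatial axis `i`).
#' @param lazy If `FALSE`, all pending operations (including this one) are
#'   applied immediately.
#' @param interpolation,padding Sampling modes recorded on the operation;
#'   `interpolation = NULL` picks linear for float data, nearest for
#'   integer data.
#' @export
lz_rotate <- function(img, angles, lazy = TRUE, interpolation = NULL,
                      padding = "zeros") {
  nd <- length(effective_shape(img))
  need <- if (nd == 2L) 1L else 3L
  if (length(angles) != need) {
    stop("rotate needs ", need, " angle(s) for a ", nd, "D image, got ",
         length(angles), call. = FALSE)
  }
  finish_op(img, rotation_pull(nd, angles), effective_shape(img),
            lazy, interpolation, padding, "rotate")
}

#' Rotate by quarter turns in an axis plane
#'
#' Exactly orthogonal (integer) matrix; for odd `k` the two plane extents
#' swap in the output shape. Lossless when applied.
#'
#' @inheritParams lz_rotate
#' @param k Number of quarter turns, 0 to 3.
#' @param plane Pair of spatial axes spanning the rotation plane.
#' @export
lz_rotate90 <- function(img, k = 1L, plane = c(1L, 2L), lazy = TRUE,
                        interpolation = NULL, padding = "zeros") {
  nd <- length(effective_shape(img))
  plane <- as.integer(plane)
  if (length(plane) != 2L || anyDuplicated(plane) ||
      any(plane < 1L) || any(plane > nd)) {
    stop("plane must be two distinct spatial axes in 1..", nd, call. = FALSE)
  }
  if (!(as.integer(k) %in% 0:3)) stop("k must be in 0..3", call. = FALSE)
  shape <- effective_shape(img)
  out_shape <- shape
  if (as.integer(k) %% 2L == 1L) {
    out_shape[plane] <- shape[rev(plane)]
  }
  finish_op(img, rotate90_pull(nd, k, plane), out_shape,
            lazy, interpolation, padding, "rotate90")
}

#' Flip spatial axes
#'
#' Pending diagonal +/-1 matrix; lossless when applied (pure value
#' permutation).
#'
#' @inheritParams lz_rotate
#' @param axes Integer vector of spatial axes to reverse (may be empty).
#' @export
lz_flip <- function(img, axes, lazy = TRUE, interpolation = NULL,
                    padding = "zeros") {
  nd <- length(effective_shape(img))
  axes <- as.integer(axes)
  if (any(axes < 1L) || any(axes > nd)) {
    stop("axes must be spatial axes in 1..", nd, call. = FALSE)
  }
  finish_op(img, affine_flip(nd, axes), effective_shape(img),
            lazy, interpolation, padding, "flip")
}

#' Zoom by per-axis scale factors
#'
#' Pull matrix with spatial diagonal `1/factors`. By default the output
#' extents follow the scale (`round(extent * factor)`, half away from
#' zero, minimum 1); with `keep_shape = TRUE` the extents are kept and the
#' image is zoomed about its centre.
#'
#' @inheritParams lz_rotate
#' @param factors Positive scale factor(s), recycled across axes.
#' @param keep_shape Keep the input extents instead of rescaling them.
#' @export
lz_zoom <- function(img, factors, keep_shape = FALSE, lazy = TRUE,
                    interpolation = NULL, padding = "zeros") {
  nd <- length(effective_shape(img))
  factors <- rep_len(as.numeric(factors), nd)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("zoom factors must be positive and finite", call. = FALSE)
  }
  shape <- effective_shape(img)
  out_shape <- if (keep_shape) {
    shape
  } else {
    pmax(1, round_half_away(shape * factors))
  }
  finish_op(img, affine_scale(1 / factors), out_shape,
            lazy, interpolation, padding, "zoom")
}

#' Translate by per-axis voxel offsets
#'
#' Content moves by `+offsets`; the pull matrix carries `-offsets`. Output
#' extents are unchanged, so eagerly applied translations destroy the
#' voxels pushed outside the field of view (the classic
#' translate-then-translate-back failure that lazy composition avoids).
#'
#' @inheritParams lz_rotate
#' @param offsets Finite per-axis offsets in voxels.
#' @export
lz_translate <- function(img, offsets, lazy = TRUE, interpolation = NULL,
                         padding = "zeros") {
  nd <- length(effective_shape(img))
  offsets <- rep_len(as.numeric(offsets), nd)
  if (any(!is.finite(offsets))) stop("offsets must be finite", call. = FALSE)
  finish_op(img, affine_translation(-offsets), effective_shape(img),
            lazy, interpolation, padding, "translate")
}

#' Resample to a target physical spacing
#'
#' Scale factors are `current_spacing / target_spacing` per axis (current
#' spacing is the [effective_spacing()], i.e. it accounts for pending
#' operations); extents rescale accordingly and the stored voxel spacing
#' is updated when the operation is applied.
#'
#' @inheritParams lz_rotate
#' @param target_spacing Positive per-axis spacing in mm.
#' @export
lz_spacing <- function(img, target_spacing, lazy = TRUE,
                       interpolation = NULL, padding = "zeros") {
  nd <- length(effective_shape(img))
  target_spacing <- rep_len(as.numeric(target_spacing), nd)
  cur <- effective_spacing(img)
  if (any(!is.finite(cur)) || any(cur <= 0)) {
    stop("current voxel spacing is unknown or non-positive", call. = FALSE)
  }
  if (any(target_spacing <= 0)) {
    stop("target spacing must be positive", call. = FALSE)
  }
  factors <- cur / target_spacing
  shape <- effective_shape(img)
  finish_op(img, affine_scale(1 / factors),
            pmax(1, round_half_away(shape * factors)),
            lazy, interpolation, padding, "spacing")
}

#' Crop a patch as a lazily-resized viewport
#'
#' The pending operation is a pure translation with `output_shape = size`:
#' output voxel `j` (0-based) maps to input voxel `start + j`. No data is
#' destroyed until the pending list is applied, so later transforms can
#' still recover content outside the window. The window may extend beyond
#' the input; `padding` covers the excess at apply time.
#'
#' @inheritParams lz_rotate
#' @param start 0-based per-axis voxel index of the window corner (may be
#'   negative).
#' @param size Per-axis window extents, all `>= 1`.
#' @export
lz_crop_patch <- function(img, start, size, lazy = TRUE,
                          interpolation = NULL, padding = "zeros") {
  nd <- length(effective_shape(img))
  start <- rep_len(as.numeric(start), nd)
  size <- rep_len(as.integer(size), nd)
  if (any(size < 1L)) stop("patch size must be >= 1 per axis", call. = FALSE)
  shape <- effective_shape(img)
  shift <- start + (size - 1) / 2 - (shape - 1) / 2
  finish_op(img, affine_translation(shift), size,
            lazy, interpolation, padding, "crop_patch")
}

#' Resize to target extents
#'
#' Equivalent to a zoom with per-axis factors `target / input` and the
#' output shape overridden to exactly `target_shape`.
#'
#' @inheritParams lz_rotate
#' @param target_shape Integer extents, all `>= 1`.
#' @export
lz_resize <- function(img, target_shape, lazy = TRUE, interpolation = NULL,
                      padding = "zeros") {
  nd <- length(effective_shape(img))
  target_shape <- rep_len(as.integer(target_shape), nd)
  if (any(target_shape < 1L)) stop("target extents must be >= 1", call. = FALSE)
  shape <- effective_shape(img)
  finish_op(img, affine_scale(shape / target_shape), target_shape,
            lazy, interpolation, padding, "resize")
}

# ---- randomised transforms -------------------------------------------------
# Parameters are drawn from a dedicated stream (seed) BEFORE delegating to
# the deterministic op, so the same seed yields identical geometry whether
# the transform executes lazily or eagerly.

#' Randomised rotation
#'
#' Draws uniform angles in `[-range, range]` per rotation plane with
#' probability `prob` (identity otherwise), then delegates to
#' [lz_rotate()]. The draw depends only on `seed`, never on the `lazy`
#' flag, so lazy and traditional runs share their randomness.
#'
#' @inheritParams lz_rotate
#' @param range Non-negative half-width of the angle range (radians).
#' @param prob Probability of applying a non-identity draw.
#' @param seed Integer seed for the transform's private stream.
#' @name rand_transforms
#' @export
lz_rand_rotate <- function(img, range = pi / 12, prob = 1, seed = 0L,
                           lazy = TRUE, interpolation = NULL,
                           padding = "zeros") {
  if (range < 0) stop("range must be >= 0", call. = FALSE)
  nd <- length(effective_shape(img))
  nang <- if (nd == 2L) 1L else 3L
  angles <- with_seed(seed, {
    if (stats::runif(1) < prob) stats::runif(nang, -range, range)
    else rep(0, nang)
  })
  lz_rotate(img, angles, lazy = lazy, interpolation = interpolation,
            padding = padding)
}

#' @rdname rand_transforms
#' @param zoom_range Length-2 positive range for the isotropic zoom factor.
#' @export
lz_rand_zoom <- function(img, zoom_range = c(0.9, 1.1), prob = 1, seed = 0L,
                         lazy = TRUE, interpolation = NULL,
                         padding = "zeros") {
  if (length(zoom_range) != 2L || any(zoom_range <= 0) ||
      zoom_range[2L] < zoom_range[1L]) {
    stop("zoom_range must be an increasing positive pair", call. = FALSE)
  }
  factor <- with_seed(seed, {
    if (stats::runif(1) < prob) stats::runif(1, zoom_range[1L], zoom_range[2L])
    else 1
  })
  lz_zoom(img, factor, lazy = lazy, interpolation = interpolation,
          padding = padding)
}

#' @rdname rand_transforms
#' @export
lz_rand_flip <- function(img, prob = 0.5, seed = 0L, lazy = TRUE,
                         interpolation = NULL, padding = "zeros") {
  nd <- length(effective_shape(img))
  axes <- with_seed(seed, which(stats::runif(nd) < prob))
  lz_flip(img, axes, lazy = lazy, interpolation = interpolation,
          padding = padding)
}

#' @rdname rand_transforms
#' @param plane Axis pair for the quarter-turn rotation.
#' @export
lz_rand_rotate90 <- function(img, prob = 1, plane = c(1L, 2L), seed = 0L,
                             lazy = TRUE, interpolation = NULL,
                             padding = "zeros") {
  k <- with_seed(seed, {
    if (stats::runif(1) < prob) sample(0:3, 1L) else 0L
  })
  lz_rotate90(img, k, plane = plane, lazy = lazy,
              interpolation = interpolation, padding = padding)
}

#' Add Gaussian noise (deliberately non-lazy)
#'
#' Noise cannot currently be described as a pending spatial operation, so
#' this transform operates on concrete data: any pending operations are
#' applied first (in a compiled pipeline the compiler inserts the
#' ApplyPending stage instead), then iid `N(0, sigma^2)` noise is added.
#'
#' @inheritParams lz_rotate
#' @param sigma Noise standard deviation, `>= 0`.
#' @param seed Integer seed for the noise field.
#' @export
lz_add_noise <- function(img, sigma, seed = 0L) {
  stopifnot(is_meta_image(img), sigma >= 0)
  img <- apply_all(img)
  if (sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(length(img$data), sd = sigma))
    img$data <- img$data + array(noise, dim = dim(img$data))
    if (is_integer_dtype(img$dtype)) {
      img$data <- cast_dtype(img$data, img$dtype)
    }
  }
  img
}

#' Invert an applied-transform record
#'
#' Returns the [pending_op()] that undoes the record: the matrix inverse
#' with input and output geometry swapped and the sampling modes of the
#' forward operation preserved. Because a trace record describes a whole
#' composed group, the inverse of a lazily merged chain is a single
#' matrix.
#'
#' @param rec A [trace_record()] whose operation is an invertible matrix.
#' @export
invert_record <- function(rec) {
  stopifnot(inherits(rec, "trace_record"))
  op <- rec$pending
  if (is_vector_grid(op$operation)) {
    stop("NotInvertible: vector-grid operations cannot be inverted",
         call. = FALSE)
  }
  s <- spatial_block(op$operation)
  if (abs(det(s)) < 1e-12) {
    stop("NotInvertible: singular transform matrix", call. = FALSE)
  }
  pending_op(solve(op$operation),
             input_shape = op$output_shape,
             output_shape = op$input_shape,
             input_dtype = op$output_dtype,
             output_dtype = op$input_dtype,
             interpolation_mode = op$interpolation_mode,
             padding_mode = op$padding_mode,
             source_name = paste0("inv(", op$source_name, ")"))
}
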