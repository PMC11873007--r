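# Data model: metadata-carrying images, pending transform descriptions and
# applied-transform traces.

.dtype_tags <- c("float32", "float64", "uint8", "int16", "int32", "int64")
.int_dtypes <- c("uint8", "int16", "int32", "int64")

is_integer_dtype <- function(dtype) dtype %in% .int_dtypes

check_dtype <- function(dtype) {
  if (!dtype %in% .dtype_tags) {
    stop("unknown dtype tag '", dtype, "'; expected one of ",
         paste(.dtype_tags, collapse = ", "), call. = FALSE)
  }
  dtype
}

#' Per-voxel displacement grid
#'
#' A dense alternative to a homogeneous matrix: an array of shape
#' `c(out_shape, N)` giving, for every output voxel, the centred input
#' coordinate to sample. Grids always force a resample and never merge with
#' neighbouring operations.
#'
#' @param vectors Numeric array with `N + 1` dimensions, the last of extent
#'   `N` (the coordinate components).
#' @return A `vector_grid` object.
#' @export
vector_grid <- function(vectors) {
  stopifnot(is.array(vectors), is.numeric(vectors))
  nd <- length(dim(vectors)) - 1L
  if (!(nd %in% c(2L, 3L)) || dim(vectors)[nd + 1L] != nd) {
    stop("vector grid must have shape c(out_shape, N) with N spatial dims",
         call. = FALSE)
  }
  structure(list(vectors = vectors,
                 shape = dim(vectors)[seq_len(nd)]),
            class = "vector_grid")
}

is_vector_grid <- function(x) inherits(x, "vector_grid")

#' Pending transform description
#'
#' One lazy spatial operation recorded on an image instead of being
#' executed: a homogeneous matrix (pull convention, centred coordinates) or
#' a [vector_grid()], plus the input/output geometry and the sampling
#' parameters that the eventual resample must honour.
#'
#' @param operation Homogeneous affine matrix or a [vector_grid()].
#' @param input_shape,output_shape Integer spatial extents (all `>= 1`).
#' @param input_dtype,output_dtype Element datatype tags; one of
#'   `"float32"`, `"float64"`, `"uint8"`, `"int16"`, `"int32"`, `"int64"`.
#' @param interpolation_mode `"linear"` or `"nearest"`.
#' @param padding_mode `"zeros"`, `"border"` or `"reflection"`.
#' @param source_name Free-text identifier of the emitting transform.
#' @return A `pending_op` object.
#' @export
pending_op <- function(operation, input_shape, output_shape,
                       input_dtype = "float64",
                       output_dtype = input_dtype,
                       interpolation_mode = c("linear", "nearest"),
                       padding_mode = c("zeros", "border", "reflection"),
                       source_name = "") {
  interpolation_mode <- match.arg(interpolation_mode)
  padding_mode <- match.arg(padding_mode)
  input_shape <- as.integer(input_shape)
  output_shape <- as.integer(output_shape)
  if (any(input_shape < 1L) || any(output_shape < 1L)) {
    stop("all shape entries must be >= 1", call. = FALSE)
  }
  check_dtype(input_dtype); check_dtype(output_dtype)
  if (is_vector_grid(operation)) {
    if (!identical(as.integer(operation$shape), output_shape)) {
      stop("vector grid spatial shape (",
           paste(operation$shape, collapse = "x"),
           ") must equal output_shape (",
           paste(output_shape, collapse = "x"), ")", call. = FALSE)
    }
    if (length(operation$shape) != length(input_shape)) {
      stop("grid dimensionality does not match input_shape", call. = FALSE)
    }
  } else {
    assert_affine(operation, "operation")
    if (affine_ndim(operation) != length(input_shape)) {
      stop("matrix dimensionality (", affine_ndim(operation),
           ") does not match shape dimensionality (",
           length(input_shape), ")", call. = FALSE)
    }
  }
  if (length(input_shape) != length(output_shape)) {
    stop("input_shape and output_shape must have equal length", call. = FALSE)
  }
  structure(list(operation = operation,
                 input_shape = input_shape,
                 input_dtype = input_dtype,
                 output_shape = output_shape,
                 output_dtype = output_dtype,
                 interpolation_mode = interpolation_mode,
                 padding_mode = padding_mode,
                 source_name = source_name),
            class = "pending_op")
}

#' Record of an applied transform
#'
#' Stored on an image when a composed group of pending operations is
#' executed; enables inversion of the whole applied pipeline.
#'
#' @param pending The [pending_op()] as actually applied (for a merged
#'   group, the composed matrix and the group's end-to-end shapes).
#' @param extra List of parameters needed to undo non-matrix effects.
#' @export
trace_record <- function(pending, extra = list()) {
  stopifnot(inherits(pending, "pending_op"))
  structure(list(pending = pending, extra = extra), class = "trace_record")
}

#' Create a metadata-carrying image
#'
#' Wraps a channel-first numeric array together with its voxel-to-world
#' affine, per-axis spacing, the list of pending (not yet executed)
#' transform descriptions and the trace of applied transforms.
#'
#' @param data Numeric array, channel-first: `C x spatial...` with 2 or 3
#'   spatial dimensions.
#' @param world_affine Optional homogeneous matrix mapping 0-based voxel
#'   indices to physical coordinates (mm). Defaults to a diagonal matrix
#'   built from `spacing`.
#' @param spacing Optional per-axis physical spacing (mm). Derived from
#'   `world_affine` column norms when omitted; if both are given they must
#'   agree.
#' @param dtype Element datatype tag; defaults to `"float64"` for double
#'   storage and `"int32"` for integer storage.
#' @return A `meta_image` with empty `pending` and `trace` lists.
#' @examples
#' img <- make_meta_image(array(0, c(1, 8, 8)))
#' effective_shape(img)
#' @export
make_meta_image <- function(data, world_affine = NULL, spacing = NULL,
                            dtype = NULL) {
  if (!is.array(data) || !is.numeric(data)) {
    stop("data must be a numeric array", call. = FALSE)
  }
  nd <- length(dim(data)) - 1L
  if (!(nd %in% c(2L, 3L))) {
    stop("data must be channel-first with 2 or 3 spatial dimensions ",
         "(got ", nd, " spatial dims); reshape e.g. a H x W matrix to ",
         "c(1, H, W)", call. = FALSE)
  }
  if (dim(data)[1L] < 1L) stop("data must have >= 1 channel", call. = FALSE)
  if (is.null(dtype)) {
    dtype <- if (is.integer(data)) "int32" else "float64"
  }
  check_dtype(dtype)
  if (is.null(world_affine)) {
    if (is.null(spacing)) spacing <- rep(1, nd)
    stopifnot(length(spacing) == nd, all(spacing > 0))
    world_affine <- affine_scale(spacing)
  } else {
    assert_affine(world_affine, "world_affine")
    stopifnot(affine_ndim(world_affine) == nd)
    col_norms <- sqrt(colSums(spatial_block(world_affine)^2))
    if (is.null(spacing)) {
      spacing <- col_norms
    } else if (any(abs(spacing - col_norms) > 1e-6 * pmax(1, col_norms))) {
      stop("spacing (", paste(signif(spacing, 6), collapse = ", "),
           ") disagrees with world_affine column norms (",
           paste(signif(col_norms, 6), collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(data = data,
                 world_affine = world_affine,
                 voxel_spacing = as.numeric(spacing),
                 dtype = dtype,
                 pending = list(),
                 trace = list()),
            class = "meta_image")
}

is_meta_image <- function(x) inherits(x, "meta_image")

spatial_shape <- function(img) as.integer(dim(img$data)[-1L])

n_channels <- function(img) dim(img$data)[1L]

img_ndim <- function(img) length(dim(img$data)) - 1L

#' Effective spatial shape of an image
#'
#' The shape the data will have once all pending operations are applied:
#' the last pending operation's `output_shape`, or the data's spatial
#' shape when nothing is pending.
#'
#' @param img A `meta_image`.
#' @export
effective_shape <- function(img) {
  stopifnot(is_meta_image(img))
  n <- length(img$pending)
  if (n == 0L) spatial_shape(img) else img$pending[[n]]$output_shape
}

#' Effective voxel spacing of an image
#'
#' Spacing implied by the world affine after carrying it through the
#' pending operations' index-space matrices (column norms of the projected
#' affine). Equals `voxel_spacing` when nothing is pending.
#'
#' @param img A `meta_image`.
#' @export
effective_spacing <- function(img) {
  stopifnot(is_meta_image(img))
  w <- img$world_affine
  for (op in img$pending) {
    if (is_vector_grid(op$operation)) {
      stop("effective spacing is undefined through a vector-grid operation",
           call. = FALSE)
    }
    w <- w %*% index_matrix(op$operation, op$input_shape, op$output_shape)
  }
  sqrt(colSums(spatial_block(w)^2))
}

#' Append a pending operation to an image
#'
#' Extends the pending list by one description; the data array is not
#' touched. The operation's `input_shape` must match the image's current
#' [effective_shape()].
#'
#' @param img A `meta_image`.
#' @param op A [pending_op()].
#' @export
push_pending <- function(img, op) {
  stopifnot(is_meta_image(img), inherits(op, "pending_op"))
  eff <- effective_shape(img)
  if (!identical(as.integer(eff), op$input_shape)) {
    stop("pending-op shape chain mismatch: image effective shape is (",
         paste(eff, collapse = "x"), ") but op '", op$source_name,
         "' expects input (", paste(op$input_shape, collapse = "x"), ")",
         call. = FALSE)
  }
  log_event("describe", op$source_name)
  img$pending[[length(img$pending) + 1L]] <- op
  img
}

#' Validate the internal invariants of a meta_image
#'
#' Checks the shape chain (first pending op consumes the data's spatial
#' shape, each subsequent op consumes its predecessor's output) and the
#' classes of the pending and trace entries. Errors on the first
#' violation, returns the image invisibly otherwise.
#'
#' @param img A `meta_image`.
#' @export
validate_meta_image <- function(img) {
  stopifnot(is_meta_image(img))
  cur <- spatial_shape(img)
  for (i in seq_along(img$pending)) {
    op <- img$pending[[i]]
    if (!inherits(op, "pending_op")) {
      stop("pending[[", i, "]] is not a pending_op", call. = FALSE)
    }
    if (!identical(op$input_shape, cur)) {
      stop("shape chain broken at pending[[", i, "]]: expected input (",
           paste(cur, collapse = "x"), "), found (",
           paste(op$input_shape, collapse = "x"), ")", call. = FALSE)
    }
    cur <- op$output_shape
  }
  for (i in seq_along(img$trace)) {
    if (!inherits(img$trace[[i]], "trace_record")) {
      stop("trace[[", i, "]] is not a trace_record", call. = FALSE)
    }
  }
  invisible(img)
}

#' @export
print.meta_image <- function(x, ...) {
  cat("<meta_image> ", n_channels(x), " channel(s), spatial ",
      paste(spatial_shape(x), collapse = "x"),
      ", dtype ", x$dtype,
      ", spacing (", paste(signif(x$voxel_spacing, 4), collapse = ", "),
      ") mm\n", sep = "")
  cat("  pending: ", length(x$pending), " op(s); trace: ",
      length(x$trace), " record(s)\n", sep = "")
  invisible(x)
}

#' @export
print.pending_op <- function(x, ...) {
  kind <- if (is_vector_grid(x$operation)) "grid" else "matrix"
  cat("<pending_op '", x$source_name, "'> ", kind, ", (",
      paste(x$input_shape, collapse = "x"), ") -> (",
      paste(x$output_shape, collapse = "x"), "), ",
      x$interpolation_mode, "/", x$padding_mode, "\n", sep = "")
  invisible(x)
}
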