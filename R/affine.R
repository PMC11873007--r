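# Homogeneous (N+1)x(N+1) matrices over centred voxel coordinates.
#
# Conventions used throughout the package:
#   * pull convention: a transform matrix maps OUTPUT voxel coordinates to
#     INPUT voxel coordinates (resampling iterates output voxels);
#   * coordinates sit at voxel centres with the origin at the array centre:
#     0-based index i corresponds to coordinate i - (extent - 1) / 2;
#   * composition in pipeline order is right-multiplication (see
#     compose_affine()).

#' Identity homogeneous matrix
#'
#' @param ndim Number of spatial dimensions (2 or 3).
#' @return An `(ndim+1) x (ndim+1)` identity matrix.
#' @export
affine_identity <- function(ndim) {
  stopifnot(ndim %in% c(2L, 3L))
  diag(ndim + 1)
}

#' Test whether a matrix is a valid homogeneous affine
#'
#' A valid matrix is square, `(N+1) x (N+1)` with N in {2, 3}, and its last
#' row equals `[0, ..., 0, 1]` within `tol`.
#'
#' @param m Matrix to test.
#' @param tol Absolute tolerance on the last row.
#' @export
is_affine_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) return(FALSE)
  n <- nrow(m)
  if (n != ncol(m) || !(n %in% c(3L, 4L))) return(FALSE)
  all(abs(m[n, ] - c(rep(0, n - 1L), 1)) <= tol)
}

assert_affine <- function(m, what = "matrix") {
  if (!is_affine_matrix(m)) {
    stop(what, " is not a valid homogeneous affine matrix ",
         "((N+1)x(N+1), last row [0,...,0,1], N in {2,3})", call. = FALSE)
  }
  invisible(m)
}

affine_ndim <- function(m) nrow(m) - 1L

#' @rdname affine_parts
#' @export
spatial_block <- function(m) {
  n <- nrow(m)
  m[seq_len(n - 1L), seq_len(n - 1L), drop = FALSE]
}

#' Spatial block and translation of a homogeneous matrix
#'
#' `spatial_block()` returns the top-left `N x N` linear part;
#' `translation_part()` the length-`N` translation column.
#'
#' @param m Homogeneous affine matrix.
#' @name affine_parts
#' @export
translation_part <- function(m) {
  n <- nrow(m)
  m[seq_len(n - 1L), n]
}

#' Elementary homogeneous matrices
#'
#' Constructors for translation, per-axis scaling and axis flips in the
#' centred-coordinate convention. These are building blocks for the lazy
#' transforms; they carry no pull/push meaning by themselves.
#'
#' @param offsets,factors Numeric vector, one entry per spatial axis.
#' @param ndim Number of spatial dimensions.
#' @param axes Integer vector of spatial axes to negate.
#' @name affine_elementary
#' @export
affine_translation <- function(offsets) {
  n <- length(offsets)
  m <- diag(n + 1)
  m[seq_len(n), n + 1L] <- as.numeric(offsets)
  m
}

#' @rdname affine_elementary
#' @export
affine_scale <- function(factors) {
  diag(c(as.numeric(factors), 1))
}

#' @rdname affine_elementary
#' @export
affine_flip <- function(ndim, axes) {
  d <- rep(1, ndim)
  d[axes] <- -1
  affine_scale(d)
}

# Forward (content) rotation matrix acting on centred coordinates.
# 2D: one angle; 3D: three angles, angle[i] rotating the plane orthogonal
# to axis i, composed as R3 %*% R2 %*% R1.
rotation_forward <- function(ndim, angles) {
  if (ndim == 2L) {
    stopifnot(length(angles) == 1L)
    c1 <- cos(angles); s1 <- sin(angles)
    r <- matrix(c(c1, s1, -s1, c1), 2L, 2L)
  } else {
    stopifnot(length(angles) == 3L)
    plane_rot <- function(a, b, th) {
      r <- diag(3)
      r[a, a] <- cos(th); r[b, b] <- cos(th)
      r[a, b] <- -sin(th); r[b, a] <- sin(th)
      r
    }
    r <- plane_rot(1L, 2L, angles[3L]) %*%
      plane_rot(1L, 3L, angles[2L]) %*%
      plane_rot(2L, 3L, angles[1L])
  }
  m <- diag(ndim + 1)
  m[seq_len(ndim), seq_len(ndim)] <- r
  m
}

# Pull-convention rotation: inverse (= transpose) of the forward rotation.
rotation_pull <- function(ndim, angles) {
  t(rotation_forward(ndim, angles))
}

# Exact pull-convention quarter-turn rotation in a given axis plane.
# Entries are exact integers so the matrix classifies as a signed
# permutation without tolerance games.
rotate90_pull <- function(ndim, k, plane) {
  k <- as.integer(k) %% 4L
  cs <- c(1L, 0L, -1L, 0L)[k + 1L]
  sn <- c(0L, 1L, 0L, -1L)[k + 1L]
  m <- diag(ndim + 1)
  a <- plane[1L]; b <- plane[2L]
  m[a, a] <- cs; m[a, b] <- sn
  m[b, a] <- -sn; m[b, b] <- cs
  m
}

#' Compose two homogeneous transforms in pipeline order
#'
#' Both matrices use the pull convention (output voxel coordinates to input
#' voxel coordinates). `compose_affine(a, b)` returns the matrix of the
#' pipeline "apply `a`, then apply `b`": an output coordinate of `b` is
#' mapped by `b` into `a`'s output space and by `a` into the original input
#' space, i.e. the product `a %*% b`. The operation is associative, so a
#' whole pipeline composes by left-to-right reduction.
#'
#' @param a,b Homogeneous affine matrices of equal dimension.
#' @return The composed homogeneous matrix (double precision).
#' @export
compose_affine <- function(a, b) {
  assert_affine(a, "a"); assert_affine(b, "b")
  stopifnot(nrow(a) == nrow(b))
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  a %*% b
}

#' Convert a centred-coordinate matrix to 0-based index space
#'
#' The resampler and the dispatch classifier operate on the index-space
#' form `T(off_in) %*% m %*% T(-off_out)` where `off = (extent - 1) / 2`,
#' which maps 0-based output indices directly to 0-based input indices.
#'
#' @param m Pull-convention matrix over centred coordinates.
#' @param in_shape,out_shape Integer spatial extents of input and output.
#' @export
index_matrix <- function(m, in_shape, out_shape) {
  off_in <- (in_shape - 1) / 2
  off_out <- (out_shape - 1) / 2
  affine_translation(off_in) %*% m %*% affine_translation(-off_out)
}

# Round half away from zero; the package's fixed rule for converting
# fractional extents (zoom/resize/spacing) to integer output shapes.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
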