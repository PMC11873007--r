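# Universal resampler: compose pending operations into minimal groups and
# execute each group with the cheapest correct mechanism.
#
# Dispatch logic: a composed matrix whose spatial block is a signed
# permutation and whose index-space translation is integral can be executed
# purely by axis permutation, reversal, slicing and padding (exact, bit
# preserving). An axis-aligned matrix with non-integer scale or translation
# needs interpolation, as does any matrix with off-axis terms; both are
# served by the same pull-convention resampling kernel.

#' Classify a composed transform for dispatch
#'
#' @param m Pull-convention homogeneous matrix (centred coordinates).
#' @param in_shape,out_shape Optional spatial extents. When supplied, the
#'   integrality of the translation is judged in 0-based index space (the
#'   space the executor actually indexes); this matters when input and
#'   output extents have different parity.
#' @param tol Absolute tolerance on matrix entries.
#' @return `"exact_op"`, `"axis_interp"` or `"full_resample"`.
#' @export
classify_affine <- function(m, in_shape = NULL, out_shape = NULL,
                            tol = 1e-5) {
  assert_affine(m)
  s <- spatial_block(m)
  nz <- abs(s) > tol
  axis_aligned <- all(rowSums(nz) == 1L) && all(colSums(nz) == 1L)
  if (!axis_aligned) return("full_resample")
  unit_scale <- all(abs(abs(s[nz]) - 1) <= tol)
  tt <- if (is.null(in_shape)) {
    translation_part(m)
  } else {
    translation_part(index_matrix(m, in_shape, out_shape))
  }
  integer_translation <- all(abs(tt - round(tt)) <= tol)
  if (unit_scale && integer_translation) "exact_op" else "axis_interp"
}

#' Greedily group a pending-operation list for composed execution
#'
#' Walks the list left to right, merging each operation into the current
#' group (matrix product in pipeline order, output geometry taken from the
#' last member) while it is compatible: matrix-based, and sharing the
#' group's interpolation mode, padding mode and output dtype. An
#' incompatible operation closes the group and opens a new one; vector-grid
#' operations always form singleton groups.
#'
#' @param pending List of [pending_op()] objects forming a valid shape
#'   chain.
#' @return List of composed groups (internal structure; one entry per
#'   eventual resample or exact operation).
#' @export
build_groups <- function(pending) {
  groups <- list()
  cur <- NULL
  close_group <- function() {
    if (!is.null(cur)) groups[[length(groups) + 1L]] <<- cur
  }
  for (op in pending) {
    grid <- is_vector_grid(op$operation)
    compatible <- !is.null(cur) && !grid && is.null(cur$grid) &&
      identical(op$interpolation_mode, cur$interpolation_mode) &&
      identical(op$padding_mode, cur$padding_mode) &&
      identical(op$output_dtype, cur$out_dtype)
    if (compatible) {
      cur$matrix <- compose_affine(cur$matrix, op$operation)
      cur$out_shape <- op$output_shape
      cur$members <- c(cur$members, op$source_name)
    } else {
      close_group()
      cur <- list(matrix = if (grid) NULL else op$operation,
                  grid = if (grid) op$operation else NULL,
                  in_shape = op$input_shape,
                  out_shape = op$output_shape,
                  in_dtype = op$input_dtype,
                  out_dtype = op$output_dtype,
                  interpolation_mode = op$interpolation_mode,
                  padding_mode = op$padding_mode,
                  members = op$source_name)
    }
  }
  close_group()
  groups
}

# 0-based index vector handling for the three padding policies.
# zeros: out-of-range positions become NA (value 0 after gather);
# border: clamp to the edge voxel; reflection: mirror about the edges
# without repeating the edge sample (period 2 * (n - 1)).
reflect_index0 <- function(i, n) {
  if (n == 1L) return(rep(0, length(i)))
  p <- 2 * (n - 1)
  r <- ((i %% p) + p) %% p
  ifelse(r >= n, p - r, r)
}

pad_index0 <- function(i, n, mode) {
  switch(mode,
    zeros = ifelse(i < 0 | i >= n, NA_real_, i),
    border = pmin(pmax(i, 0), n - 1),
    reflection = reflect_index0(i, n),
    stop("unsupported padding mode '", mode, "'", call. = FALSE))
}

# Flat 0-based spatial offset from per-axis 0-based index vectors.
spatial_offset0 <- function(idx_list, in_shape) {
  off <- idx_list[[1L]]
  mult <- in_shape[1L]
  for (a in seq_along(idx_list)[-1L]) {
    off <- off + mult * idx_list[[a]]
    mult <- mult * in_shape[a]
  }
  off
}

cast_dtype <- function(x, dtype) {
  if (is_integer_dtype(dtype)) {
    x <- round(x)
    storage.mode(x) <- "integer"
  }
  x
}

#' Execute an exact-class group by pure array manipulation
#'
#' Axis permutation, axis reversal, integer slicing and padding only; no
#' arithmetic touches the values, so the result is bit-exact. Guarded:
#' calling it on a group that does not classify as `exact_op` is an
#' internal error.
#'
#' @param data Channel-first array.
#' @param group A composed group from [build_groups()].
#' @export
apply_exact <- function(data, group) {
  nd <- length(group$in_shape)
  in_shape <- group$in_shape
  out_shape <- group$out_shape
  a_idx <- index_matrix(group$matrix, in_shape, out_shape)
  s <- spatial_block(a_idx)
  tt <- translation_part(a_idx)
  perm <- integer(nd); sgn <- numeric(nd)
  for (a in seq_len(nd)) {
    r <- which(abs(s[, a]) > 0.5)
    if (length(r) != 1L || abs(abs(s[r, a]) - 1) > 1e-4) {
      stop("internal: apply_exact called on a non-exact group", call. = FALSE)
    }
    perm[a] <- r
    sgn[a] <- round(s[r, a])
  }
  if (anyDuplicated(perm) ||
      any(abs(tt - round(tt)) > 1e-4)) {
    stop("internal: apply_exact called on a non-exact group", call. = FALSE)
  }
  tt <- round(tt)
  data_p <- aperm(data, c(1L, 1L + perm))
  ivs <- vector("list", nd)
  for (a in seq_len(nd)) {
    n_in <- in_shape[perm[a]]
    idx0 <- sgn[a] * (0:(out_shape[a] - 1L)) + tt[perm[a]]
    ivs[[a]] <- pad_index0(idx0, n_in, group$padding_mode) + 1
  }
  out <- do.call(`[`, c(list(data_p), list(TRUE), ivs, list(drop = FALSE)))
  if (anyNA(out)) out[is.na(out)] <- if (is.integer(out)) 0L else 0
  cast_dtype(out, group$out_dtype)
}

#' Resample a composed group with the general pull-convention kernel
#'
#' For every output voxel the input is sampled at the matrix-mapped (or
#' grid-supplied) coordinate with the group's interpolation and padding
#' modes. Linear interpolation gathers the 2^N corner voxels; nearest
#' resolves half-way ties toward the lower input index, so it only ever
#' reproduces values present in the input.
#'
#' @param data Channel-first array.
#' @param group A composed group from [build_groups()].
#' @export
resample <- function(data, group) {
  nd <- length(group$in_shape)
  in_shape <- as.numeric(group$in_shape)
  out_shape <- group$out_shape
  nchan <- dim(data)[1L]
  nvox <- prod(out_shape)
  if (!is.null(group$grid)) {
    off_in <- (in_shape - 1) / 2
    gm <- matrix(group$grid$vectors, nrow = nvox, ncol = nd)
    src <- t(gm) + off_in  # recycles off_in down rows
  } else {
    a_idx <- index_matrix(group$matrix, group$in_shape, out_shape)
    coords <- matrix(1, nd + 1L, nvox)
    for (a in seq_len(nd)) {
      each <- prod(out_shape[seq_len(a - 1L)])
      coords[a, ] <- rep(0:(out_shape[a] - 1L), each = each,
                         length.out = nvox)
    }
    src <- (a_idx %*% coords)[seq_len(nd), , drop = FALSE]
  }
  mode <- group$interpolation_mode
  pad <- group$padding_mode
  if (mode == "nearest") {
    idx <- vector("list", nd)
    zero <- rep(FALSE, nvox)
    for (a in seq_len(nd)) {
      ni <- ceiling(src[a, ] - 0.5)  # half-way ties toward the lower index
      pi <- pad_index0(ni, in_shape[a], pad)
      if (pad == "zeros") {
        bad <- is.na(pi)
        zero <- zero | bad
        pi[bad] <- 0
      }
      idx[[a]] <- pi
    }
    off <- spatial_offset0(idx, in_shape)
    outm <- matrix(vector(typeof(data), nchan * nvox), nchan, nvox)
    for (ch in seq_len(nchan)) {
      outm[ch, ] <- data[ch + nchan * off]
    }
    if (any(zero)) outm[, zero] <- if (is.integer(outm)) 0L else 0
  } else if (mode == "linear") {
    i0 <- floor(src)
    fr <- src - i0
    outm <- matrix(0, nchan, nvox)
    for (corner in 0:(2L^nd - 1L)) {
      w <- rep(1, nvox)
      idx <- vector("list", nd)
      zero <- rep(FALSE, nvox)
      for (a in seq_len(nd)) {
        hi <- bitwAnd(corner, bitwShiftL(1L, a - 1L)) > 0L
        ia <- i0[a, ] + as.numeric(hi)
        w <- w * if (hi) fr[a, ] else 1 - fr[a, ]
        pi <- pad_index0(ia, in_shape[a], pad)
        if (pad == "zeros") {
          bad <- is.na(pi)
          zero <- zero | bad
          pi[bad] <- 0
        }
        idx[[a]] <- pi
      }
      if (any(zero)) w[zero] <- 0
      off <- spatial_offset0(idx, in_shape)
      for (ch in seq_len(nchan)) {
        outm[ch, ] <- outm[ch, ] + w * data[ch + nchan * off]
      }
    }
  } else {
    stop("unsupported interpolation mode '", mode, "'", call. = FALSE)
  }
  out <- array(outm, dim = c(nchan, out_shape))
  cast_dtype(out, group$out_dtype)
}

group_name <- function(group) paste(group$members, collapse = "+")

#' Apply all pending operations of an image
#'
#' Implements the composed application algorithm: pending operations are
#' grouped greedily ([build_groups()]), each group is classified
#' ([classify_affine()]) and executed by [apply_exact()] or [resample()],
#' the pending list is emptied, one [trace_record()] per group is appended
#' (with the dispatch class in `extra`), and the world affine and voxel
#' spacing are updated by the applied index-space matrix.
#'
#' @param img A `meta_image`; returned unchanged when nothing is pending.
#' @export
apply_all <- function(img) {
  stopifnot(is_meta_image(img))
  if (length(img$pending) == 0L) return(img)
  validate_meta_image(img)
  groups <- build_groups(img$pending)
  data <- img$data
  w <- img$world_affine
  for (g in groups) {
    cls <- if (is.null(g$grid)) {
      classify_affine(g$matrix, g$in_shape, g$out_shape)
    } else {
      "full_resample"
    }
    bump("resample_events")
    log_event("resample", group_name(g))
    if (cls == "exact_op") {
      data <- apply_exact(data, g)
      bump("exact_events")
      log_event("exact_op", group_name(g))
    } else {
      data <- resample(data, g)
      bump("interpolation_events")
      log_event("interp", group_name(g))
    }
    if (is.null(g$grid)) {
      w <- w %*% index_matrix(g$matrix, g$in_shape, g$out_shape)
    }
    rec <- trace_record(
      pending_op(if (is.null(g$grid)) g$matrix else g$grid,
                 input_shape = g$in_shape,
                 output_shape = g$out_shape,
                 input_dtype = g$in_dtype,
                 output_dtype = g$out_dtype,
                 interpolation_mode = g$interpolation_mode,
                 padding_mode = g$padding_mode,
                 source_name = group_name(g)),
      extra = list(dispatch = cls))
    img$trace[[length(img$trace) + 1L]] <- rec
    img$dtype <- g$out_dtype
  }
  img$data <- data
  img$world_affine <- w
  img$voxel_spacing <- sqrt(colSums(spatial_block(w)^2))
  img$pending <- list()
  img
}
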