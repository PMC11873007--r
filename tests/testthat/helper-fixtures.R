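# Shared fixtures and independent oracles for the test suite.

# Channel-first ramp image: values 1..prod(shape), deterministic.
ramp_image <- function(shape, dtype = "float64") {
  data <- array(as.numeric(seq_len(prod(shape))), dim = c(1L, shape))
  if (dtype %in% c("uint8", "int16", "int32", "int64")) {
    storage.mode(data) <- "integer"
  }
  make_meta_image(data, dtype = dtype)
}

random_image <- function(shape, seed = 1L, channels = 1L) {
  set.seed(seed)
  make_meta_image(array(stats::rnorm(channels * prod(shape)),
                        dim = c(channels, shape)))
}

random_label_image <- function(shape, seed = 1L, n_classes = 3L) {
  set.seed(seed)
  data <- array(sample(0:n_classes, prod(shape), replace = TRUE),
                dim = c(1L, shape))
  make_meta_image(data, dtype = "int32")
}

# Brute-force per-pixel 2D resampler, independent of the package kernel:
# double loop over output pixels, scalar interpolation, scalar padding.
ref_pad_px <- function(data_2d, i, j, pad) {
  n1 <- nrow(data_2d); n2 <- ncol(data_2d)
  reflect1 <- function(i, n) {
    if (n == 1L) return(0)
    p <- 2 * (n - 1)
    r <- ((i %% p) + p) %% p
    if (r >= n) p - r else r
  }
  if (pad == "zeros") {
    if (i < 0 || i >= n1 || j < 0 || j >= n2) return(0)
  } else if (pad == "border") {
    i <- min(max(i, 0), n1 - 1); j <- min(max(j, 0), n2 - 1)
  } else {
    i <- reflect1(i, n1); j <- reflect1(j, n2)
  }
  data_2d[i + 1, j + 1]
}

ref_resample_2d <- function(data_2d, m, out_shape, interp, pad) {
  a_idx <- index_matrix(m, dim(data_2d), out_shape)
  out <- matrix(0, out_shape[1], out_shape[2])
  for (j2 in 0:(out_shape[2] - 1)) {
    for (j1 in 0:(out_shape[1] - 1)) {
      src <- as.numeric(a_idx %*% c(j1, j2, 1))[1:2]
      if (interp == "nearest") {
        ni <- ceiling(src - 0.5)
        out[j1 + 1, j2 + 1] <- ref_pad_px(data_2d, ni[1], ni[2], pad)
      } else {
        i0 <- floor(src); f <- src - i0
        acc <- 0
        for (b1 in 0:1) for (b2 in 0:1) {
          w <- (if (b1) f[1] else 1 - f[1]) * (if (b2) f[2] else 1 - f[2])
          acc <- acc + w * ref_pad_px(data_2d, i0[1] + b1, i0[2] + b2, pad)
        }
        out[j1 + 1, j2 + 1] <- acc
      }
    }
  }
  out
}

# Independent compose-then-single-resample oracle: composes pending
# matrices with a plain left-to-right product and executes one resample of
# the whole chain through the general kernel (no grouping, no dispatch).
oracle_single_resample <- function(img) {
  stopifnot(length(img$pending) > 0)
  m <- diag(length(spatial_shape(img)) + 1)
  for (op in img$pending) m <- m %*% op$operation
  last <- img$pending[[length(img$pending)]]
  group <- list(matrix = m, grid = NULL,
                in_shape = spatial_shape(img),
                out_shape = last$output_shape,
                in_dtype = img$dtype, out_dtype = last$output_dtype,
                interpolation_mode = last$interpolation_mode,
                padding_mode = last$padding_mode,
                members = "oracle")
  resample(img$data, group)
}

# The rotate/zoom chain whose composition is the identity.
identity_chain <- function(img) {
  img <- lz_rotate(img, pi / 4)
  img <- lz_zoom(img, 1.25)
  img <- lz_rotate(img, 22 * pi / 180)
  img <- lz_rotate(img, -22 * pi / 180)
  img <- lz_zoom(img, 0.8)
  lz_rotate(img, -pi / 4)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("lzr")
  dir.create(d, recursive = TRUE)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
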