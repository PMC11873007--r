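test_that("the resampling kernel matches a brute-force per-pixel reference", {
  set.seed(31)
  for (case in 1:12) {
    shape <- sample(4:9, 2, replace = TRUE)
    out_shape <- sample(3:10, 2, replace = TRUE)
    data <- array(stats::rnorm(prod(shape)), dim = c(1L, shape))
    th <- stats::runif(1, -pi, pi)
    m <- compose_affine(
      lazyresample:::rotation_pull(2L, th),
      compose_affine(affine_scale(stats::runif(2, 0.6, 1.6)),
                     affine_translation(stats::runif(2, -2, 2))))
    interp <- sample(c("linear", "nearest"), 1)
    pad <- sample(c("zeros", "border", "reflection"), 1)
    group <- list(matrix = m, grid = NULL, in_shape = shape,
                  out_shape = out_shape, in_dtype = "float64",
                  out_dtype = "float64", interpolation_mode = interp,
                  padding_mode = pad, members = "case")
    got <- resample(data, group)
    ref <- ref_resample_2d(data[1L, , ], m, out_shape, interp, pad)
    expect_equal(got[1L, , ], ref, tolerance = 1e-12,
                 info = paste("case", case, interp, pad))
  }
})

test_that("nearest upsampling by 2 duplicates samples under centre alignment", {
  row <- make_meta_image(array(c(7, 9), c(1L, 2L, 1L)))
  out <- apply_all(lz_zoom(row, c(2, 1), interpolation = "nearest"))
  expect_identical(as.numeric(out$data), c(7, 7, 9, 9))
})

test_that("identity resample reproduces the input within float round-off", {
  img <- random_image(c(9L, 7L), seed = 5)
  group <- list(matrix = affine_identity(2), grid = NULL,
                in_shape = c(9L, 7L), out_shape = c(9L, 7L),
                in_dtype = "float64", out_dtype = "float64",
                interpolation_mode = "linear", padding_mode = "zeros",
                members = "id")
  expect_equal(resample(img$data, group), img$data, tolerance = 1e-12)
})

test_that("build_groups merges compatible ops and splits on mode changes", {
  img <- ramp_image(c(8L, 8L))
  all_compat <- lz_rotate(lz_flip(lz_zoom(img, 1.5), 1L), 0.2)
  expect_length(build_groups(all_compat$pending), 1L)

  mixed <- lz_rotate(img, 0.1, interpolation = "linear")
  mixed <- lz_rotate(mixed, 0.2, interpolation = "nearest")
  expect_length(build_groups(mixed$pending), 2L)

  g <- vector_grid(array(0, c(8L, 8L, 2L)))
  grid_sand <- push_pending(img, pending_op(affine_identity(2), c(8L, 8L),
                                            c(8L, 8L)))
  grid_sand <- push_pending(grid_sand, pending_op(g, c(8L, 8L), c(8L, 8L)))
  grid_sand <- push_pending(grid_sand, pending_op(affine_identity(2),
                                                  c(8L, 8L), c(8L, 8L)))
  expect_length(build_groups(grid_sand$pending), 3L)
})

test_that("apply_exact equals the general resampler on exact-class groups", {
  set.seed(77)
  for (case in 1:60) {
    shape <- sample(c(4L, 5L, 6L), 3, replace = TRUE)
    data <- array(stats::rnorm(prod(shape) * 2), dim = c(2L, shape))
    img <- make_meta_image(data)
    n_ops <- sample(1:3, 1)
    for (i in seq_len(n_ops)) {
      img <- switch(sample(3, 1),
        lz_flip(img, sample(3, sample(0:3, 1))),
        lz_rotate90(img, sample(0:3, 1),
                    plane = sample(3, 2)),
        lz_translate(img, sample(-2:2, 3, replace = TRUE)))
    }
    groups <- build_groups(img$pending)
    expect_length(groups, 1L)
    grp <- groups[[1L]]
    expect_identical(classify_affine(grp$matrix, grp$in_shape,
                                     grp$out_shape), "exact_op")
    exact <- apply_exact(data, grp)
    general <- resample(data, grp)
    expect_equal(exact, general, tolerance = 1e-12, info = paste("case", case))
    # exactness: every output value was moved, not recomputed
    expect_true(all(exact %in% c(data, 0)))
  }
})

test_that("apply_exact refuses non-exact groups", {
  img <- lz_rotate(ramp_image(c(8L, 8L)), pi / 4)
  grp <- build_groups(img$pending)[[1L]]
  expect_error(apply_exact(img$data, grp), "non-exact")
})

test_that("the rotate/zoom identity chain applies without interpolating", {
  lz_reset_counters()
  img <- random_image(c(64L, 64L), seed = 3)
  x <- identity_chain(img)
  g <- build_groups(x$pending)
  expect_length(g, 1L)
  expect_lt(max(abs(g[[1L]]$matrix - affine_identity(2))), 1e-6)
  expect_identical(classify_affine(g[[1L]]$matrix, g[[1L]]$in_shape,
                                   g[[1L]]$out_shape), "exact_op")
  out <- apply_all(x)
  expect_identical(out$data, img$data)
  counters <- lz_counters()
  expect_identical(counters$interpolation_events, 0L)
  expect_identical(counters$exact_events, 1L)
})

test_that("lazy apply_all equals the compose-then-single-resample oracle", {
  set.seed(123)
  for (case in 1:40) {
    nd <- sample(2:3, 1)
    shape <- sample(8:16, nd, replace = TRUE)
    img <- random_image(shape, seed = 1000 + case)
    n_ops <- sample(2:5, 1)
    for (i in seq_len(n_ops)) {
      img <- switch(sample(5, 1),
        lz_rotate(img, stats::runif(if (nd == 2) 1 else 3, -0.5, 0.5)),
        lz_zoom(img, stats::runif(1, 0.8, 1.3)),
        lz_translate(img, stats::runif(nd, -2, 2)),
        lz_flip(img, sample(nd, 1)),
        lz_rotate90(img, sample(0:3, 1), plane = sample(nd, 2)))
    }
    oracle <- oracle_single_resample(img)
    got <- apply_all(img)$data
    expect_equal(got, oracle, tolerance = 1e-5, info = paste("case", case))
  }
})

test_that("nearest-mode groups only emit values present in the input", {
  img <- random_label_image(c(10L, 10L, 6L), seed = 8)
  x <- lz_rotate(img, c(0.4, -0.2, 0.3), padding = "border")
  x <- lz_zoom(x, 1.2, padding = "border")
  out <- apply_all(x)
  expect_true(all(out$data %in% img$data))
  expect_identical(storage.mode(out$data), "integer")
})

test_that("pure permutation groups conserve the multiset of values", {
  img <- random_image(c(6L, 6L, 6L), seed = 12)
  x <- lz_rotate90(lz_flip(img, c(1L, 3L)), 1, plane = c(2L, 3L))
  out <- apply_all(x)
  expect_identical(sort(as.numeric(out$data)), sort(as.numeric(img$data)))
})

test_that("a vector grid reproduces its equivalent matrix transform", {
  img <- random_image(c(12L, 12L), seed = 6)
  m <- compose_affine(lazyresample:::rotation_pull(2L, 0.3),
                      affine_scale(c(1.1, 0.9)))
  out_shape <- c(12L, 12L)
  # build the grid by mapping every output voxel through the matrix
  coords <- as.matrix(expand.grid(x1 = 0:11, x2 = 0:11))
  centred <- sweep(coords, 2, (out_shape - 1) / 2)
  mapped <- t(m %*% rbind(t(centred), 1))[, 1:2]
  grid <- vector_grid(array(mapped, dim = c(out_shape, 2L)))
  via_grid <- apply_all(push_pending(img, pending_op(grid, c(12L, 12L),
                                                     out_shape)))
  via_matrix <- apply_all(push_pending(img, pending_op(m, c(12L, 12L),
                                                       out_shape)))
  expect_equal(via_grid$data, via_matrix$data, tolerance = 1e-10)
  expect_identical(via_grid$trace[[1L]]$extra$dispatch, "full_resample")
})

test_that("linear resampling of an integer-output group rounds to integers", {
  img <- random_label_image(c(8L, 8L), seed = 2)
  x <- lz_zoom(img, 1.5, interpolation = "linear")
  out <- apply_all(x)
  expect_identical(storage.mode(out$data), "integer")
})
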