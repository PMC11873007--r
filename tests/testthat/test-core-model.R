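test_that("make_meta_image accepts 2D/3D channel-first data and rejects others", {
  img <- make_meta_image(array(0, c(1L, 8L, 8L)))
  expect_s3_class(img, "meta_image")
  expect_length(img$pending, 0L)
  expect_length(img$trace, 0L)
  expect_equal(effective_shape(img), c(8L, 8L))

  # multi-modal volume at 1 mm isotropic, as in typical brain-MRI tasks
  big <- make_meta_image(array(0, c(4L, 24L, 24L, 16L)), spacing = c(1, 1, 1))
  expect_equal(effective_shape(big), c(24L, 24L, 16L))
  expect_equal(big$voxel_spacing, c(1, 1, 1))

  expect_error(make_meta_image(array(0, c(1, 2, 2, 2, 2, 2))),
               "spatial dimensions")
  expect_error(make_meta_image(array(0, c(1, 8))), "spatial dimensions")
  expect_error(make_meta_image(list()), "numeric array")
})

test_that("spacing must agree with the world affine column norms", {
  aff <- affine_scale(c(2, 2, 2))
  img <- make_meta_image(array(0, c(1, 4, 4, 4)), world_affine = aff)
  expect_equal(img$voxel_spacing, c(2, 2, 2))
  expect_error(make_meta_image(array(0, c(1, 4, 4, 4)), world_affine = aff,
                               spacing = c(1, 1, 1)),
               "disagrees")
})

test_that("push_pending chains shapes and never touches the data", {
  img <- ramp_image(c(8L, 8L))
  before <- img$data
  a <- pending_op(affine_identity(2), c(8L, 8L), c(4L, 4L),
                  source_name = "A")
  b <- pending_op(affine_identity(2), c(4L, 4L), c(2L, 2L),
                  source_name = "B")
  img <- push_pending(img, a)
  expect_length(img$pending, 1L)
  img <- push_pending(img, b)
  expect_length(img$pending, 2L)
  expect_identical(img$data, before)
  bad <- pending_op(affine_identity(2), c(9L, 9L), c(2L, 2L))
  expect_error(push_pending(img, bad), "2x2.*9x9")
  expect_silent(validate_meta_image(img))
})

test_that("effective shape follows the pending chain", {
  img <- ramp_image(c(8L, 8L))
  expect_equal(effective_shape(img), c(8L, 8L))
  img2 <- lz_crop_patch(img, c(2, 2), c(4L, 4L))
  expect_equal(effective_shape(img2), c(4L, 4L))
  img3 <- lz_zoom(lz_zoom(img, 2), 2)
  expect_equal(effective_shape(img3), c(32L, 32L))
  expect_equal(img3$pending[[1L]]$output_shape, c(16L, 16L))
})

test_that("validate_meta_image detects a broken shape chain", {
  img <- ramp_image(c(8L, 8L))
  img <- push_pending(img, pending_op(affine_identity(2), c(8L, 8L),
                                      c(4L, 4L)))
  img$pending[[2L]] <- pending_op(affine_identity(2), c(5L, 5L), c(4L, 4L))
  expect_error(validate_meta_image(img), "shape chain")
})

test_that("pending_op rejects invalid shapes, dtypes and grids", {
  expect_error(pending_op(affine_identity(2), c(0L, 4L), c(4L, 4L)), ">= 1")
  expect_error(pending_op(affine_identity(2), c(4L, 4L), c(4L, 4L),
                          input_dtype = "complex"), "dtype")
  g <- vector_grid(array(0, c(3L, 3L, 2L)))
  expect_error(pending_op(g, c(4L, 4L), c(4L, 4L)), "grid")
  expect_silent(pending_op(g, c(8L, 8L), c(3L, 3L)))
  expect_error(vector_grid(array(0, c(3L, 3L, 3L))), "shape")
})

test_that("pending ops and trace records round-trip through JSON bit-exactly", {
  m <- lazyresample:::rotation_pull(2L, pi / 7)
  m[1:2, 3] <- c(0.1234567890123456, -9.87)
  op <- pending_op(m, c(8L, 6L), c(5L, 7L), input_dtype = "float32",
                   output_dtype = "int16", interpolation_mode = "nearest",
                   padding_mode = "reflection", source_name = "roundtrip")
  back <- pending_op_from_json(pending_op_to_json(op))
  expect_identical(back$operation, op$operation)
  expect_identical(unclass(back), unclass(op))

  g <- vector_grid(array(stats::rnorm(3 * 4 * 2), c(3L, 4L, 2L)))
  opg <- pending_op(g, c(9L, 9L), c(3L, 4L))
  backg <- pending_op_from_json(pending_op_to_json(opg))
  expect_identical(backg$operation$vectors, opg$operation$vectors)

  rec <- trace_record(op, extra = list(dispatch = "full_resample"))
  rec2 <- trace_record_from_json(trace_record_to_json(rec))
  expect_identical(rec2$pending$operation, rec$pending$operation)
  expect_identical(rec2$extra$dispatch, "full_resample")
})

test_that("effective_spacing projects the world affine through pending ops", {
  img <- make_meta_image(array(0, c(1, 10, 10)), spacing = c(2, 2))
  expect_equal(effective_spacing(img), c(2, 2))
  img <- lz_spacing(img, c(1, 1))
  expect_equal(effective_spacing(img), c(1, 1))
  expect_equal(effective_shape(img), c(20L, 20L))
  applied <- apply_all(img)
  expect_equal(applied$voxel_spacing, c(1, 1))
})
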