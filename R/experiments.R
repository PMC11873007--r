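# Desk-scale experiments: forward-pass entropy comparison, round-trip
# label Dice comparison, and the checkerboard aliasing demonstration, each
# run in lazy vs traditional mode with shared random draws.

#' Standard augmentation pipelines
#'
#' `whole_volume_pipeline()` is the spacing - flip - rotate90 - zoom -
#' rotate sequence used throughout the bundled experiments;
#' `patch_pipeline()` prepends a fixed-centre patch crop. The random
#' parameter ranges are this package's documented defaults (rotation
#' +/- 15 degrees, zoom 0.9-1.1, flip probability 0.5), chosen as typical
#' augmentation strengths; override them per call.
#'
#' @param target_spacing Spacing target in mm.
#' @param flip_prob Per-axis flip probability.
#' @param zoom_range Isotropic zoom factor range.
#' @param rotate_range Half-width of the rotation angle range (radians).
#' @param patch_size Patch extents for the patch pipeline.
#' @return List of transform specs for [compile_pipeline()].
#' @export
whole_volume_pipeline <- function(target_spacing = c(1, 1, 1),
                                  flip_prob = 0.5,
                                  zoom_range = c(0.9, 1.1),
                                  rotate_range = pi / 12) {
  list(t_spacing(target_spacing),
       t_rand_flip(prob = flip_prob),
       t_rand_rotate90(prob = 1),
       t_rand_zoom(range = zoom_range, prob = 1),
       t_rand_rotate(range = rotate_range, prob = 1))
}

#' @rdname whole_volume_pipeline
#' @export
patch_pipeline <- function(patch_size = c(48L, 48L, 48L),
                           target_spacing = c(1, 1, 1),
                           flip_prob = 0.5,
                           zoom_range = c(0.9, 1.1),
                           rotate_range = pi / 12) {
  c(list(t_patch_sample(1L, patch_size, mode = "center")),
    whole_volume_pipeline(target_spacing, flip_prob, zoom_range,
                          rotate_range))
}

default_phantom_spacing <- c(1.1, 1.1, 1.1)

run_modes <- function(mode) {
  if (identical(mode, "both")) c("lazy", "traditional") else mode
}

first_sample <- function(x) if (is_meta_image(x)) x else x[[1L]]

#' Forward-pass entropy comparison
#'
#' Runs the given pipeline over `n_samples` textured phantoms in lazy
#' and/or traditional mode with identical random draws, and reports the
#' 256-bin Shannon entropy of input and output plus the resample-event
#' counts per run.
#'
#' @param n_samples Number of phantoms.
#' @param shape Phantom extents.
#' @param seed Master seed (phantom seeds and augmentation streams derive
#'   from it).
#' @param pipeline Transform spec list; [whole_volume_pipeline()] by
#'   default.
#' @param mode `"lazy"`, `"traditional"` or `"both"`.
#' @param spacing Phantom voxel spacing in mm (non-unit by default so the
#'   spacing stage really resamples).
#' @param bins Histogram bins for the entropy.
#' @param entropy_range `"input"` (default) bins each output over its input
#'   volume's intensity range, so the in/out entropies share bin edges and
#'   their difference isolates histogram concentration; `"per_array"` bins
#'   every array over its own range.
#' @return data.frame with one row per (sample, mode): entropy in/out and
#'   delta, and resample/interpolation/exact counts.
#' @export
run_forward <- function(n_samples = 10L, shape = c(64L, 64L, 64L),
                        seed = 1L, pipeline = whole_volume_pipeline(),
                        mode = "both", spacing = default_phantom_spacing,
                        bins = 256L,
                        entropy_range = c("input", "per_array")) {
  entropy_range <- match.arg(entropy_range)
  rows <- list()
  for (i in seq_len(n_samples)) {
    ph <- phantom_volume(phantom_spec(shape = shape,
                                      seed = derive_seed(seed, i),
                                      spacing = spacing))
    rng <- if (entropy_range == "input") {
      c(min(ph$image$data), max(ph$image$data))
    } else {
      NULL
    }
    ein <- shannon_entropy(ph$image$data, bins = bins, range = rng)
    for (m in run_modes(mode)) {
      p <- compile_pipeline(pipeline, lazy_default = (m == "lazy"),
                            master_seed = derive_seed(seed, 10000L + i))
      out <- first_sample(execute_pipeline(p, ph$image))
      ev <- count_events(out)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = i, mode = m,
        entropy_in = ein,
        entropy_out = shannon_entropy(out$data, bins = bins, range = rng),
        resamples = ev$resamples,
        interpolations = ev$interpolations,
        exact_ops = ev$exact_ops)
    }
  }
  out <- do.call(rbind, rows)
  out$entropy_delta <- out$entropy_in - out$entropy_out
  out
}

#' Round-trip label Dice comparison
#'
#' Passes phantom label volumes (nearest-neighbour interpolated) through
#' the pipeline forward and then back through the inverted trace, in lazy
#' and/or traditional mode with identical draws, and reports the per-class
#' Dice between the original and round-tripped labels plus event counts
#' over the full round trip.
#'
#' @inheritParams run_forward
#' @param n_runs Number of (phantom, pipeline-seed) runs.
#' @param n_phantoms Distinct phantoms to cycle through.
#' @return data.frame with one row per (run, mode, class).
#' @export
run_roundtrip <- function(n_runs = 20L, n_phantoms = 10L,
                          shape = c(64L, 64L, 64L), seed = 1L,
                          pipeline = whole_volume_pipeline(),
                          mode = "both",
                          spacing = default_phantom_spacing) {
  rows <- list()
  for (r in seq_len(n_runs)) {
    ph_id <- ((r - 1L) %% n_phantoms) + 1L
    ph <- phantom_volume(phantom_spec(shape = shape,
                                      seed = derive_seed(seed, ph_id),
                                      spacing = spacing))
    if (!is_integer_dtype(ph$labels$dtype)) {
      stop("round-trip inputs must be integer label volumes", call. = FALSE)
    }
    classes <- sort(setdiff(unique(as.vector(ph$labels$data)), 0))
    for (m in run_modes(mode)) {
      lazy <- m == "lazy"
      p <- compile_pipeline(pipeline, lazy_default = lazy,
                            master_seed = derive_seed(seed, 20000L + r))
      fwd <- first_sample(execute_pipeline(p, ph$labels))
      back <- execute_pipeline(invert_pipeline(fwd$trace, lazy = lazy), fwd)
      ev <- count_events(back)
      for (k in classes) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, phantom = ph_id, mode = m, class = k,
          dice = dice(ph$labels$data, back$data, k),
          resamples = ev$resamples,
          interpolations = ev$interpolations,
          exact_ops = ev$exact_ops)
      }
    }
  }
  do.call(rbind, rows)
}

#' Checkerboard scale round-trip (aliasing demonstration)
#'
#' For each cell size, scales a checkerboard by `factor` and back by
#' `1/factor`. Lazily the two scales compose to the identity and the round
#' trip is bit-exact; traditionally two linear resamples run, producing
#' aliasing patterns, new intermediate intensities and a non-zero
#' histogram divergence against the original.
#'
#' @param cells Checkerboard cell sizes to test.
#' @param shape Image extents.
#' @param factor Forward scale factor (inverted on the way back).
#' @param out_dir Optional directory: writes per-cell PNG grids
#'   (original / scaled / round-trip per mode).
#' @return data.frame with one row per (cell, mode): histogram divergence
#'   of the round trip vs the original, number of intensity values not
#'   present in the original, and whether the round trip was bit-equal.
#' @export
run_moire <- function(cells = c(1L, 2L, 4L), shape = c(64L, 64L),
                      factor = 6 / 5, out_dir = NULL) {
  rows <- list()
  for (cell in cells) {
    board <- checkerboard(shape, cell)
    img <- make_meta_image(array(board, dim = c(1L, shape)))
    scaled <- apply_all(lz_zoom(img, factor, lazy = TRUE))
    for (m in c("lazy", "traditional")) {
      lazy <- m == "lazy"
      rt <- lz_zoom(img, factor, lazy = lazy)
      rt <- lz_zoom(rt, 1 / factor, lazy = lazy)
      rt <- apply_all(rt)
      new_vals <- setdiff(unique(as.vector(rt$data)),
                          unique(as.vector(img$data)))
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell, mode = m,
        divergence = histogram_divergence(img$data, rt$data),
        n_new_values = length(new_vals),
        bit_equal = identical(dim(rt$data), dim(img$data)) &&
          all(rt$data == img$data))
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        write_gray_png(rt$data[1L, , ],
                       file.path(out_dir,
                                 sprintf("cell%d_%s_roundtrip.png", cell, m)))
      }
    }
    if (!is.null(out_dir)) {
      write_gray_png(board, file.path(out_dir,
                                      sprintf("cell%d_original.png", cell)))
      write_gray_png(scaled$data[1L, , ],
                     file.path(out_dir, sprintf("cell%d_scaled.png", cell)))
    }
  }
  do.call(rbind, rows)
}

write_gray_png <- function(mat, path) {
  rng <- range(mat)
  norm <- if (diff(rng) > 0) (mat - rng[1L]) / diff(rng) else mat * 0
  png::writePNG(norm, path)
  invisible(path)
}
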