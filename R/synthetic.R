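# Synthetic inputs: checkerboards for the aliasing/round-trip experiment
# and labelled 3D phantoms whose foreground fractions emulate the label
# statistics of public brain-MRI segmentation tasks (small foreground
# classes, fractions well under 10% of the volume).

#' Binary checkerboard image
#'
#' Alternating 0/1 cells; when the cell size divides both extents the two
#' values are exactly balanced and the 256-bin entropy is exactly 1 bit.
#'
#' @param shape Length-2 extents.
#' @param cell Cell edge length in pixels (`>= 1`).
#' @return A `shape[1] x shape[2]` numeric 0/1 matrix.
#' @export
checkerboard <- function(shape = c(64L, 64L), cell = 1L) {
  stopifnot(length(shape) == 2L, cell >= 1L)
  r <- floor((seq_len(shape[1L]) - 1L) / cell)
  c_ <- floor((seq_len(shape[2L]) - 1L) / cell)
  outer(r, c_, function(i, j) (i + j) %% 2)
}

#' Specification of a labelled phantom volume
#'
#' @param shape Spatial extents (default 64^3).
#' @param n_classes Number of foreground label classes.
#' @param fg_fraction_range `c(low, high)` volume-fraction range from which
#'   each class's target foreground fraction is drawn. The default follows
#'   brain-tumour-task label statistics (0.0816% to 3.57% of the volume);
#'   use `c(0.0376, 0.0748)` for hippocampus-like phantoms.
#' @param n_blobs Ellipsoidal blobs per class.
#' @param seed Integer seed; the phantom is fully reproducible from it.
#' @param spacing Per-axis voxel spacing in mm.
#' @param margin Minimum distance (voxels) between any blob and the volume
#'   border, so small integer translations cannot push foreground out of
#'   the field of view.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), n_classes = 3L,
                         fg_fraction_range = c(0.000816, 0.0357),
                         n_blobs = 1L, seed = 1L,
                         spacing = c(1, 1, 1), margin = 4L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_classes >= 1L,
            length(fg_fraction_range) == 2L,
            fg_fraction_range[1L] > 0,
            fg_fraction_range[2L] >= fg_fraction_range[1L],
            fg_fraction_range[2L] < 1,
            n_blobs >= 1L, all(spacing > 0), margin >= 0L)
  structure(list(shape = as.integer(shape), n_classes = as.integer(n_classes),
                 fg_fraction_range = as.numeric(fg_fraction_range),
                 n_blobs = as.integer(n_blobs), seed = as.integer(seed),
                 spacing = as.numeric(spacing), margin = as.integer(margin)),
            class = "phantom_spec")
}

# Smooth low-frequency background: a few random separable cosine modes.
smooth_background <- function(shape) {
  nd <- length(shape)
  field <- array(0, dim = shape)
  axes_coords <- lapply(shape, function(n) (seq_len(n) - 1) / n)
  for (m in seq_len(4L)) {
    freqs <- sample(1:3, nd, replace = TRUE)
    phases <- stats::runif(nd, 0, 2 * pi)
    amp <- stats::runif(1, 0.2, 0.5)
    comps <- lapply(seq_len(nd), function(a) {
      cos(2 * pi * freqs[a] * axes_coords[[a]] + phases[a])
    })
    mode_field <- outer(comps[[1L]], comps[[2L]])
    if (nd == 3L) mode_field <- outer(mode_field, comps[[3L]])
    field <- field + amp * mode_field
  }
  field
}

#' Generate a labelled phantom volume
#'
#' The image channel is a smooth random background plus a constant
#' intensity offset inside each label blob plus fine per-voxel Gaussian
#' texture; the fine texture gives interpolation something to degrade, so
#' entropy loss under resampling is measurable. Labels are axis-aligned
#' random ellipsoids, one value per class, non-overlapping (earlier
#' classes keep priority), each sized to a foreground fraction drawn from
#' the spec's range. Fully reproducible from the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (1-channel float `meta_image`), `labels`
#'   (int32 `meta_image`, values `0..n_classes`), and `spec`.
#' @export
phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  vol <- prod(shape)
  with_seed(spec$seed, {
    labels <- array(0L, dim = shape)
    coords <- lapply(shape, function(n) seq_len(n) - 1)
    for (cls in seq_len(spec$n_classes)) {
      frac <- stats::runif(1, spec$fg_fraction_range[1L],
                           spec$fg_fraction_range[2L])
      target_per_blob <- frac * vol / spec$n_blobs
      for (b in seq_len(spec$n_blobs)) {
        r0 <- (3 * target_per_blob / (4 * pi))^(1 / 3)
        u <- stats::runif(3, 0.75, 1.3)
        radii <- r0 * u / prod(u)^(1 / 3)
        lo <- spec$margin + radii
        hi <- shape - 1 - spec$margin - radii
        if (any(hi < lo)) {
          stop("infeasible phantom spec: a blob of radius ~",
               round(max(radii), 1), " voxels does not fit inside ",
               paste(shape, collapse = "x"), " with margin ", spec$margin,
               call. = FALSE)
        }
        centre <- stats::runif(3, lo, hi)
        d2 <- outer(((coords[[1L]] - centre[1L]) / radii[1L])^2,
                    ((coords[[2L]] - centre[2L]) / radii[2L])^2, `+`)
        d2 <- outer(d2, ((coords[[3L]] - centre[3L]) / radii[3L])^2, `+`)
        mask <- d2 <= 1 & labels == 0L
        labels[mask] <- cls
      }
    }
    img <- smooth_background(shape)
    for (cls in seq_len(spec$n_classes)) {
      img[labels == cls] <- img[labels == cls] + 0.4 * cls
    }
    img <- img + stats::rnorm(vol, sd = 0.15)
    list(image = make_meta_image(array(img, dim = c(1L, shape)),
                                 spacing = spec$spacing, dtype = "float64"),
         labels = make_meta_image(array(labels, dim = c(1L, shape)),
                                  spacing = spec$spacing, dtype = "int32"),
         spec = spec)
  })
}

#' Write a reproducible NIfTI fixture set
#'
#' One image/label NIfTI pair per spec plus a JSON manifest recording each
#' spec (including its seed), so the exact volumes can be regenerated from
#' the manifest alone.
#'
#' @param dir Writable output directory (created if missing).
#' @param specs List of [phantom_spec()]s.
#' @return Invisibly, the manifest as a list; written to
#'   `manifest.json` in `dir`.
#' @export
write_fixture_set <- function(dir, specs) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    ph <- phantom_volume(specs[[i]])
    image_file <- sprintf("phantom_%03d_image.nii.gz", i)
    label_file <- sprintf("phantom_%03d_labels.nii.gz", i)
    write_meta_image(ph$image, file.path(dir, image_file))
    write_meta_image(ph$labels, file.path(dir, label_file))
    entries[[i]] <- c(unclass(specs[[i]]),
                      list(image = image_file, labels = label_file))
  }
  manifest <- list(generator = "lazyresample", entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture manifest back into phantom specs
#'
#' @param path Path to a `manifest.json` written by [write_fixture_set()].
#' @return List of [phantom_spec()]s.
#' @export
read_fixture_manifest <- function(path) {
  manifest <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(manifest$entries, function(e) {
    phantom_spec(shape = unlist(e$shape), n_classes = e$n_classes,
                 fg_fraction_range = unlist(e$fg_fraction_range),
                 n_blobs = e$n_blobs, seed = e$seed,
                 spacing = unlist(e$spacing), margin = e$margin)
  })
}

#' Foreground fraction per label class
#'
#' @param labels Integer label array or label `meta_image`.
#' @return Named numeric vector of per-class volume fractions.
#' @export
label_fractions <- function(labels) {
  if (is_meta_image(labels)) labels <- labels$data
  cls <- sort(setdiff(unique(as.vector(labels)), 0))
  out <- vapply(cls, function(k) mean(labels == k), numeric(1))
  names(out) <- as.character(cls)
  out
}
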