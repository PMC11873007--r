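# Pipeline representation, compilation and execution.
#
# A pipeline is an ordered list of declarative transform specs. Compilation
# turns it into a stage list: transform stages, ApplyPending markers
# (inserted at lazy/non-lazy boundaries, after per-transform lazy = FALSE
# overrides, and at the end), and at most one MultiSampler container
# wrapping a multi-sample transform together with everything downstream of
# it. Execution then walks the stages; randomised transforms draw from
# per-transform streams derived from the pipeline's master seed and the
# transform's position, so the drawn geometry is identical in lazy and
# traditional modes.

new_transform_spec <- function(name, params = list(), lazy = NA,
                               interpolation = NULL, padding = "zeros") {
  structure(list(name = name, params = params, lazy = lazy,
                 interpolation = interpolation, padding = padding),
            class = "lz_transform")
}

# name -> fn(img, params, seed, interpolation, padding), capability flags
transform_registry <- function() {
  list(
    rotate = list(
      fn = function(img, p, seed, interp, pad)
        lz_rotate(img, p$angles, lazy = TRUE, interpolation = interp,
                  padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    rotate90 = list(
      fn = function(img, p, seed, interp, pad)
        lz_rotate90(img, p$k, plane = p$plane %||% c(1L, 2L), lazy = TRUE,
                    interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    flip = list(
      fn = function(img, p, seed, interp, pad)
        lz_flip(img, p$axes, lazy = TRUE, interpolation = interp,
                padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    zoom = list(
      fn = function(img, p, seed, interp, pad)
        lz_zoom(img, p$factors, keep_shape = isTRUE(p$keep_shape),
                lazy = TRUE, interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    translate = list(
      fn = function(img, p, seed, interp, pad)
        lz_translate(img, p$offsets, lazy = TRUE, interpolation = interp,
                     padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    spacing = list(
      fn = function(img, p, seed, interp, pad)
        lz_spacing(img, p$target_spacing, lazy = TRUE,
                   interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    crop_patch = list(
      fn = function(img, p, seed, interp, pad)
        lz_crop_patch(img, p$start, p$size, lazy = TRUE,
                      interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    resize = list(
      fn = function(img, p, seed, interp, pad)
        lz_resize(img, p$target_shape, lazy = TRUE,
                  interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = FALSE),
    rand_rotate = list(
      fn = function(img, p, seed, interp, pad)
        lz_rand_rotate(img, range = p$range %||% (pi / 12),
                       prob = p$prob %||% 1, seed = seed, lazy = TRUE,
                       interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = TRUE),
    rand_zoom = list(
      fn = function(img, p, seed, interp, pad)
        lz_rand_zoom(img, zoom_range = p$range %||% c(0.9, 1.1),
                     prob = p$prob %||% 1, seed = seed, lazy = TRUE,
                     interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = TRUE),
    rand_flip = list(
      fn = function(img, p, seed, interp, pad)
        lz_rand_flip(img, prob = p$prob %||% 0.5, seed = seed, lazy = TRUE,
                     interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = TRUE),
    rand_rotate90 = list(
      fn = function(img, p, seed, interp, pad)
        lz_rand_rotate90(img, prob = p$prob %||% 1,
                         plane = p$plane %||% c(1L, 2L), seed = seed,
                         lazy = TRUE, interpolation = interp, padding = pad),
      lazy_capable = TRUE, multi_sample = FALSE, randomised = TRUE),
    add_noise = list(
      fn = function(img, p, seed, interp, pad)
        lz_add_noise(img, p$sigma, seed = seed),
      lazy_capable = FALSE, multi_sample = FALSE, randomised = TRUE),
    patch_sample = list(
      fn = NULL,  # executed by the MultiSampler container
      lazy_capable = TRUE, multi_sample = TRUE, randomised = TRUE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

registry_info <- function(name) {
  reg <- transform_registry()
  info <- reg[[name]]
  if (is.null(info)) stop("unknown transform '", name, "'", call. = FALSE)
  info
}

#' Declarative transform specs
#'
#' Constructors for pipeline entries; each records a transform name, its
#' parameters, an optional per-transform `lazy` override (default: inherit
#' the pipeline's `lazy_default`), and sampling modes. See the matching
#' `lz_*` functions for the semantics.
#'
#' @param lazy `NA` to inherit the pipeline default, or `TRUE`/`FALSE`.
#' @param interpolation,padding Sampling modes for the emitted operation.
#' @param angles,k,plane,axes,factors,keep_shape,offsets,target_spacing,start,size,target_shape,range,prob,sigma,n,mode
#'   Transform parameters, as in the corresponding `lz_*` function.
#' @name transform_specs
#' @export
t_rotate <- function(angles, lazy = NA, interpolation = NULL,
                     padding = "zeros") {
  new_transform_spec("rotate", list(angles = angles), lazy, interpolation,
                     padding)
}

#' @rdname transform_specs
#' @export
t_rotate90 <- function(k = 1L, plane = c(1L, 2L), lazy = NA,
                       interpolation = NULL, padding = "zeros") {
  new_transform_spec("rotate90", list(k = k, plane = plane), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_flip <- function(axes, lazy = NA, interpolation = NULL,
                   padding = "zeros") {
  new_transform_spec("flip", list(axes = axes), lazy, interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_zoom <- function(factors, keep_shape = FALSE, lazy = NA,
                   interpolation = NULL, padding = "zeros") {
  new_transform_spec("zoom", list(factors = factors, keep_shape = keep_shape),
                     lazy, interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_translate <- function(offsets, lazy = NA, interpolation = NULL,
                        padding = "zeros") {
  new_transform_spec("translate", list(offsets = offsets), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_spacing <- function(target_spacing, lazy = NA, interpolation = NULL,
                      padding = "zeros") {
  new_transform_spec("spacing", list(target_spacing = target_spacing), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_crop_patch <- function(start, size, lazy = NA, interpolation = NULL,
                         padding = "zeros") {
  new_transform_spec("crop_patch", list(start = start, size = size), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_resize <- function(target_shape, lazy = NA, interpolation = NULL,
                     padding = "zeros") {
  new_transform_spec("resize", list(target_shape = target_shape), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_rand_rotate <- function(range = pi / 12, prob = 1, lazy = NA,
                          interpolation = NULL, padding = "zeros") {
  new_transform_spec("rand_rotate", list(range = range, prob = prob), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_rand_zoom <- function(range = c(0.9, 1.1), prob = 1, lazy = NA,
                        interpolation = NULL, padding = "zeros") {
  new_transform_spec("rand_zoom", list(range = range, prob = prob), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_rand_flip <- function(prob = 0.5, lazy = NA, interpolation = NULL,
                        padding = "zeros") {
  new_transform_spec("rand_flip", list(prob = prob), lazy, interpolation,
                     padding)
}

#' @rdname transform_specs
#' @export
t_rand_rotate90 <- function(prob = 1, plane = c(1L, 2L), lazy = NA,
                            interpolation = NULL, padding = "zeros") {
  new_transform_spec("rand_rotate90", list(prob = prob, plane = plane), lazy,
                     interpolation, padding)
}

#' @rdname transform_specs
#' @export
t_add_noise <- function(sigma, lazy = NA) {
  new_transform_spec("add_noise", list(sigma = sigma), lazy)
}

#' @rdname transform_specs
#' @export
t_patch_sample <- function(n, size, mode = c("random", "center"), lazy = NA,
                           interpolation = NULL, padding = "zeros") {
  mode <- match.arg(mode)
  new_transform_spec("patch_sample", list(n = n, size = size, mode = mode),
                     lazy, interpolation, padding)
}

#' Deterministic patch-window corners
#'
#' The positions a `patch_sample` stage will use: `mode = "center"` repeats
#' the centred window; `mode = "random"` draws uniformly over the valid
#' corner range from `seed`. Exposed so naive re-executions (and tests) can
#' reproduce a sampler's windows exactly.
#'
#' @param shape Input spatial extents.
#' @param size Patch extents.
#' @param n Number of patches.
#' @param mode `"random"` or `"center"`.
#' @param seed Integer seed for the random mode.
#' @return List of `n` 0-based corner vectors.
#' @export
patch_starts <- function(shape, size, n, mode = "random", seed = 0L) {
  shape <- as.integer(shape); size <- rep_len(as.integer(size), length(shape))
  if (mode == "center") {
    start <- floor((shape - size) / 2)
    return(rep(list(start), n))
  }
  hi <- pmax(shape - size, 0L)
  with_seed(seed, lapply(seq_len(n), function(i) {
    vapply(hi, function(h) sample.int(h + 1L, 1L) - 1L, integer(1))
  }))
}

stage_apply <- function() list(kind = "apply")

is_stage_apply <- function(st) identical(st$kind, "apply")

#' Compile a transform list into an executable pipeline
#'
#' Inserts ApplyPending stages (i) before every non-lazy-capable transform
#' that may arrive with pending operations, (ii) after every lazy-capable
#' transform whose effective lazy flag is `FALSE`, and (iii) at the
#' pipeline end; wraps a multi-sample transform and all transforms
#' downstream of it in a single MultiSampler container. Compiling an
#' already-compiled pipeline returns it unchanged (idempotence).
#'
#' @param transforms List of transform specs (see [t_rotate()] and
#'   friends), or an already compiled pipeline.
#' @param lazy_default Pipeline-wide lazy flag inherited by transforms with
#'   `lazy = NA`. `FALSE` reproduces a traditional per-transform-resample
#'   pipeline.
#' @param master_seed Master seed; each randomised transform draws from a
#'   stream derived from `(master_seed, position)`.
#' @return An `lz_pipeline`.
#' @export
compile_pipeline <- function(transforms, lazy_default = TRUE,
                             master_seed = 0L) {
  if (inherits(transforms, "lz_pipeline")) return(transforms)
  if (inherits(transforms, "lz_transform")) transforms <- list(transforms)
  stopifnot(length(transforms) > 0)
  for (i in seq_along(transforms)) {
    stopifnot(inherits(transforms[[i]], "lz_transform"))
    transforms[[i]]$index <- i
  }
  build <- function(specs) {
    stages <- list()
    may_pend <- FALSE
    push <- function(st) stages[[length(stages) + 1L]] <<- st
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      info <- registry_info(sp$name)
      if (info$multi_sample) {
        rest <- specs[seq_along(specs) > j]
        if (any(vapply(rest, function(s) registry_info(s$name)$multi_sample,
                       logical(1)))) {
          stop("nested multi-samplers are unsupported", call. = FALSE)
        }
        push(list(kind = "multisampler", spec = sp, index = sp$index,
                  downstream = build(rest)))
        return(stages)
      }
      if (!info$lazy_capable) {
        if (may_pend) push(stage_apply())
        push(list(kind = "transform", spec = sp, index = sp$index))
        may_pend <- FALSE
      } else {
        push(list(kind = "transform", spec = sp, index = sp$index))
        eff_lazy <- if (is.na(sp$lazy)) lazy_default else isTRUE(sp$lazy)
        if (eff_lazy) {
          may_pend <- TRUE
        } else {
          push(stage_apply())
          may_pend <- FALSE
        }
      }
    }
    if (may_pend) push(stage_apply())
    stages
  }
  structure(list(stages = build(transforms),
                 lazy_default = lazy_default,
                 master_seed = as.integer(master_seed)),
            class = "lz_pipeline")
}

#' Apply-pending pipeline stage
#'
#' No-op when nothing is pending; otherwise delegates to [apply_all()] and
#' counts an ApplyPending event.
#'
#' @param img A `meta_image`.
#' @export
apply_pending <- function(img) {
  if (length(img$pending) == 0L) return(img)
  bump("apply_pending_events")
  log_event("apply")
  apply_all(img)
}

run_transform_stage <- function(st, img, master_seed) {
  sp <- st$spec
  info <- registry_info(sp$name)
  seed <- derive_seed(master_seed, st$index)
  info$fn(img, sp$params, seed, sp$interpolation, sp$padding)
}

run_multisampler <- function(st, img, master_seed) {
  p <- st$spec$params
  starts <- patch_starts(effective_shape(img), p$size, p$n,
                         mode = p$mode %||% "random",
                         seed = derive_seed(master_seed, st$index))
  out <- vector("list", p$n)
  for (s in seq_len(p$n)) {
    sampler_enter()
    sub <- lz_crop_patch(img, starts[[s]], p$size, lazy = TRUE,
                         interpolation = st$spec$interpolation,
                         padding = st$spec$padding)
    sub <- run_stages(st$downstream, sub, master_seed)
    out[[s]] <- sub
    sampler_exit()
  }
  out
}

run_stages <- function(stages, img, master_seed) {
  for (st in stages) {
    img <- switch(st$kind,
      apply = apply_pending(img),
      transform = run_transform_stage(st, img, master_seed),
      pushop = push_pending(img, st$op),
      multisampler = return(run_multisampler(st, img, master_seed)),
      stop("unknown stage kind '", st$kind, "'", call. = FALSE))
  }
  img
}

#' Execute a compiled pipeline
#'
#' @param p An `lz_pipeline` from [compile_pipeline()] or
#'   [invert_pipeline()].
#' @param img Input `meta_image`.
#' @return A single `meta_image`, or a list of them (one per sample,
#'   produced depth-first) when the pipeline contains a multi-sampler.
#'   Every output carries its complete trace.
#' @export
execute_pipeline <- function(p, img) {
  stopifnot(inherits(p, "lz_pipeline"), is_meta_image(img))
  run_stages(p$stages, img, p$master_seed)
}

#' Build the inverse pipeline of an applied-transform trace
#'
#' One inverse operation per trace record, in reverse order. Because trace
#' records describe composed groups, a lazily merged forward pass inverts
#' with the same (small) number of resamples as it used going forward.
#' With `lazy = FALSE` each inverse operation is applied individually,
#' mirroring a traditional inverse pass.
#'
#' @param trace List of [trace_record()]s (or a `meta_image`, whose trace
#'   is used).
#' @param lazy Compile the inverse pass lazily (default) or traditionally.
#' @return An `lz_pipeline`; empty traces give a pipeline with no stages.
#' @export
invert_pipeline <- function(trace, lazy = TRUE) {
  if (is_meta_image(trace)) trace <- trace$trace
  stages <- list()
  for (rec in rev(trace)) {
    op <- invert_record(rec)
    stages[[length(stages) + 1L]] <- list(kind = "pushop", op = op)
    if (!lazy) stages[[length(stages) + 1L]] <- stage_apply()
  }
  if (length(stages) > 0L && !is_stage_apply(stages[[length(stages)]])) {
    stages[[length(stages) + 1L]] <- stage_apply()
  }
  structure(list(stages = stages, lazy_default = lazy, master_seed = 0L),
            class = "lz_pipeline")
}

#' Count ApplyPending stages of a compiled pipeline
#'
#' @param p An `lz_pipeline`.
#' @export
n_apply_stages <- function(p) {
  stopifnot(inherits(p, "lz_pipeline"))
  count <- function(stages) {
    sum(vapply(stages, function(st) {
      if (identical(st$kind, "multisampler")) count(st$downstream)
      else as.integer(is_stage_apply(st))
    }, integer(1)))
  }
  count(p$stages)
}

#' @export
print.lz_pipeline <- function(x, ...) {
  describe <- function(stages, indent) {
    for (st in stages) {
      pad <- strrep("  ", indent)
      if (identical(st$kind, "multisampler")) {
        cat(pad, "- MultiSampler(", st$spec$name, ")\n", sep = "")
        describe(st$downstream, indent + 1L)
      } else if (is_stage_apply(st)) {
        cat(pad, "- ApplyPending\n", sep = "")
      } else if (identical(st$kind, "pushop")) {
        cat(pad, "- push ", st$op$source_name, "\n", sep = "")
      } else {
        cat(pad, "- ", st$spec$name, "\n", sep = "")
      }
    }
  }
  cat("<lz_pipeline> lazy_default = ", x$lazy_default, "\n", sep = "")
  describe(x$stages, 1L)
  invisible(x)
}
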