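# Information-loss and label-degradation metrics.

#' Shannon entropy of an array's intensity histogram
#'
#' Values are binned into `bins` equal-width bins over `range` (the
#' array's own `[min, max]` by default) and the entropy
#' `-sum(p * log2(p))` is taken over the occupied bins. A constant array
#' occupies a single bin and has entropy 0.
#'
#' @param data Non-empty numeric array or vector.
#' @param bins Number of bins (`>= 2`); 256 by default.
#' @param range Optional fixed `c(lo, hi)` intensity range; use a shared
#'   range to compare histograms across images on an absolute scale.
#' @return Entropy in bits, in `[0, log2(bins)]`.
#' @export
shannon_entropy <- function(data, bins = 256L, range = NULL) {
  x <- as.numeric(data)
  stopifnot(length(x) > 0L, bins >= 2L)
  if (is.null(range)) range <- c(min(x), max(x))
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) return(0)
  idx <- pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1L)
  idx <- pmax(1L, idx)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Dice similarity coefficient for one label class
#'
#' `2 |A n B| / (|A| + |B|)` for the binary masks of `cls`; defined as 1
#' when both masks are empty (vacuous agreement).
#'
#' @param a,b Integer label arrays of identical shape.
#' @param cls Class id whose masks are compared.
#' @export
dice <- function(a, b, cls) {
  if (!identical(dim(a), dim(b))) {
    stop("label arrays differ in shape: (",
         paste(dim(a), collapse = "x"), ") vs (",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  }
  ma <- a == cls
  mb <- b == cls
  denom <- sum(ma) + sum(mb)
  if (denom == 0L) return(1)
  2 * sum(ma & mb) / denom
}

#' Per-class Dice report
#'
#' Dice coefficient for every non-background class present in either
#' array, plus their mean.
#'
#' @inheritParams dice
#' @param classes Class ids to score; defaults to all non-zero values seen
#'   in `a` or `b`.
#' @return List with `per_class` (named numeric) and `mean`.
#' @export
dice_report <- function(a, b, classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(c(unique(as.vector(a)),
                                     unique(as.vector(b)))), 0))
  }
  per <- vapply(classes, function(k) dice(a, b, k), numeric(1))
  names(per) <- as.character(classes)
  list(per_class = per,
       mean = if (length(per)) mean(per) else NA_real_)
}

#' L1 divergence between two intensity histograms
#'
#' Both arrays are binned over the combined `[min, max]` range with shared
#' bin edges; the distance is `sum(|p - q|)` of the normalised histograms,
#' 0 iff the binned distributions are identical and at most 2.
#'
#' @param a,b Numeric arrays (shapes may differ).
#' @param bins Number of shared bins.
#' @export
histogram_divergence <- function(a, b, bins = 256L) {
  xa <- as.numeric(a); xb <- as.numeric(b)
  lo <- min(xa, xb); hi <- max(xa, xb)
  if (hi <= lo) return(0)
  binned <- function(x) {
    idx <- pmax(1L, pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1L))
    tabulate(idx, nbins = bins) / length(x)
  }
  sum(abs(binned(xa) - binned(xb)))
}

#' Count resample / interpolation / exact events
#'
#' Counts from applied-transform traces: each trace record is one executed
#' composed group; its `extra$dispatch` says whether it ran as an exact
#' array operation or needed interpolation.
#'
#' @param x A `meta_image`, a list of them, or a list of
#'   [trace_record()]s.
#' @return List with integer `resamples`, `interpolations`, `exact_ops`.
#' @export
count_events <- function(x) {
  recs <- list()
  collect <- function(obj) {
    if (is_meta_image(obj)) {
      recs[length(recs) + seq_along(obj$trace)] <<- obj$trace
    } else if (inherits(obj, "trace_record")) {
      recs[[length(recs) + 1L]] <<- obj
    } else if (is.list(obj)) {
      for (el in obj) collect(el)
    } else {
      stop("count_events expects meta_image(s) or trace records",
           call. = FALSE)
    }
  }
  collect(x)
  disp <- vapply(recs, function(r) r$extra$dispatch %||% "full_resample",
                 character(1))
  list(resamples = length(disp),
       interpolations = sum(disp != "exact_op"),
       exact_ops = sum(disp == "exact_op"))
}
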