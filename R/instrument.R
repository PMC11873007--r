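# Instrumentation: event counters and a structured event log.
# A single package-level environment records how many resample /
# interpolation / exact events a run performed; tests and the CLI report
# read it. Not safe for concurrent use from multiple R processes.

.lz_state <- new.env(parent = emptyenv())

#' Reset the instrumentation counters and event log
#' @export
lz_reset_counters <- function() {
  .lz_state$resample_events <- 0L
  .lz_state$interpolation_events <- 0L
  .lz_state$exact_events <- 0L
  .lz_state$apply_pending_events <- 0L
  .lz_state$active_samples <- 0L
  .lz_state$max_active_samples <- 0L
  .lz_state$log <- list()
  invisible(NULL)
}

#' Read the instrumentation counters
#'
#' @return A list with `resample_events` (composed groups executed),
#'   `interpolation_events` (groups executed by interpolation rather than
#'   exact array ops), `exact_events`, `apply_pending_events` (ApplyPending
#'   stages that had work to do), and `max_active_samples` (peak number of
#'   concurrently materialised multi-sampler intermediates).
#' @export
lz_counters <- function() {
  list(resample_events = .lz_state$resample_events,
       interpolation_events = .lz_state$interpolation_events,
       exact_events = .lz_state$exact_events,
       apply_pending_events = .lz_state$apply_pending_events,
       max_active_samples = .lz_state$max_active_samples)
}

#' Structured event log of the current run
#'
#' One record per event with fields `event` (one of `describe`, `apply`,
#' `resample`, `exact_op`, `interp`, `sample_begin`, `sample_end`) and
#' `stage` (the transform or group name).
#'
#' @param path Optional file; when given the log is written as JSON lines.
#' @export
lz_event_log <- function(path = NULL) {
  log <- .lz_state$log
  if (!is.null(path)) {
    lines <- vapply(log, function(rec) {
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path)
    return(invisible(log))
  }
  log
}

log_event <- function(event, stage = "") {
  if (is.null(.lz_state$log)) lz_reset_counters()
  .lz_state$log[[length(.lz_state$log) + 1L]] <-
    list(event = event, stage = stage)
  invisible(NULL)
}

bump <- function(field, by = 1L) {
  if (is.null(.lz_state[[field]])) lz_reset_counters()
  .lz_state[[field]] <- .lz_state[[field]] + by
  invisible(NULL)
}

sampler_enter <- function() {
  bump("active_samples")
  if (.lz_state$active_samples > .lz_state$max_active_samples) {
    .lz_state$max_active_samples <- .lz_state$active_samples
  }
  log_event("sample_begin")
}

sampler_exit <- function() {
  bump("active_samples", -1L)
  log_event("sample_end")
}

# Derive a 32-bit seed for stream `index` from a master seed, so that
# editing one transform in a pipeline does not shift the draws of others.
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(index) * 8191 + 1) %% 2147483647)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
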