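# JSON serialisation of pending operations and trace records.
# Matrices are stored row-major. Doubles are written as 17-significant-
# digit strings: that is the shortest representation guaranteed to
# round-trip IEEE doubles bit-exactly (plain JSON numbers pass through
# a 15-digit formatter and lose the last ulps).

fmt_doubles <- function(x) sprintf("%.17g", as.numeric(x))

op_to_list <- function(op) {
  operation <- if (is_vector_grid(op$operation)) {
    list(kind = "grid",
         dim = as.integer(dim(op$operation$vectors)),
         values = fmt_doubles(op$operation$vectors))
  } else {
    m <- op$operation
    list(kind = "matrix",
         dim = as.integer(dim(m)),
         values = fmt_doubles(t(m)))  # row-major
  }
  list(operation = operation,
       input_shape = op$input_shape,
       input_dtype = op$input_dtype,
       output_shape = op$output_shape,
       output_dtype = op$output_dtype,
       interpolation_mode = op$interpolation_mode,
       padding_mode = op$padding_mode,
       source_name = op$source_name)
}

op_from_list <- function(x) {
  vals <- as.numeric(unlist(x$operation$values))
  operation <- if (identical(x$operation$kind, "grid")) {
    vector_grid(array(vals, dim = as.integer(x$operation$dim)))
  } else {
    d <- as.integer(x$operation$dim)
    t(matrix(vals, d[2L], d[1L]))
  }
  pending_op(operation,
             input_shape = as.integer(x$input_shape),
             output_shape = as.integer(x$output_shape),
             input_dtype = x$input_dtype,
             output_dtype = x$output_dtype,
             interpolation_mode = x$interpolation_mode,
             padding_mode = x$padding_mode,
             source_name = if (is.null(x$source_name)) "" else x$source_name)
}

#' Serialise pending operations and trace records to JSON
#'
#' Full double precision is preserved (`digits = NA`), so round trips are
#' bit-exact.
#'
#' @param op A [pending_op()].
#' @param rec A [trace_record()].
#' @param json JSON string produced by the corresponding `*_to_json()`.
#' @name lazy_json
#' @export
pending_op_to_json <- function(op) {
  stopifnot(inherits(op, "pending_op"))
  jsonlite::toJSON(op_to_list(op), auto_unbox = TRUE, digits = NA)
}

#' @rdname lazy_json
#' @export
pending_op_from_json <- function(json) {
  op_from_list(jsonlite::fromJSON(json, simplifyVector = TRUE))
}

#' @rdname lazy_json
#' @export
trace_record_to_json <- function(rec) {
  stopifnot(inherits(rec, "trace_record"))
  jsonlite::toJSON(list(pending = op_to_list(rec$pending),
                        extra = rec$extra),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname lazy_json
#' @export
trace_record_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  trace_record(op_from_list(x$pending), extra = as.list(x$extra))
}
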