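#' @keywords internal
#' @import stats
#' @importFrom utils head modifyList read.csv write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name = "p") {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_bad(name, " must lie strictly inside (0, 1)")
  invisible(p)
}

# Derive a child seed from a user seed; keeps results < 2^31 and stable.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) + as.integer(offset)
}
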