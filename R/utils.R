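#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbinom rnbinom rnorm rpois sd setNames
#' @importFrom utils head modifyList
NULL

# Condition helpers ----------------------------------------------------------

msc_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "muscscreen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

param_error <- function(message, ...) msc_error("msc_param_error", message, ...)
data_error  <- function(message, ...) msc_error("msc_data_error", message, ...)
schema_error <- function(message, ...) msc_error("msc_schema_error", message, ...)
qc_error    <- function(message, ...) msc_error("msc_qc_error", message, ...)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators in the package funnel their randomness through this helper so
# that a single integer seed reproduces every artifact byte for byte.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    param_error(sprintf("`%s` must be a single number in (0, 1), got %s",
                        name, deparse(x)))
  invisible(x)
}
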