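#' @useDynLib fibremesh, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.csv modifyList
NULL

# Typed conditions so callers (and the CLI) can map failures to exit codes:
# validation -> 2, I/O -> 3, computation -> 4.

fm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fm_stop_validation <- function(msg) fm_stop(msg, "fm_validation_error")
fm_stop_io <- function(msg) fm_stop(msg, "fm_io_error")
fm_stop_computation <- function(msg) fm_stop(msg, "fm_computation_error")

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    fm_stop_validation(sprintf("'%s' must be a single non-missing number", name))
  if (finite && !is.finite(x))
    fm_stop_validation(sprintf("'%s' must be finite", name))
  if (positive && x <= 0)
    fm_stop_validation(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    fm_stop_validation(sprintf("'%s' must be >= 0 (got %g)", name, x))
  if (integerish && abs(x - round(x)) > 1e-8)
    fm_stop_validation(sprintf("'%s' must be an integer (got %g)", name, x))
  x
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
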