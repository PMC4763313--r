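#' @keywords internal
"_PACKAGE"

.mc_version <- function() {
  tryCatch(as.character(utils::packageVersion("minecore")), error = function(e) "0.0.0")
}

#' Derive a reproducible sub-stream seed
#'
#' A single top-level seed deterministically spawns per-stage seeds so that
#' pipeline stages can be rerun in isolation. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer scalar, the parent seed.
#' @param stream integer scalar, index of the sub-stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L)
  as.integer((abs(as.numeric(seed)) + 99991 * (as.numeric(stream) + 1)) %% 2147483587)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Full-precision text rendering of numeric columns so TSV round trips are
# exact for integers and within double precision for reals.
.format_cell <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) return("NA")
      if (is.finite(v) && v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
      sprintf("%.17g", v)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
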