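`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a numeric series: finite values, minimum length.
check_series <- function(x, min_len = 2L, what = "series") {
  if (!is.numeric(x)) {
    stop(what, " must be numeric, got ", class(x)[1], call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(what, " too short: length ", length(x), " < ", min_len, call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop(what, " contains non-finite value(s) at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(v, name, min = 0L) {
  if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v != round(v)) {
    stop(name, " must be a single integer, got ", deparse(v), call. = FALSE)
  }
  if (v < min) {
    stop(name, " must be >= ", min, ", got ", v, call. = FALSE)
  }
  as.integer(v)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
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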