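#' @keywords internal
#' @useDynLib emgadapt, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Stop with a formatted message, without the call in the condition.
stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All seeded operations in the package
# route through this so that user-level RNG state is never clobbered.
with_seed_ <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_("`seed` must be a single finite number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps all
# derived seeds inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% 2147483629
  as.integer(h) + 1L
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_("%s contains non-finite values", what)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
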