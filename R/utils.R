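# Internal helpers shared across modules.

#' @useDynLib silicostain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All randomness in the package flows through this so that a top-level seed
# makes every output reproducible.
with_seed <- function(seed, expr) {
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
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and string tags.
# Arithmetic stays in doubles below 2^53 so the modulus is exact.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- 0
  if (nzchar(tags)) {
    for (v in utf8ToInt(tags)) h <- (h * 131 + v) %% 2147483629
  }
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
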