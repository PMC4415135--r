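#' @keywords internal
"_PACKAGE"

# Run `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomness in the package flows through
# this helper so that a single master seed fixes every output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-trait seed derived from a master seed and a trait index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 7919 + 11) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
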