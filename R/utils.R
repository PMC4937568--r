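#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state so callers see no side effects.
#' All seeded operations in the package go through this helper, which is
#' what makes dataset generation, splits and training runs reproducible.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a child seed from a run seed and a stream label, keeping the
# result inside the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

an_message <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
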