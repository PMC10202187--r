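#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  code
}

# single scalar check used across constructors
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x <= 1
}
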