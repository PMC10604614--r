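#' @keywords internal
#' @noRd
BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. `seed = NULL` uses the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from the current stream, kept within the 32-bit
# integer range so it is itself a valid `set.seed()` argument.
#' @noRd
draw_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

#' @noRd
clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

#' @noRd
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
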