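# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators do not perturb user simulations.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# clamp values into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a reproducible 31-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopifnot_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}
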