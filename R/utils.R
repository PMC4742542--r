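# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package operations do not perturb the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop() with a class so callers/tests can distinguish error kinds
abort_dwiph <- function(message, class) {
  stop(structure(
    class = c(class, "dwiphantom_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))
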