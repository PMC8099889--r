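# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the session stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Path length of an n x 3 coordinate matrix.
polyline_length <- function(xyz) {
  if (nrow(xyz) < 2) return(0)
  d <- diff(xyz)
  sum(sqrt(rowSums(d^2)))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop2("cannot normalise a zero vector")
  v / n
}
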