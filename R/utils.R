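# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# degrees/radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Row-wise cross product of two N x 3 matrices
#' @keywords internal
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Normalize rows of an N x 3 matrix to unit length
#' @keywords internal
rows_unit <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
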