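#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so generators are pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive reproducible child seeds from a master seed
#'
#' One master seed spawns a fixed stream of stage seeds so that individual
#' pipeline stages (scene, probes, counting, ...) are independently
#' reproducible. The derivation is a seeded draw without replacement from
#' the 31-bit integer range.
#'
#' @param seed Master seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seeds(1, 3)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
segment_lengths <- function(seg) {
  if (nrow(seg) == 0L) return(numeric(0))
  sqrt((seg[, 4] - seg[, 1])^2 + (seg[, 5] - seg[, 2])^2 + (seg[, 6] - seg[, 3])^2)
}

# polylines (list of n x 3 matrices) -> segment matrix with columns
# x1 y1 z1 x2 y2 z2
polylines_to_segments <- function(polylines) {
  keep <- vapply(polylines, nrow, 1L) >= 2L
  polylines <- polylines[keep]
  if (length(polylines) == 0L)
    return(matrix(numeric(0), ncol = 6,
                  dimnames = list(NULL, c("x1", "y1", "z1", "x2", "y2", "z2"))))
  segs <- lapply(polylines, function(p) {
    n <- nrow(p)
    cbind(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  })
  out <- do.call(rbind, segs)
  colnames(out) <- c("x1", "y1", "z1", "x2", "y2", "z2")
  out
}

total_polyline_length <- function(polylines) {
  sum(segment_lengths(polylines_to_segments(polylines)))
}
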