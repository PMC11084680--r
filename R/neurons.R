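new_neuron_set <- function(cells, roi) {
  stopifnot(is.data.frame(cells))
  structure(list(cells = cells, true_count = nrow(cells), roi = roi),
            class = "neuron_set")
}

#' @export
print.neuron_set <- function(x, ...) {
  cat(sprintf("<neuron_set> %d cells in %s\n", x$true_count, x$roi$name))
  invisible(x)
}

#' Generate a synthetic neuron population
#'
#' Places `true_count` cells with reference points uniform in the region
#' box. Cell shape is a sphere or a triaxial ellipsoid centered on the
#' reference point, with semi-axes drawn from `shape`.
#'
#' @param roi A [region_box()].
#' @param true_count Number of cells (>= 0).
#' @param shape Either `list(type = "sphere", radius =)` (scalar or
#'   length-2 uniform range), or `list(type = "ellipsoid", semi_axes =)`
#'   with a length-3 vector (fixed) or 3 x 2 matrix of uniform ranges.
#'   Default: spheres of radius 5 um (soma-scale).
#' @param seed Integer seed.
#'
#' @return A `neuron_set`: data frame `cells` with columns
#'   `x, y, z, a, b, c` (reference point and semi-axes, um) plus
#'   `true_count` and the `roi`.
#' @export
#' @examples
#' roi <- region_box("NbM", c(200, 200, 80))
#' generate_neurons(roi, 100, seed = 1)$true_count
generate_neurons <- function(roi, true_count,
                             shape = list(type = "sphere", radius = 5),
                             seed) {
  stopifnot(inherits(roi, "region_box"))
  stopifnot_scalar(true_count, "true_count", integerish = TRUE)
  if (true_count < 0) stop("`true_count` must be >= 0", call. = FALSE)
  hi <- unname(roi$extent)
  n <- as.integer(true_count)
  cells <- with_seed(seed, {
    pos <- cbind(x = runif(n, 0, hi[1]), y = runif(n, 0, hi[2]),
                 z = runif(n, 0, hi[3]))
    ax <- switch(shape$type,
      sphere = {
        r <- shape$radius
        rr <- if (length(r) == 2L) runif(n, r[1], r[2]) else rep(r, n)
        cbind(a = rr, b = rr, c = rr)
      },
      ellipsoid = {
        s <- shape$semi_axes
        if (is.matrix(s)) {
          cbind(a = runif(n, s[1, 1], s[1, 2]),
                b = runif(n, s[2, 1], s[2, 2]),
                c = runif(n, s[3, 1], s[3, 2]))
        } else {
          cbind(a = rep(s[1], n), b = rep(s[2], n), c = rep(s[3], n))
        }
      },
      stop("unknown shape type: ", shape$type, call. = FALSE))
    if (n > 0 && any(ax <= 0)) stop("semi-axes must be > 0", call. = FALSE)
    as.data.frame(cbind(pos, ax))
  })
  new_neuron_set(cells, roi)
}

#' Thin a neuron population by independent random loss
#'
#' Each cell is retained independently with probability
#' `1 - loss_fraction`; used to impose a known percent neuron loss on a
#' control population.
#'
#' @param neurons A `neuron_set`.
#' @param loss_fraction Probability of losing each cell, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `neuron_set` with the surviving cells and updated
#'   `true_count`.
#' @export
thin_neurons <- function(neurons, loss_fraction, seed) {
  stopifnot(inherits(neurons, "neuron_set"))
  if (loss_fraction < 0 || loss_fraction > 1)
    stop("`loss_fraction` must be in [0, 1]", call. = FALSE)
  keep <- with_seed(seed, runif(nrow(neurons$cells)) >= loss_fraction)
  new_neuron_set(neurons$cells[keep, , drop = FALSE], neurons$roi)
}
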