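new_plaque_set <- function(plaques, roi) {
  colnames(plaques) <- c("cx", "cy", "cz", "r")
  burden <- if (nrow(plaques)) sum(4 / 3 * pi * plaques[, "r"]^3) / roi$volume else 0
  structure(list(plaques = plaques, burden = burden, roi = roi),
            class = "plaque_set")
}

#' @export
print.plaque_set <- function(x, ...) {
  cat(sprintf("<plaque_set> %d plaques, burden %.3g\n",
              nrow(x$plaques), x$burden))
  invisible(x)
}

#' Generate a set of spherical amyloid-type plaques
#'
#' Places `count` non-overlapping spheres with centers uniform in the region
#' box by rejection sampling. Radii are drawn either uniformly between
#' `radius[1]` and `radius[2]`, or lognormally when `radius` is
#' `list(meanlog =, sdlog =)`. The recorded `burden` is the fraction of the
#' region volume occupied by plaque spheres (spheres are disjoint by
#' construction; small spill-over past the box edge is ignored).
#'
#' @param roi A [region_box()].
#' @param count Number of plaques (>= 0).
#' @param radius Length-2 numeric `c(min, max)` um for uniform radii, or
#'   `list(meanlog =, sdlog =)` for lognormal radii.
#' @param min_edge_separation Minimum surface-to-surface distance between
#'   plaques, um (default 0).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget per plaque (default 1000).
#'
#' @return A `plaque_set`: matrix `plaques` with columns `cx, cy, cz, r`
#'   (um), scalar `burden`, and the `roi`.
#' @export
#' @examples
#' roi <- region_box("Cg", c(100, 100, 40))
#' p <- generate_plaques(roi, count = 3, radius = c(5, 10), seed = 1)
#' p$burden
generate_plaques <- function(roi, count, radius = c(5, 12),
                             min_edge_separation = 0, seed,
                             max_attempts = 1000) {
  stopifnot(inherits(roi, "region_box"))
  stopifnot_scalar(count, "count", integerish = TRUE)
  if (count < 0) stop("`count` must be >= 0", call. = FALSE)
  if (min_edge_separation < 0)
    stop("`min_edge_separation` must be >= 0", call. = FALSE)
  if (count == 0)
    return(new_plaque_set(matrix(numeric(0), ncol = 4), roi))

  hi <- unname(roi$extent)
  with_seed(seed, {
    radii <- if (is.list(radius)) {
      rlnorm(count, radius$meanlog, radius$sdlog)
    } else {
      stopifnot(length(radius) == 2L, all(radius > 0))
      runif(count, radius[1], radius[2])
    }
    if (any(radii <= 0)) stop("plaque radii must be positive", call. = FALSE)
    # place the largest first: markedly better packing feasibility
    radii <- sort(radii, decreasing = TRUE)
    centers <- matrix(NA_real_, count, 3)
    for (i in seq_len(count)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- runif(3) * hi
        if (i > 1L) {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          gap <- sqrt(rowSums(sweep(prev, 2, cand)^2)) -
            radii[seq_len(i - 1L)] - radii[i]
          if (any(gap < min_edge_separation)) next
        }
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "plaque packing failed: placed %d of %d plaques (attempt budget %d)",
          i - 1L, count, max_attempts), call. = FALSE)
    }
    new_plaque_set(cbind(centers, radii), roi)
  })
}

#' Monte-Carlo estimate of plaque burden
#'
#' Independent check of the recorded `burden` field: fraction of uniform
#' sample points inside any plaque sphere.
#'
#' @param plaques A `plaque_set`.
#' @param n_points Number of Monte-Carlo points (default 20000).
#' @param seed Integer seed.
#' @return Estimated volume fraction.
#' @export
plaque_burden_mc <- function(plaques, n_points = 20000, seed = 1) {
  roi <- plaques$roi
  pm <- plaques$plaques
  if (nrow(pm) == 0L) return(0)
  hi <- unname(roi$extent)
  with_seed(seed, {
    pts <- cbind(runif(n_points, 0, hi[1]), runif(n_points, 0, hi[2]),
                 runif(n_points, 0, hi[3]))
    inside <- rep(FALSE, n_points)
    for (i in seq_len(nrow(pm))) {
      d2 <- (pts[, 1] - pm[i, 1])^2 + (pts[, 2] - pm[i, 2])^2 +
        (pts[, 3] - pm[i, 3])^2
      inside <- inside | d2 < pm[i, 4]^2
    }
    mean(inside)
  })
}

# signed distance from points (n x 3) to the nearest plaque EDGE:
# negative inside a plaque, Inf when the set is empty
plaque_edge_distance <- function(points, plaques) {
  pm <- if (inherits(plaques, "plaque_set")) plaques$plaques else plaques
  n <- nrow(points)
  if (is.null(pm) || nrow(pm) == 0L) return(rep(Inf, n))
  d <- rep(Inf, n)
  for (i in seq_len(nrow(pm))) {
    di <- sqrt((points[, 1] - pm[i, 1])^2 + (points[, 2] - pm[i, 2])^2 +
                 (points[, 3] - pm[i, 3])^2) - pm[i, 4]
    d <- pmin(d, di)
  }
  d
}
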