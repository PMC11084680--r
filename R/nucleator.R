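#' Nucleator estimate of cell volume and cross-sectional area
#'
#' Vertical-design nucleator: rays from the cell's reference point are
#' drawn in planes containing the vertical (cutting) axis, with the
#' colatitude sine-weighted, which makes the ray directions isotropic in
#' 3D. For each ray the distance l to the cell boundary gives the unbiased
#' estimators `V = (4*pi/3) * mean(l^3)` and profile area
#' `A = pi * mean(l^2)`. For a sphere probed from its center l is constant,
#' so the estimate is exact with zero variance.
#'
#' @param shape Cell shape: `list(center =, semi_axes =)` with a length-3
#'   center (um) and length-3 semi-axes (a sphere when all equal); axes are
#'   aligned with the coordinate axes.
#' @param n_rays Number of rays (>= 2).
#' @param reference_point Ray origin (defaults to the shape center); must
#'   lie inside the shape, which must be star-shaped about it (always true
#'   for ellipsoids and interior points).
#' @param vertical_axis The vertical axis of the design; `"z"` (the cutting
#'   axis) by default. The estimator is isotropic, so this only fixes the
#'   sampling frame.
#' @param seed Integer seed.
#' @return A `size_estimate`: `volume` (um^3), `area` (um^2), `n_rays`,
#'   `ray_lengths`.
#' @export
#' @examples
#' s <- list(center = c(0, 0, 0), semi_axes = c(5, 5, 5))
#' nucleator_size(s, n_rays = 4, seed = 1)$volume # (4*pi/3) * 125
nucleator_size <- function(shape, n_rays = 6, reference_point = NULL,
                           vertical_axis = "z", seed) {
  stopifnot_scalar(n_rays, "n_rays", positive = TRUE, integerish = TRUE)
  if (n_rays < 2) stop("`n_rays` must be >= 2", call. = FALSE)
  ctr <- as.numeric(shape$center)
  ax <- as.numeric(shape$semi_axes)
  stopifnot(length(ctr) == 3L, length(ax) == 3L, all(ax > 0))
  p <- if (is.null(reference_point)) ctr else as.numeric(reference_point)
  q <- (p - ctr) / ax
  if (sum(q^2) >= 1)
    stop("reference point lies outside the cell", call. = FALSE)
  if (!vertical_axis %in% c("x", "y", "z"))
    stop("`vertical_axis` must be one of x, y, z", call. = FALSE)

  dirs <- with_seed(seed, {
    phi <- runif(n_rays, 0, 2 * pi)     # azimuth of the vertical plane
    cos_t <- runif(n_rays, -1, 1)       # sine-weighted colatitude
    sin_t <- sqrt(pmax(0, 1 - cos_t^2))
    d <- cbind(sin_t * cos(phi), sin_t * sin(phi), cos_t)
    # permute so the sampled colatitude is measured from the vertical axis
    switch(vertical_axis,
           z = d, x = d[, c(3, 1, 2), drop = FALSE],
           y = d[, c(2, 3, 1), drop = FALSE])
  })
  # ray/ellipsoid boundary: solve sum(((q + l*d)/1)^2) = 1 in scaled coords
  ds <- sweep(dirs, 2, ax, "/")
  A <- rowSums(ds^2)
  B <- 2 * (ds[, 1] * q[1] + ds[, 2] * q[2] + ds[, 3] * q[3])
  C <- sum(q^2) - 1
  l <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  structure(
    list(volume = 4 * pi / 3 * mean(l^3),
         area = pi * mean(l^2),
         n_rays = as.integer(n_rays),
         ray_lengths = l),
    class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("<size_estimate> V = %.4g um^3, A = %.4g um^2 (%d rays)\n",
              x$volume, x$area, x$n_rays))
  invisible(x)
}

#' Mean nucleator size over a neuron population
#'
#' Applies [nucleator_size()] to every cell of a `neuron_set` (reference
#' point = cell centroid) and averages.
#'
#' @param neurons A `neuron_set`.
#' @param n_rays Rays per cell.
#' @param seed Integer seed (per-cell seeds are derived from it).
#' @return List with `mean_volume`, `mean_area`, `n_cells` and the
#'   per-cell data frame `per_cell`.
#' @export
nucleator_sizes <- function(neurons, n_rays = 6, seed) {
  stopifnot(inherits(neurons, "neuron_set"))
  cells <- neurons$cells
  n <- nrow(cells)
  if (n == 0L)
    return(list(mean_volume = NA_real_, mean_area = NA_real_, n_cells = 0L,
                per_cell = data.frame()))
  seeds <- child_seeds(seed, n)
  res <- lapply(seq_len(n), function(i) {
    est <- nucleator_size(
      list(center = as.numeric(cells[i, c("x", "y", "z")]),
           semi_axes = as.numeric(cells[i, c("a", "b", "c")])),
      n_rays = n_rays, seed = seeds[i])
    c(volume = est$volume, area = est$area)
  })
  per_cell <- as.data.frame(do.call(rbind, res))
  list(mean_volume = mean(per_cell$volume),
       mean_area = mean(per_cell$area),
       n_cells = n,
       per_cell = per_cell)
}
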