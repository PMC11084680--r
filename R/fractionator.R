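#' Optical fractionator sampling design
#'
#' The default values are the classical design for basal-forebrain counts:
#' a 100 x 100 um counting frame on a 200 x 200 um sampling grid, a 10 um
#' dissector with a 1 um guard, every 6th section.
#'
#' @param counting_frame Frame width/height `c(w, h)` um.
#' @param sampling_grid Grid step `c(gx, gy)` um; the frame must fit in a
#'   grid cell.
#' @param dissector_height Height of the optical dissector, um (measured in
#'   the mounted section).
#' @param guard Guard distance from the upper cut surface, um.
#' @param section_interval Count every k-th section.
#' @param mounted_thickness Mounted section thickness, um; must accommodate
#'   `dissector_height + 2 * guard`.
#' @return A `fractionator_design` with the three sampling fractions
#'   (`ssf`, `asf`, `hsf`) precomputed.
#' @export
#' @examples
#' fractionator_design()$asf # 1/4
fractionator_design <- function(counting_frame = c(100, 100),
                                sampling_grid = c(200, 200),
                                dissector_height = 10,
                                guard = 1,
                                section_interval = 6,
                                mounted_thickness = 20) {
  stopifnot(length(counting_frame) == 2L, all(counting_frame > 0),
            length(sampling_grid) == 2L, all(sampling_grid > 0))
  if (any(counting_frame > sampling_grid))
    stop("counting frame must fit inside the sampling grid cell", call. = FALSE)
  stopifnot_scalar(dissector_height, "dissector_height", positive = TRUE)
  if (guard < 0) stop("`guard` must be >= 0", call. = FALSE)
  stopifnot_scalar(section_interval, "section_interval", positive = TRUE,
                   integerish = TRUE)
  stopifnot_scalar(mounted_thickness, "mounted_thickness", positive = TRUE)
  if (dissector_height + 2 * guard > mounted_thickness)
    stop("dissector height + 2*guard exceeds mounted thickness", call. = FALSE)
  structure(
    list(counting_frame = counting_frame,
         sampling_grid = sampling_grid,
         dissector_height = dissector_height,
         guard = guard,
         section_interval = as.integer(section_interval),
         mounted_thickness = mounted_thickness,
         ssf = 1 / section_interval,
         asf = prod(counting_frame) / prod(sampling_grid),
         hsf = dissector_height / mounted_thickness),
    class = "fractionator_design")
}

#' @export
print.fractionator_design <- function(x, ...) {
  cat(sprintf(
    "<fractionator_design> frame %gx%g / grid %gx%g um, h = %g um, guard %g um, every %d-th section\n",
    x$counting_frame[1], x$counting_frame[2], x$sampling_grid[1],
    x$sampling_grid[2], x$dissector_height, x$guard, x$section_interval))
  cat(sprintf("  ssf = %.4g, asf = %.4g, hsf = %.4g\n", x$ssf, x$asf, x$hsf))
  invisible(x)
}

#' Count neurons in dissector frames over sampled sections
#'
#' Frames tile each sampled section on a systematic-uniform-random grid
#' (one random offset per run). A cell is counted iff its unique reference
#' point falls strictly inside the frame or on the two inclusion edges
#' (right/top) — never on the forbidden left/bottom edges or their
#' extensions — and its mounted-depth coordinate lies inside the dissector
#' window `[guard, guard + dissector_height)`.
#'
#' @param neurons A `neuron_set` (reference points in global cut
#'   coordinates).
#' @param design A [fractionator_design()].
#' @param section_set A `section_set` whose `sampling_interval` and
#'   `mounted_thickness` match the design.
#' @param seed Integer seed for the grid offset.
#' @param offset Optional fixed grid offset `c(ox, oy)` um overriding the
#'   random one (useful for design checks; offsets differing by whole grid
#'   steps give identical counts).
#' @return Integer `sum_Qminus`; per-section counts are attached as the
#'   `"per_section"` attribute.
#' @export
count_in_frames <- function(neurons, design, section_set, seed,
                            offset = NULL) {
  stopifnot(inherits(neurons, "neuron_set"),
            inherits(design, "fractionator_design"),
            inherits(section_set, "section_set"))
  if (section_set$sampling_interval != design$section_interval)
    stop("section_set sampling interval does not match the design", call. = FALSE)
  if (abs(section_set$mounted_thickness - design$mounted_thickness) > 1e-9)
    stop("section_set mounted thickness does not match the design", call. = FALSE)
  cells <- neurons$cells
  t <- section_set$section_thickness
  shrink <- section_set$shrink
  w <- design$counting_frame[1]; h <- design$counting_frame[2]
  gx <- design$sampling_grid[1]; gy <- design$sampling_grid[2]
  off <- if (is.null(offset)) with_seed(seed, runif(2) * c(gx, gy)) else
    as.numeric(offset)
  per_section <- vapply(section_set$sections, function(sec) {
    z0 <- sec$z0
    in_slab <- cells$z >= z0 & cells$z < z0 + t
    if (!any(in_slab)) return(0L)
    cz <- (cells$z[in_slab] - z0) * shrink # mounted local depth
    in_z <- cz >= design$guard & cz < design$guard + design$dissector_height
    if (!any(in_z)) return(0L)
    x <- cells$x[in_slab][in_z]; y <- cells$y[in_slab][in_z]
    # position within the grid cell; frame occupies (0, w] x (0, h]
    u <- (x - off[1]) %% gx
    v <- (y - off[2]) %% gy
    sum(u > 0 & u <= w & v > 0 & v <= h)
  }, 0L)
  out <- sum(per_section)
  attr(out, "per_section") <- per_section
  out
}

#' Optical fractionator total-number estimate
#'
#' `N_hat = sum_Qminus / (ssf * asf * hsf)` with the section, area and
#' thickness sampling fractions of the design.
#'
#' @param sum_Qminus Total dissector count (>= 0).
#' @param design A [fractionator_design()].
#' @return A `count_estimate` with `N_hat` and the three fractions.
#' @export
#' @examples
#' d <- fractionator_design()
#' fractionator_estimate(25, d)$N_hat # 25 * 6 * 4 * 2
fractionator_estimate <- function(sum_Qminus, design) {
  stopifnot(inherits(design, "fractionator_design"))
  sum_Qminus <- as.numeric(sum_Qminus)
  if (sum_Qminus < 0) stop("`sum_Qminus` must be >= 0", call. = FALSE)
  if (design$ssf <= 0 || design$asf <= 0 || design$hsf <= 0)
    stop("all sampling fractions must be > 0", call. = FALSE)
  structure(
    list(sum_Qminus = sum_Qminus,
         ssf = design$ssf, asf = design$asf, hsf = design$hsf,
         N_hat = sum_Qminus / (design$ssf * design$asf * design$hsf)),
    class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("<count_estimate> N = %.1f (sum Q- = %g; 1/ssf=%g 1/asf=%g 1/hsf=%g)\n",
              x$N_hat, x$sum_Qminus, 1 / x$ssf, 1 / x$asf, 1 / x$hsf))
  invisible(x)
}
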