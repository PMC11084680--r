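#' Place virtual spherical probes in sampled sections
#'
#' Probes are allocated evenly across the sampled sections (all sections
#' share the region's xy-area), positioned in the plane on a
#' systematic-uniform-random grid (square grid with a uniformly random
#' offset), and in depth uniformly at random so that the whole sphere —
#' a true sphere in tissue (cut) coordinates — stays inside the guarded
#' z-window of the mounted section.
#'
#' @param section_set A [slice_sections()] result.
#' @param roi The [region_box()] the sections came from.
#' @param n_locations Total number of probe locations (default 50).
#' @param probe_radius Sphere radius in tissue um (default 5, i.e. a 10 um
#'   diameter probe).
#' @param guard_z Guard distance from each mounted cut surface, um
#'   (default 1).
#' @param seed Integer seed.
#'
#' @return A data frame of class `sphere_probe_frame` with one row per
#'   probe: `probe_id`, `section` (index into the sampled sections),
#'   `x`, `y` (um), `z_mounted` (local mounted z of the center),
#'   `z_world` (center z in global cut coordinates), `radius`,
#'   `surface_area` (full sphere, tissue um^2), `Q` (NA until counted) and
#'   `proximity` (`"unset"` until classified).
#' @export
place_probes <- function(section_set, roi, n_locations = 50,
                         probe_radius = 5, guard_z = 1, seed) {
  stopifnot(inherits(section_set, "section_set"))
  stopifnot_scalar(n_locations, "n_locations", positive = TRUE,
                   integerish = TRUE)
  stopifnot_scalar(probe_radius, "probe_radius", positive = TRUE)
  if (guard_z < 0) stop("`guard_z` must be >= 0", call. = FALSE)
  m <- section_set$mounted_thickness
  if (2 * probe_radius + 2 * guard_z > m)
    stop(sprintf(
      "probe does not fit: 2*radius + 2*guard = %g um exceeds mounted thickness %g um",
      2 * probe_radius + 2 * guard_z, m), call. = FALSE)
  shrink <- section_set$shrink
  # mounted z-extent of the tissue-coordinate sphere is 2*r*shrink
  z_lo <- guard_z + probe_radius * shrink
  z_hi <- m - guard_z - probe_radius * shrink
  n_sec <- length(section_set$sections)
  hi <- unname(roi$extent)

  with_seed(seed, {
    per <- diff(round(seq(0, n_locations, length.out = n_sec + 1)))
    rows <- vector("list", n_sec)
    r <- probe_radius
    if (hi[1] <= 2 * r || hi[2] <= 2 * r)
      stop("region too small in xy for the probe radius", call. = FALSE)
    for (i in seq_len(n_sec)) {
      ni <- per[i]
      if (ni == 0L) next
      # SUR grid over the inset rectangle so the whole sphere stays inside
      # the region laterally
      wx <- hi[1] - 2 * r; wy <- hi[2] - 2 * r
      g <- sqrt(wx * wy / ni)
      off <- runif(2, 0, g)
      gx <- seq(r + off[1], hi[1] - r, by = g)
      gy <- seq(r + off[2], hi[2] - r, by = g)
      pts <- expand.grid(x = gx, y = gy)
      zc <- runif(nrow(pts), z_lo, z_hi)
      z0 <- section_set$sections[[i]]$z0
      rows[[i]] <- data.frame(
        section = i, x = pts$x, y = pts$y, z_mounted = zc,
        z_world = z0 + zc / shrink)
    }
    out <- do.call(rbind, rows)
    out <- cbind(probe_id = seq_len(nrow(out)), out)
    out$radius <- probe_radius
    out$surface_area <- 4 * pi * probe_radius^2
    out$Q <- NA_integer_
    out$proximity <- "unset"
    rownames(out) <- NULL
    class(out) <- c("sphere_probe_frame", class(out))
    out
  })
}

#' Count fiber crossings of a sphere surface
#'
#' Counts the transversal intersections of polyline segments with the
#' surface of a sphere: the segment/sphere quadratic is solved per segment
#' and each root strictly inside the open segment-parameter interval counts
#' once. Tangencies (zero discriminant) count zero; a vertex lying exactly
#' on the surface is perturbed radially outward by 1e-9 um as a tie-break.
#' Degenerate (zero-length) segments carry no length and are dropped.
#'
#' @param center Sphere center, length-3 numeric (um).
#' @param radius Sphere radius (um).
#' @param field A `fiber_field`, or a segment matrix with columns
#'   `x1 y1 z1 x2 y2 z2` in the same coordinate frame as the probe.
#' @return Integer crossing count Q.
#' @export
#' @examples
#' seg <- matrix(c(-20, 0, 0, 20, 0, 0), 1)
#' count_crossings(c(0, 0, 0), 5, seg) # chord through the center: Q = 2
count_crossings <- function(center, radius, field) {
  seg <- if (inherits(field, "fiber_field")) field$segments else field
  if (is.null(seg) || nrow(seg) == 0L) return(0L)
  stopifnot_scalar(radius, "radius", positive = TRUE)
  cand <- segments_near_sphere(seg, center, radius)
  if (!length(cand)) return(0L)
  s <- seg[cand, , drop = FALSE]
  len2 <- (s[, 4] - s[, 1])^2 + (s[, 5] - s[, 2])^2 + (s[, 6] - s[, 3])^2
  s <- s[len2 > 0, , drop = FALSE]
  if (nrow(s) == 0L) return(0L)
  # tie-break: push vertices lying exactly on the surface radially outward
  for (cols in list(1:3, 4:6)) {
    p <- s[, cols, drop = FALSE]
    d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
                (p[, 3] - center[3])^2)
    on_surface <- which(d == radius)
    if (length(on_surface)) {
      sc <- 1 + 1e-9 / radius
      for (i in on_surface)
        s[i, cols] <- center + (s[i, cols] - center) * sc
    }
  }
  roots <- segment_sphere_roots(s, center, radius)
  sum(roots > 0 & roots < 1, na.rm = TRUE)
}

#' Count crossings for every probe in a probe frame
#'
#' Fills the `Q` column: each probe is matched with its section's fiber
#' geometry. Counting is performed in tissue (cut) coordinates — the
#' mounted-section z-axis is expanded back by the recorded shrinkage factor
#' — so the probe is a true sphere in the tissue and the crossing counts
#' estimate tissue-scale length density for any fiber orientation.
#'
#' @param probes A `sphere_probe_frame` from [place_probes()].
#' @param section_set The matching `section_set`.
#' @return The probe frame with `Q` filled in.
#' @export
probe_crossings <- function(probes, section_set) {
  stopifnot(inherits(section_set, "section_set"))
  shrink <- section_set$shrink
  cut_segs <- lapply(seq_along(section_set$sections), function(i)
    section_segments(section_set, i, frame = "cut"))
  probes$Q <- vapply(seq_len(nrow(probes)), function(j) {
    ctr <- c(probes$x[j], probes$y[j], probes$z_mounted[j] / shrink)
    count_crossings(ctr, probes$radius[j], cut_segs[[probes$section[j]]])
  }, integer(1))
  probes
}

#' Spaceball estimate of fiber length density
#'
#' The classical spherical-probe identity: an isotropic probe surface of
#' area s intersected by a fiber process of length density L_V yields
#' E(Q) = L_V * s / 2, so `Lv_hat = 2 * sum(Q) / sum(surface_area)` is
#' unbiased for any fiber orientation distribution.
#'
#' @param probes A `sphere_probe_frame` with `Q` filled
#'   (see [probe_crossings()]).
#' @return A `length_estimate`: `Lv_hat` (um/um^3), `sum_Q`, `n_probes`,
#'   `total_surface_area`.
#' @export
estimate_length_density <- function(probes) {
  if (nrow(probes) < 1L)
    stop("need at least one probe", call. = FALSE)
  if (anyNA(probes$Q))
    stop("probes have uncounted Q; run probe_crossings() first",
         call. = FALSE)
  s_tot <- sum(probes$surface_area)
  if (s_tot <= 0) stop("total probe surface area must be > 0", call. = FALSE)
  structure(
    list(Lv_hat = 2 * sum(probes$Q) / s_tot,
         sum_Q = sum(probes$Q),
         n_probes = nrow(probes),
         total_surface_area = s_tot),
    class = "length_estimate")
}

#' @export
print.length_estimate <- function(x, ...) {
  cat(sprintf("<length_estimate> Lv = %.5g um/um^3 (sum Q = %d over %d probes)\n",
              x$Lv_hat, x$sum_Q, x$n_probes))
  invisible(x)
}

#' Total fiber length in the reference region
#'
#' Converts a length-density estimate to total length in pre-shrinkage
#' (cut) tissue coordinates: `L_hat = Lv_hat * volume(roi)`. The axial
#' shrinkage correction is already embedded in the density — crossings are
#' counted in cut coordinates using the z-rescaling factor recorded by
#' [slice_sections()] — so the section set is required as evidence that the
#' factor is known.
#'
#' @param est A `length_estimate`.
#' @param roi The reference [region_box()].
#' @param section_set The `section_set` used for counting (must carry the
#'   shrinkage metadata).
#' @return Estimated total length L in um.
#' @export
estimate_total_length <- function(est, roi, section_set) {
  stopifnot(inherits(est, "length_estimate"), inherits(roi, "region_box"))
  if (!inherits(section_set, "section_set") ||
      is.null(section_set$shrink) || !is.finite(section_set$shrink))
    stop("section_set with shrinkage metadata required", call. = FALSE)
  est$Lv_hat * roi$volume
}
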