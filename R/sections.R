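# clip a segment matrix (with optional per-segment zone labels) to the
# half-open z-slab [z0, z1); returns the clipped segments and their labels
clip_segments_to_slab <- function(seg, zone, z0, z1) {
  n <- nrow(seg)
  if (n == 0L)
    return(list(segments = seg, zone = zone))
  za <- seg[, 3]; zb <- seg[, 6]
  dz <- zb - za
  s_lo <- ifelse(dz != 0, (z0 - za) / dz, -Inf)
  s_hi <- ifelse(dz != 0, (z1 - za) / dz, Inf)
  s0 <- pmax(0, pmin(s_lo, s_hi))
  s1 <- pmin(1, pmax(s_lo, s_hi))
  flat <- dz == 0
  inside_flat <- flat & za >= z0 & za < z1
  s0[flat] <- ifelse(inside_flat[flat], 0, 1)
  s1[flat] <- ifelse(inside_flat[flat], 1, 0)
  keep <- which(s1 - s0 > 1e-12)
  if (!length(keep))
    return(list(segments = seg[0, , drop = FALSE], zone = zone[0]))
  p1 <- seg[keep, 1:3, drop = FALSE]
  d <- seg[keep, 4:6, drop = FALSE] - p1
  out <- cbind(p1 + s0[keep] * d, p1 + s1[keep] * d)
  colnames(out) <- colnames(seg)
  list(segments = out, zone = if (is.null(zone)) NULL else zone[keep])
}

#' Slice a scene into systematically sampled thick sections
#'
#' Cuts the region into consecutive z-slabs of `section_thickness` (the
#' slabs partition the region exactly), selects every
#' `sampling_interval`-th slab starting from a uniformly random phase
#' (systematic-uniform-random sampling), clips the fiber geometry to each
#' sampled slab, and rescales local z from the cut thickness to the mounted
#' (post-shrinkage) thickness — a uniform axial shrinkage model.
#'
#' @param x A `fiber_field` or a [scene()] (whose `fibers` are sliced).
#' @param section_thickness Cut thickness, um (default 40).
#' @param sampling_interval Keep every k-th section (default 1).
#' @param mounted_thickness Post-shrinkage thickness, um, in
#'   `(0, section_thickness]` (default 20).
#' @param phase_seed Integer seed for the random starting phase.
#'
#' @return A `section_set`: sampled sections (each with `index`, `z0`, and
#'   fiber `segments` in mounted local coordinates, z in `[0, mounted)`),
#'   plus the sampling metadata (`shrink = mounted/cut` rescaling factor,
#'   `phase`, `n_total`).
#' @export
#' @examples
#' roi <- region_box("M1", c(100, 100, 80))
#' f <- generate_fiber_field(roi, 0.01, seed = 1)
#' ss <- slice_sections(f, sampling_interval = 2, phase_seed = 2)
#' length(ss$sections)
slice_sections <- function(x, section_thickness = 40, sampling_interval = 1,
                           mounted_thickness = 20, phase_seed) {
  field <- if (inherits(x, "scene")) x$fibers else x
  stopifnot(inherits(field, "fiber_field"))
  stopifnot_scalar(sampling_interval, "sampling_interval", integerish = TRUE)
  if (sampling_interval < 1)
    stop("`sampling_interval` must be >= 1", call. = FALSE)
  if (mounted_thickness <= 0 || mounted_thickness > section_thickness)
    stop("`mounted_thickness` must be in (0, section_thickness]",
         call. = FALSE)
  roi <- field$roi
  n_total <- round(roi$extent[["z"]] / section_thickness)
  if (abs(n_total * section_thickness - roi$extent[["z"]]) > 1e-6)
    stop("z extent must be an integer multiple of section thickness",
         call. = FALSE)
  shrink <- mounted_thickness / section_thickness
  phase <- with_seed(phase_seed,
                     sample.int(sampling_interval, 1L) - 1L)
  sampled <- seq(phase + 1L, n_total, by = sampling_interval)
  seg <- field$segments
  zone <- field$segment_zone
  sections <- lapply(sampled, function(i) {
    z0 <- (i - 1) * section_thickness
    cl <- clip_segments_to_slab(seg, zone, z0, z0 + section_thickness)
    s <- cl$segments
    if (nrow(s)) { # local mounted z
      s[, 3] <- (s[, 3] - z0) * shrink
      s[, 6] <- (s[, 6] - z0) * shrink
    }
    list(index = i, z0 = z0, segments = s, zone = cl$zone)
  })
  structure(
    list(sections = sections,
         section_thickness = section_thickness,
         sampling_interval = as.integer(sampling_interval),
         mounted_thickness = mounted_thickness,
         shrink = shrink,
         phase = phase,
         n_total = n_total,
         roi = roi),
    class = "section_set")
}

#' @export
print.section_set <- function(x, ...) {
  cat(sprintf(
    "<section_set> %d of %d sections (every %d-th, phase %d), %g -> %g um\n",
    length(x$sections), x$n_total, x$sampling_interval, x$phase,
    x$section_thickness, x$mounted_thickness))
  invisible(x)
}

#' Fiber segments of one sampled section
#'
#' @param section_set A `section_set`.
#' @param i Index into the sampled sections.
#' @param frame `"mounted"` (local z in `[0, mounted_thickness)`, as
#'   observed under the objective) or `"cut"` (local z rescaled back to the
#'   cut thickness, i.e. true tissue coordinates).
#' @return Segment matrix with columns `x1 y1 z1 x2 y2 z2`.
#' @export
section_segments <- function(section_set, i, frame = c("mounted", "cut")) {
  frame <- match.arg(frame)
  s <- section_set$sections[[i]]$segments
  if (frame == "cut" && nrow(s)) {
    s[, 3] <- s[, 3] / section_set$shrink
    s[, 6] <- s[, 6] / section_set$shrink
  }
  s
}

#' Total clipped fiber length across sampled sections
#'
#' @inheritParams section_segments
#' @return Total length in um, in the requested frame.
#' @export
section_fiber_length <- function(section_set, frame = c("cut", "mounted")) {
  frame <- match.arg(frame)
  sum(vapply(seq_along(section_set$sections), function(i)
    sum(segment_lengths(section_segments(section_set, i, frame))), 0))
}
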