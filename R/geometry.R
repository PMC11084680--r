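# Segment/sphere intersection parameters, vectorized over segments.
# Returns a two-column matrix of root parameters (NA when no real root or
# the segment is degenerate); roots are on the infinite line through the
# segment, in units of the segment parameter s in [0, 1].
segment_sphere_roots <- function(seg, center, r) {
  n <- nrow(seg)
  out <- matrix(NA_real_, n, 2)
  if (n == 0L) return(out)
  dx <- seg[, 4] - seg[, 1]; dy <- seg[, 5] - seg[, 2]; dz <- seg[, 6] - seg[, 3]
  fx <- seg[, 1] - center[1]; fy <- seg[, 2] - center[2]; fz <- seg[, 3] - center[3]
  a <- dx^2 + dy^2 + dz^2
  b <- 2 * (fx * dx + fy * dy + fz * dz)
  cc <- fx^2 + fy^2 + fz^2 - r^2
  disc <- b^2 - 4 * a * cc
  ok <- which(disc > 0 & a > 0)
  if (length(ok)) {
    sq <- sqrt(disc[ok])
    out[ok, 1] <- (-b[ok] - sq) / (2 * a[ok])
    out[ok, 2] <- (-b[ok] + sq) / (2 * a[ok])
  }
  out
}

# quick axis-aligned bounding-box prefilter: indices of segments whose AABB
# intersects the sphere's AABB
segments_near_sphere <- function(seg, center, r) {
  which(pmin(seg[, 1], seg[, 4]) <= center[1] + r &
          pmax(seg[, 1], seg[, 4]) >= center[1] - r &
          pmin(seg[, 2], seg[, 5]) <= center[2] + r &
          pmax(seg[, 2], seg[, 5]) >= center[2] - r &
          pmin(seg[, 3], seg[, 6]) <= center[3] + r &
          pmax(seg[, 3], seg[, 6]) >= center[3] - r)
}
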