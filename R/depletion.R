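#' Apply plaque-local fiber depletion to a fiber field
#'
#' Models the local toxicity of compact amyloid deposits: every polyline is
#' split where it crosses a zone boundary (plaque surface, or the
#' near/distant shell at `threshold_d` from the plaque edge). Length
#' elements falling inside any plaque are removed deterministically
#' (compact cores displace neuropil); elements in the near shell are
#' retained independently with probability `survival_near`, distant
#' elements with `survival_distant`. Zone membership of an element is the
#' signed distance of its midpoint from the nearest plaque edge.
#'
#' @param field A `fiber_field`.
#' @param plaques A `plaque_set` (may be empty: everything is then distant,
#'   so `survival_distant` acts as a global thinning fraction).
#' @param threshold_d Near/distant threshold distance from the plaque edge,
#'   um (default 20).
#' @param survival_near,survival_distant Per-element retention
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed for the retention draws.
#'
#' @return A new `fiber_field` whose `true_length_by_zone` records the
#'   surviving length per zone (`inside` is always 0) and whose
#'   `predepletion_length_by_zone` attribute records zone lengths before
#'   depletion; `segment_zone` labels every surviving segment.
#' @export
#' @examples
#' roi <- region_box("DG", c(100, 100, 40))
#' f <- generate_fiber_field(roi, 0.02, seed = 1)
#' p <- generate_plaques(roi, 2, c(8, 10), seed = 2)
#' fd <- apply_depletion(f, p, survival_near = 0.4, survival_distant = 1,
#'                       seed = 3)
#' fd$true_length_by_zone
apply_depletion <- function(field, plaques, threshold_d = 20,
                            survival_near, survival_distant, seed) {
  stopifnot(inherits(field, "fiber_field"))
  stopifnot_scalar(threshold_d, "threshold_d", positive = TRUE)
  for (s in c(survival_near, survival_distant))
    if (s < 0 || s > 1) stop("survival fractions must be in [0, 1]", call. = FALSE)

  seg <- field$segments
  n <- nrow(seg)
  pm <- if (inherits(plaques, "plaque_set")) plaques$plaques else plaques
  if (is.null(pm)) pm <- matrix(numeric(0), ncol = 4)
  empty_zone <- c(inside = 0, near = 0, distant = 0)
  if (n == 0L) {
    out <- new_fiber_field(list(), field$orientation, field$roi, empty_zone)
    attr(out, "predepletion_length_by_zone") <- empty_zone
    out$depletion <- list(threshold_d = threshold_d,
                          survival = c(near = survival_near,
                                       distant = survival_distant))
    return(out)
  }

  # split parameters where segments cross the plaque surface or the
  # near/distant shell boundary
  br_i <- integer(0); br_t <- numeric(0)
  for (p in seq_len(nrow(pm))) {
    ctr <- pm[p, 1:3]
    for (rad in c(pm[p, 4], pm[p, 4] + threshold_d)) {
      cand <- segments_near_sphere(seg, ctr, rad)
      if (!length(cand)) next
      roots <- segment_sphere_roots(seg[cand, , drop = FALSE], ctr, rad)
      for (k in 1:2) {
        hit <- which(!is.na(roots[, k]) & roots[, k] > 0 & roots[, k] < 1)
        br_i <- c(br_i, cand[hit]); br_t <- c(br_t, roots[hit, k])
      }
    }
  }

  # build pieces: per segment, parameter intervals delimited by its breaks
  ord <- order(br_i, br_t)
  br_i <- br_i[ord]; br_t <- br_t[ord]
  n_breaks <- tabulate(br_i, n)
  n_pieces <- n_breaks + 1L
  idx_end <- cumsum(n_pieces)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  total <- idx_end[n]
  t0 <- numeric(total); t1 <- numeric(total)
  t0[idx_start] <- 0
  if (length(br_t)) t0[-idx_start] <- br_t
  t1[idx_end] <- 1
  if (length(br_t)) t1[-idx_end] <- br_t
  piece_seg <- rep(seq_len(n), n_pieces)

  p1 <- seg[piece_seg, 1:3, drop = FALSE]
  dvec <- seg[piece_seg, 4:6, drop = FALSE] - p1
  a0 <- p1 + t0 * dvec
  a1 <- p1 + t1 * dvec
  mid <- p1 + (t0 + t1) / 2 * dvec
  plen <- (t1 - t0) * segment_lengths(seg)[piece_seg]

  dmin <- plaque_edge_distance(mid, pm)
  zone <- ifelse(dmin <= 0, "inside",
                 ifelse(dmin <= threshold_d, "near", "distant"))

  pre <- vapply(c("inside", "near", "distant"),
                function(z) sum(plen[zone == z]), 0)
  names(pre) <- c("inside", "near", "distant")

  keep <- with_seed(seed, {
    u <- runif(total)
    (zone == "near" & u < survival_near) |
      (zone == "distant" & u < survival_distant)
  })

  surv <- vapply(c("inside", "near", "distant"),
                 function(z) sum(plen[keep & zone == z]), 0)
  names(surv) <- c("inside", "near", "distant")

  if (nrow(pm) == 0L && survival_near == 1 && survival_distant == 1) {
    # exact pass-through: no zone boundaries, nothing removed
    out <- new_fiber_field(field$polylines, field$orientation, field$roi,
                           surv)
    out$segment_zone <- rep("distant", n)
  } else {
    ki <- which(keep)
    polylines <- lapply(ki, function(i) unname(rbind(a0[i, ], a1[i, ])))
    out <- new_fiber_field(polylines, field$orientation, field$roi, surv)
    out$segment_zone <- zone[ki]
  }
  attr(out, "predepletion_length_by_zone") <- pre
  out$depletion <- list(threshold_d = threshold_d,
                        survival = c(near = survival_near,
                                     distant = survival_distant))
  out
}
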