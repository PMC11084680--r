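#' @keywords internal
normalize_orientation <- function(orientation) {
  if (is.character(orientation) && length(orientation) == 1L) {
    if (orientation == "isotropic") return(list(type = "isotropic"))
    m <- regmatches(orientation, regexec("^parallel-([xyz])$", orientation))[[1]]
    if (length(m) == 2L) return(list(type = "parallel", axis = m[2]))
    stop("unknown orientation model: ", orientation, call. = FALSE)
  }
  if (is.list(orientation) && !is.null(orientation$type)) {
    type <- orientation$type
    if (type == "isotropic") return(list(type = "isotropic"))
    if (type == "parallel") {
      axis <- orientation$axis %||% "x"
      stopifnot(axis %in% c("x", "y", "z"))
      return(list(type = "parallel", axis = axis))
    }
    if (type == "mixed") {
      w <- orientation$weight %||% 0.5
      stopifnot(w >= 0, w <= 1)
      return(list(type = "mixed", axis = orientation$axis %||% "x", weight = w))
    }
  }
  stop("orientation must be 'isotropic', 'parallel-<axis>' or a mixed spec",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

axis_unit <- function(axis) {
  switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
}

# uniform directions on the unit sphere (n x 3)
random_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# rotate each row of `dir` by a random polar angle <= max_turn (radians),
# uniform over the spherical cap around the current direction
turn_directions <- function(dir, max_turn) {
  n <- nrow(dir)
  if (n == 0L) return(dir)
  cos_t <- runif(n, cos(max_turn), 1)
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- runif(n, 0, 2 * pi)
  # per-row orthonormal frame; helper axis switched away from near-parallel z
  hz <- abs(dir[, 3]) < 0.9
  h <- cbind(ifelse(hz, 0, 1), 0, ifelse(hz, 1, 0))
  u <- cbind(dir[, 2] * h[, 3] - dir[, 3] * h[, 2],
             dir[, 3] * h[, 1] - dir[, 1] * h[, 3],
             dir[, 1] * h[, 2] - dir[, 2] * h[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dir[, 2] * u[, 3] - dir[, 3] * u[, 2],
             dir[, 3] * u[, 1] - dir[, 1] * u[, 3],
             dir[, 1] * u[, 2] - dir[, 2] * u[, 1])
  cos_t * dir + sin_t * (cos(phi) * u + sin(phi) * v)
}

new_fiber_field <- function(polylines, orientation, roi,
                            true_length_by_zone = NULL) {
  seg <- polylines_to_segments(polylines)
  structure(
    list(polylines = polylines,
         segments = seg,
         true_total_length = sum(segment_lengths(seg)),
         true_length_by_zone = true_length_by_zone,
         orientation = orientation,
         roi = roi),
    class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("<fiber_field> %d polylines, L = %.1f um (%s)\n",
              length(x$polylines), x$true_total_length, x$orientation$type))
  if (!is.null(x$true_length_by_zone)) {
    z <- x$true_length_by_zone
    cat(sprintf("  zones: inside %.1f / near %.1f / distant %.1f um\n",
                z[["inside"]], z[["near"]], z[["distant"]]))
  }
  invisible(x)
}

#' Generate a synthetic fiber field of known length density
#'
#' Grows piecewise-linear polylines inside a region box until the total
#' length reaches `target_Lv * volume(roi)` exactly (the final segment is
#' trimmed to hit the target). Inter-vertex lengths are exponentially
#' distributed; curvature is emulated by bounded random turning angles
#' between consecutive segments. Polylines are clipped at the box boundary.
#'
#' @param roi A [region_box()].
#' @param target_Lv Target length density in um/um^3 (L per unit volume).
#' @param orientation `"isotropic"` (default), `"parallel-x"` / `-y` / `-z`
#'   (straight fibers along one axis), or
#'   `list(type = "mixed", axis, weight)` where `weight` is the fraction of
#'   fibers that are parallel.
#' @param mean_segment_length Mean inter-vertex distance, um (default 10).
#' @param mean_fiber_length Mean total length per fiber before boundary
#'   clipping, um (default 250).
#' @param max_turn_deg Maximum turning angle between consecutive segments,
#'   degrees (default 30; ignored for parallel fibers, which are straight).
#' @param seed Integer seed; identical seeds give identical fields.
#'
#' @return A `fiber_field`: list with `polylines` (list of n x 3 matrices,
#'   um), `segments` (cached segment matrix), `true_total_length`,
#'   `orientation` and `roi`.
#' @export
#' @examples
#' roi <- region_box("S1BF", c(100, 100, 40))
#' f <- generate_fiber_field(roi, target_Lv = 0.02, seed = 1)
#' f$true_total_length / roi$volume # == 0.02
generate_fiber_field <- function(roi, target_Lv,
                                 orientation = "isotropic",
                                 mean_segment_length = 10,
                                 mean_fiber_length = 250,
                                 max_turn_deg = 30,
                                 seed) {
  stopifnot(inherits(roi, "region_box"))
  stopifnot_scalar(target_Lv, "target_Lv")
  if (target_Lv < 0) stop("`target_Lv` must be >= 0", call. = FALSE)
  stopifnot_scalar(mean_segment_length, "mean_segment_length", positive = TRUE)
  orientation <- normalize_orientation(orientation)
  target_L <- target_Lv * roi$volume
  if (target_L == 0)
    return(new_fiber_field(list(), orientation, roi))

  max_turn <- max_turn_deg * pi / 180
  lo <- c(0, 0, 0); hi <- unname(roi$extent)
  eps <- 1e-9

  # Chains wrap around the box periodically (torus), which makes the
  # expected length density exactly uniform over the region; each wrap
  # starts a new polyline, so all polylines stay inside the box.
  with_seed(seed, {
    chains <- list()    # per-chain segment matrices (may contain wrap jumps)
    total <- 0
    chain_id <- 0L
    while (total < target_L) {
      n <- max(20L, ceiling((target_L - total) / mean_fiber_length * 1.3))
      pos <- cbind(runif(n, 0, hi[1]), runif(n, 0, hi[2]), runif(n, 0, hi[3]))
      par_flag <- switch(orientation$type,
        isotropic = rep(FALSE, n),
        parallel = rep(TRUE, n),
        mixed = runif(n) < orientation$weight)
      dir <- random_directions(n)
      if (any(par_flag)) {
        ax <- axis_unit(orientation$axis %||% "x")
        sgn <- sample(c(-1, 1), sum(par_flag), replace = TRUE)
        dir[par_flag, ] <- matrix(ax, sum(par_flag), 3, byrow = TRUE) * sgn
      }
      budget <- rexp(n, 1 / mean_fiber_length)
      active <- rep(TRUE, n)
      segs <- vector("list", n)
      step <- 0L
      while (any(active) && step < 20000L) {
        step <- step + 1L
        idx <- which(active)
        m <- length(idx)
        l <- pmin(rexp(m, 1 / mean_segment_length), budget[idx])
        d <- dir[idx, , drop = FALSE]
        p0 <- pos[idx, , drop = FALSE]
        # first boundary hit along the proposed segment, if any
        t_exit <- rep(1, m)
        for (k in 1:3) {
          dk <- d[, k]
          tk <- rep(Inf, m)
          up <- which(dk > 0)
          tk[up] <- (hi[k] - p0[up, k]) / (dk[up] * l[up])
          dn <- which(dk < 0)
          tk[dn] <- (lo[k] - p0[dn, k]) / (dk[dn] * l[dn])
          t_exit <- pmin(t_exit, pmax(tk, 0))
        }
        hit <- t_exit < 1
        laid <- t_exit * l
        budget[idx] <- budget[idx] - laid
        p1 <- p0 + laid * d
        # guard against float overshoot at the faces
        for (k in 1:3) p1[, k] <- pmin(pmax(p1[, k], lo[k]), hi[k])
        for (j in seq_len(m)) {
          i <- idx[j]
          segs[[i]] <- c(segs[[i]], p0[j, ], p1[j, ])
        }
        # wrap exited chains to the opposite face; the interrupted segment
        # continues there with the SAME direction (no turn at the seam),
        # so the process is exactly translation-invariant on the torus
        p_next <- p1
        if (any(hit)) {
          for (k in 1:3) {
            at_hi <- hit & p1[, k] >= hi[k] - eps & d[, k] > 0
            at_lo <- hit & p1[, k] <= lo[k] + eps & d[, k] < 0
            p_next[at_hi, k] <- lo[k]
            p_next[at_lo, k] <- hi[k]
          }
        }
        pos[idx, ] <- p_next
        done <- budget[idx] <= eps
        active[idx[done]] <- FALSE
        # turn only the chains whose exponential inter-vertex length
        # completed inside the box
        turn_sel <- idx[!done & !hit & !par_flag[idx]]
        if (length(turn_sel) && orientation$type != "parallel")
          dir[turn_sel, ] <- turn_directions(dir[turn_sel, , drop = FALSE],
                                             max_turn)
      }
      for (i in seq_len(n)) {
        if (is.null(segs[[i]])) next
        chain_id <- chain_id + 1L
        mm <- matrix(segs[[i]], ncol = 6, byrow = TRUE)
        chains[[chain_id]] <- mm
        total <- total + sum(segment_lengths(mm))
        if (total >= target_L) break
      }
      chains <- chains[seq_len(chain_id)]
    }
    # cut the pooled segment sequence so total length equals the target exactly
    id <- rep(seq_along(chains), vapply(chains, nrow, 1L))
    seg <- do.call(rbind, chains)
    len <- segment_lengths(seg)
    drop0 <- len > 0
    seg <- seg[drop0, , drop = FALSE]; id <- id[drop0]; len <- len[drop0]
    cum <- cumsum(len)
    k <- which(cum >= target_L)[1]
    seg <- seg[seq_len(k), , drop = FALSE]
    id <- id[seq_len(k)]
    frac <- (target_L - (if (k > 1) cum[k - 1] else 0)) / len[k]
    seg[k, 4:6] <- seg[k, 1:3] + frac * (seg[k, 4:6] - seg[k, 1:3])
    # split chains into polylines at wrap discontinuities
    brk <- c(TRUE, id[-1] != id[-length(id)] |
               rowSums(abs(seg[-1, 1:3, drop = FALSE] -
                             seg[-length(id), 4:6, drop = FALSE])) > 1e-9)
    pid <- cumsum(brk)
    polylines <- lapply(split(seq_len(k), pid), function(rows) {
      unname(rbind(seg[rows[1], 1:3],
                   seg[rows, 4:6, drop = FALSE]))
    })
    names(polylines) <- NULL
    new_fiber_field(polylines, orientation, roi)
  })
}
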