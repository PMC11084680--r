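# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

small_roi <- function(extent = c(100, 100, 40), name = "M1") {
  region_box(name, extent)
}

# a single-subject probe run on a (possibly depleted) field
probe_run <- function(field, roi, n_probes, seed, sampling_interval = 1) {
  s <- child_seeds(seed, 2)
  ss <- slice_sections(field, sampling_interval = sampling_interval,
                       phase_seed = s[1])
  pr <- place_probes(ss, roi, n_probes, seed = s[2])
  list(probes = probe_crossings(pr, ss), section_set = ss)
}

# ---- independent oracles -------------------------------------------------

# crossing count by dense sampling along the fiber and sign changes of the
# distance to the sphere surface (independent of the quadratic solver)
oracle_crossings <- function(center, radius, polylines, step = 0.02) {
  tot <- 0L
  for (p in polylines) {
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      t <- seq(0, 1, length.out = max(10, ceiling(L / step)))
      pts <- outer(t, b - a) + matrix(a, length(t), 3, byrow = TRUE)
      d <- sqrt(rowSums((pts - matrix(center, length(t), 3,
                                      byrow = TRUE))^2)) - radius
      tot <- tot + sum(abs(diff(sign(d))) == 2)
    }
  }
  tot
}

# deterministic Fibonacci lattice of directions on the unit sphere
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5)) * 2
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# expected Q of a probe in a zone-modulated stationary field: surface
# average of the local expected density times 2*pi*r^2
oracle_expected_Q <- function(center, radius, base_Lv, plaques, threshold,
                              survival_near, survival_distant, n_dirs = 500) {
  pts <- fibonacci_directions(n_dirs) * radius +
    matrix(center, n_dirs, 3, byrow = TRUE)
  pm <- if (inherits(plaques, "plaque_set")) plaques$plaques else plaques
  d <- rep(Inf, n_dirs)
  if (!is.null(pm) && nrow(pm)) {
    for (i in seq_len(nrow(pm))) {
      di <- sqrt((pts[, 1] - pm[i, 1])^2 + (pts[, 2] - pm[i, 2])^2 +
                   (pts[, 3] - pm[i, 3])^2) - pm[i, 4]
      d <- pmin(d, di)
    }
  }
  rho <- base_Lv * ifelse(d <= 0, 0,
                          ifelse(d <= threshold, survival_near,
                                 survival_distant))
  2 * pi * radius^2 * mean(rho)
}

# brute-force proximity classification (independent re-statement of the rule)
oracle_classify <- function(probes, pm, threshold, mode, section_set) {
  n <- nrow(probes)
  out <- character(n)
  for (j in seq_len(n)) {
    d <- Inf
    if (!is.null(pm) && nrow(pm)) {
      for (i in seq_len(nrow(pm))) {
        if (mode == "full_3d") {
          di <- sqrt((probes$x[j] - pm[i, 1])^2 +
                       (probes$y[j] - pm[i, 2])^2 +
                       (probes$z_world[j] - pm[i, 3])^2) - pm[i, 4]
        } else {
          sec <- section_set$sections[[probes$section[j]]]
          z_mid <- sec$z0 + section_set$section_thickness / 2
          dz <- pm[i, 3] - z_mid
          if (abs(dz) >= pm[i, 4]) next
          di <- sqrt((probes$x[j] - pm[i, 1])^2 +
                       (probes$y[j] - pm[i, 2])^2) -
            sqrt(pm[i, 4]^2 - dz^2)
        }
        d <- min(d, di)
      }
    }
    out[j] <- if (d <= 0) "within" else if (d <= threshold) "near" else "distant"
  }
  out
}

# minimal hand-built probe frame (for classification tests that need no
# counting)
make_probe_frame <- function(x, y, z_world, section = 1L, radius = 5) {
  data.frame(probe_id = seq_along(x), section = section, x = x, y = y,
             z_mounted = NA_real_, z_world = z_world, radius = radius,
             surface_area = 4 * pi * radius^2, Q = NA_integer_,
             proximity = "unset")
}
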