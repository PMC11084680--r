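test_that("region boxes validate their geometry", {
  roi <- region_box("DG", c(200, 100, 80))
  expect_equal(roi$volume, 200 * 100 * 80)
  expect_error(region_box("DG", c(0, 100, 40)), "positive")
  expect_error(region_box("DG", c(100, 100, 50), section_thickness = 40),
               "multiple")
})

test_that("fiber fields hit the requested length density exactly", {
  roi <- small_roi()
  f0 <- generate_fiber_field(roi, 0, seed = 1)
  expect_length(f0$polylines, 0)
  expect_equal(f0$true_total_length, 0)

  f <- generate_fiber_field(roi, 0.05, seed = 1)
  expect_equal(f$true_total_length, 0.05 * roi$volume, tolerance = 1e-12)
  # recorded length agrees with the geometry
  expect_equal(f$true_total_length,
               sum(sqrt(rowSums((f$segments[, 4:6] - f$segments[, 1:3])^2))),
               tolerance = 1e-9)
  # contained in the box
  expect_true(all(f$segments[, c(1, 4)] >= 0 & f$segments[, c(1, 4)] <= 100))
  expect_true(all(f$segments[, c(3, 6)] >= 0 & f$segments[, c(3, 6)] <= 40))
  # pure function of the seed
  expect_identical(generate_fiber_field(roi, 0.05, seed = 1)$segments,
                   f$segments)
  expect_false(identical(generate_fiber_field(roi, 0.05, seed = 2)$segments,
                         f$segments))
})

test_that("parallel and mixed orientation models constrain directions", {
  roi <- small_roi()
  fp <- generate_fiber_field(roi, 0.02, orientation = "parallel-x", seed = 3)
  expect_equal(max(abs(fp$segments[, 5] - fp$segments[, 2])), 0)
  expect_equal(max(abs(fp$segments[, 6] - fp$segments[, 3])), 0)
  fz <- generate_fiber_field(roi, 0.02, orientation = "parallel-z", seed = 3)
  expect_equal(max(abs(fz$segments[, 4] - fz$segments[, 1])), 0)
  fm <- generate_fiber_field(
    roi, 0.02, orientation = list(type = "mixed", axis = "x", weight = 0.5),
    seed = 4)
  dy <- abs(fm$segments[, 5] - fm$segments[, 2])
  expect_true(any(dy == 0) && any(dy > 0))
  expect_error(generate_fiber_field(roi, 0.02, orientation = "spiral",
                                    seed = 1), "orientation")
})

test_that("generated fiber intensity is uniform across the box", {
  # average clipped length per z-band over replicate fields; the periodic
  # (torus) generator should show no face artifacts
  roi <- small_roi()
  bands <- matrix(0, 30, 8)
  for (i in 1:30) {
    f <- generate_fiber_field(roi, 0.05, seed = 1000 + i)
    bands[i, ] <- vapply(0:7, function(j) {
      cl <- stereosim:::clip_segments_to_slab(f$segments, NULL,
                                              j * 5, (j + 1) * 5)
      sum(stereosim:::segment_lengths(cl$segments))
    }, 0)
  }
  dens <- colMeans(bands) / (100 * 100 * 5)
  se <- apply(bands / (100 * 100 * 5), 2, sd) / sqrt(30)
  expect_true(all(abs(dens - 0.05) < 3 * pmax(se, 1e-4)))
})

test_that("plaque sets respect packing constraints and record burden", {
  roi <- small_roi()
  p0 <- generate_plaques(roi, 0, seed = 1)
  expect_equal(nrow(p0$plaques), 0)
  expect_equal(p0$burden, 0)

  # single sphere in a 100^3 box: burden is the analytic volume fraction
  roi_cube <- region_box("Cg", c(100, 100, 100), section_thickness = 20)
  p1 <- generate_plaques(roi_cube, 1, radius = c(10, 10), seed = 2)
  expect_equal(p1$burden, 4 / 3 * pi * 1e3 / 1e6, tolerance = 1e-12)
  expect_equal(p1$burden, plaque_burden_mc(p1, 40000, seed = 3),
               tolerance = 0.15)

  p <- generate_plaques(roi, 8, radius = c(5, 9), min_edge_separation = 6,
                        seed = 4)
  pm <- p$plaques
  expect_true(all(pm[, 1:3] >= 0 & pm[, 1:3] <= rep(roi$extent, each = 8)))
  gap <- as.matrix(dist(pm[, 1:3])) - outer(pm[, 4], pm[, 4], "+")
  diag(gap) <- Inf
  expect_true(all(gap >= 6))

  expect_error(generate_plaques(roi, 50, radius = c(5, 9),
                                min_edge_separation = 40, seed = 5,
                                max_attempts = 200),
               "packing failed")
})

test_that("depletion removes intra-plaque length and thins zones", {
  roi <- small_roi()
  f <- generate_fiber_field(roi, 0.03, seed = 11)
  none <- generate_plaques(roi, 0, seed = 1)

  # identity case: no plaques, full survival
  id <- apply_depletion(f, none, survival_near = 1, survival_distant = 1,
                        seed = 2)
  expect_identical(id$segments, f$segments)
  expect_equal(id$true_length_by_zone[["distant"]], f$true_total_length)

  plq <- generate_plaques(roi, 3, radius = c(8, 12), seed = 3)
  d <- apply_depletion(f, plq, threshold_d = 20, survival_near = 0,
                       survival_distant = 1, seed = 4)
  expect_equal(d$true_length_by_zone[["near"]], 0)
  expect_equal(d$true_length_by_zone[["inside"]], 0)
  pre <- attr(d, "predepletion_length_by_zone")
  # zone partition conserves length
  expect_equal(sum(pre), f$true_total_length, tolerance = 1e-9)
  expect_gt(pre[["near"]], 0)
  # surviving distant length untouched
  expect_equal(d$true_length_by_zone[["distant"]], pre[["distant"]])
  # zone labels partition surviving segments
  expect_true(all(d$segment_zone %in% c("near", "distant")))
  expect_error(apply_depletion(f, plq, survival_near = 1.2,
                               survival_distant = 1, seed = 1), "survival")
})

test_that("depletion is measure-preserving in expectation", {
  roi <- region_box("DG", c(60, 60, 40))
  f <- generate_fiber_field(roi, 0.05, seed = 21)
  plq <- generate_plaques(roi, 2, radius = c(8, 10), seed = 22)
  pre <- attr(apply_depletion(f, plq, survival_near = 0.4,
                              survival_distant = 1, seed = 1),
              "predepletion_length_by_zone")
  ratios <- vapply(1:200, function(s) {
    d <- apply_depletion(f, plq, survival_near = 0.4, survival_distant = 1,
                         seed = s)
    d$true_length_by_zone[["near"]] / pre[["near"]]
  }, 0)
  se <- sd(ratios) / sqrt(200)
  expect_lt(abs(mean(ratios) - 0.4), 3 * se)
})

test_that("neuron generation and thinning match their binomial oracle", {
  roi <- small_roi(c(200, 200, 80), "NbM")
  expect_equal(generate_neurons(roi, 0, seed = 1)$true_count, 0)
  n <- generate_neurons(roi, 1000, seed = 2)
  expect_equal(n$true_count, 1000)
  expect_identical(generate_neurons(roi, 1000, seed = 2)$cells, n$cells)
  # uniform placement: mean x within 3 SE of the midpoint
  se_x <- 200 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(n$cells$x) - 100), 3 * se_x)

  expect_identical(thin_neurons(n, 0, seed = 3)$cells, n$cells)
  expect_equal(thin_neurons(n, 1, seed = 3)$true_count, 0)
  kept <- vapply(1:200, function(s)
    thin_neurons(n, 0.2, seed = s)$true_count / 1000, 0)
  se <- sd(kept) / sqrt(200)
  expect_lt(abs(mean(kept) - 0.8), 3 * se)
})

test_that("sectioning samples systematically, rescales z and conserves length", {
  roi <- region_box("M1", c(100, 100, 480))
  f <- generate_fiber_field(roi, 0.01, seed = 31)

  # every section kept: clipping conserves length exactly (cut frame)
  ss1 <- slice_sections(f, sampling_interval = 1, phase_seed = 1)
  expect_equal(section_fiber_length(ss1, "cut"), f$true_total_length,
               tolerance = 1e-9)
  expect_equal(ss1$n_total, 12)
  # slabs partition the roi
  expect_equal(vapply(ss1$sections, function(s) s$z0, 0), seq(0, 440, 40))

  # every 12th section over a 480 um extent: exactly one sampled
  ss12 <- slice_sections(f, sampling_interval = 12, phase_seed = 2)
  expect_length(ss12$sections, 1)

  # mounted z-ranges are compressed to <= mounted thickness
  seg <- section_segments(ss1, 3, "mounted")
  expect_true(all(seg[, c(3, 6)] >= 0 & seg[, c(3, 6)] <= 20))
  expect_equal(ss1$shrink, 0.5)
  # cut frame restores tissue coordinates
  segc <- section_segments(ss1, 3, "cut")
  expect_equal(max(segc[, c(3, 6)]) <= 40, TRUE)

  expect_error(slice_sections(f, mounted_thickness = 0, phase_seed = 1),
               "mounted_thickness")
  expect_error(slice_sections(f, mounted_thickness = 50, phase_seed = 1),
               "mounted_thickness")

  # the sampling phase is random: both phases occur across seeds
  phases <- vapply(1:20, function(s)
    slice_sections(f, sampling_interval = 2, phase_seed = s)$phase, 0L)
  expect_setequal(unique(phases), c(0L, 1L))
})

test_that("scene serialization round-trips geometry exactly", {
  roi <- small_roi()
  f <- generate_fiber_field(roi, 0.005, seed = 41)
  plq <- generate_plaques(roi, 3, radius = c(6, 9), seed = 42)
  n <- generate_neurons(roi, 25, seed = 43)
  sc <- scene(roi, f, plq, n, meta = list(seed = 41, preset = "test"))
  path <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, path)
  sc2 <- read_scene(path)
  expect_identical(sc2$fibers$segments, sc$fibers$segments)
  expect_identical(unname(sc2$plaques$plaques), unname(sc$plaques$plaques))
  expect_identical(unname(as.matrix(sc2$neurons$cells)),
                   unname(as.matrix(sc$neurons$cells)))
  expect_equal(sc2$fibers$true_total_length, sc$fibers$true_total_length)
  expect_equal(sc2$meta$units, "micrometer")
})
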