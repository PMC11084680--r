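test_that("fractionator designs validate and expose sampling fractions", {
  d <- fractionator_design()
  expect_equal(d$ssf, 1 / 6)
  expect_equal(d$asf, 1 / 4)
  expect_equal(d$hsf, 1 / 2)
  expect_error(fractionator_design(counting_frame = c(300, 100)), "fit")
  expect_error(fractionator_design(dissector_height = 19, guard = 1),
               "exceeds")
})

test_that("the counting frame applies forbidden/inclusion edges", {
  roi <- region_box("NbM", c(400, 400, 240))
  f <- generate_fiber_field(roi, 0, seed = 1)
  d <- fractionator_design(section_interval = 1)
  ss <- slice_sections(f, sampling_interval = 1, phase_seed = 2)
  # grid offset 0: frames occupy (0, 100] x (0, 100] of each 200-grid cell;
  # mounted z window [1, 11) is cut z [2, 22)
  mk <- function(x, y, z = 10) {
    n <- length(x)
    cells <- data.frame(x = x, y = y, z = rep(z, length.out = n),
                        a = rep(5, n), b = rep(5, n), c = rep(5, n))
    stereosim:::new_neuron_set(cells, roi)
  }
  cnt <- function(cells) as.integer(count_in_frames(cells, d, ss, seed = 1,
                                                    offset = c(0, 0)))
  expect_equal(cnt(mk(50, 50)), 1L)      # interior
  expect_equal(cnt(mk(0, 50)), 0L)       # left forbidden edge
  expect_equal(cnt(mk(200, 50)), 0L)     # its extension on the next cell
  expect_equal(cnt(mk(100, 50)), 1L)     # right inclusion edge
  expect_equal(cnt(mk(50, 0)), 0L)       # bottom forbidden edge
  expect_equal(cnt(mk(50, 100)), 1L)     # top inclusion edge
  expect_equal(cnt(mk(150, 50)), 0L)     # in the grid gap
  expect_equal(cnt(mk(50, 50, z = 30)), 0L)  # outside the dissector window
  expect_equal(cnt(mk(50, 50, z = 1)), 0L)   # inside the guard
  # no cells
  expect_equal(cnt(mk(numeric(0), numeric(0), numeric(0))), 0L)
})

test_that("grid translation by whole steps never changes the count", {
  roi <- region_box("NbM", c(400, 400, 240))
  f <- generate_fiber_field(roi, 0, seed = 1)
  cells <- generate_neurons(roi, 2000, seed = 3)
  d <- fractionator_design()
  ss <- slice_sections(f, sampling_interval = 6, phase_seed = 4)
  q0 <- count_in_frames(cells, d, ss, seed = 1, offset = c(37.5, 81.25))
  q1 <- count_in_frames(cells, d, ss, seed = 1, offset = c(237.5, 281.25))
  expect_identical(q0, q1)
  # frame = grid: every cell in the sampled z-windows counted exactly once,
  # independent of offset
  dfull <- fractionator_design(counting_frame = c(200, 200),
                               sampling_grid = c(200, 200))
  qa <- count_in_frames(cells, dfull, ss, seed = 1, offset = c(0, 0))
  qb <- count_in_frames(cells, dfull, ss, seed = 1, offset = c(61.7, 143.9))
  expect_equal(as.integer(qa), as.integer(qb))
})

test_that("dissector counts recover the product of sampling fractions", {
  roi <- region_box("NbM", c(400, 400, 960))
  f <- generate_fiber_field(roi, 0, seed = 1)
  d <- fractionator_design()
  qs <- vapply(1:60, function(s) {
    sd <- child_seeds(s, 3)
    cells <- generate_neurons(roi, 10000, seed = sd[1])
    ss <- slice_sections(f, sampling_interval = 6, phase_seed = sd[2])
    as.integer(count_in_frames(cells, d, ss, seed = sd[3]))
  }, 0L)
  expected <- 10000 * d$ssf * d$asf * d$hsf
  se <- sd(qs) / sqrt(60)
  expect_lt(abs(mean(qs) - expected), 3 * se)
})

test_that("fractionator estimates follow the inverse-fraction formula", {
  d <- fractionator_design()
  expect_equal(fractionator_estimate(0, d)$N_hat, 0)
  d2 <- fractionator_design(section_interval = 6,
                            counting_frame = c(100, 100),
                            sampling_grid = c(200, 200),
                            dissector_height = 10, mounted_thickness = 20)
  expect_equal(fractionator_estimate(25, d2)$N_hat, 25 * 6 * 4 * 2)
  expect_error(fractionator_estimate(-1, d), ">= 0")
})

test_that("the nucleator is exact on centered spheres and unbiased otherwise", {
  sph <- list(center = c(0, 0, 0), semi_axes = c(5, 5, 5))
  v_true <- 4 * pi / 3 * 125
  for (n in c(2, 4, 9)) {
    est <- nucleator_size(sph, n_rays = n, seed = n)
    expect_equal(est$volume, v_true, tolerance = 1e-12)
    expect_equal(est$area, pi * 25, tolerance = 1e-12)
    expect_equal(var(est$ray_lengths), 0)
  }
  # dense-ray numerical integration is the oracle for off-center and
  # ellipsoidal shapes
  dense_off <- nucleator_size(sph, n_rays = 200000,
                              reference_point = c(0, 0, 2), seed = 1)$volume
  expect_equal(dense_off, v_true, tolerance = 0.01)
  off <- vapply(1:250, function(s)
    nucleator_size(sph, n_rays = 4, reference_point = c(0, 0, 2),
                   seed = s)$volume, 0)
  se <- sd(off) / sqrt(250)
  expect_lt(abs(mean(off) - dense_off), 3 * se)

  ell <- list(center = c(0, 0, 0), semi_axes = c(5, 5, 10))
  dense_ell <- nucleator_size(ell, n_rays = 200000, seed = 2)$volume
  expect_equal(dense_ell, 4 * pi / 3 * 250, tolerance = 0.01)
  vs <- vapply(1:250, function(s)
    nucleator_size(ell, n_rays = 4, seed = s)$volume, 0)
  se2 <- sd(vs) / sqrt(250)
  expect_lt(abs(mean(vs) - 4 * pi / 3 * 250), 3 * se2)

  expect_error(nucleator_size(sph, n_rays = 1, seed = 1), "n_rays")
  expect_error(nucleator_size(sph, n_rays = 4, reference_point = c(9, 0, 0),
                              seed = 1), "outside")
})

test_that("population-level nucleator averages per-cell estimates", {
  roi <- small_roi(c(100, 100, 40), "NbM")
  n <- generate_neurons(roi, 30, shape = list(type = "sphere", radius = 5),
                        seed = 5)
  res <- nucleator_sizes(n, n_rays = 4, seed = 6)
  expect_equal(res$n_cells, 30)
  expect_equal(res$mean_volume, 4 * pi / 3 * 125, tolerance = 1e-9)
  empty <- nucleator_sizes(generate_neurons(roi, 0, seed = 1), seed = 2)
  expect_true(is.na(empty$mean_volume))
})
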