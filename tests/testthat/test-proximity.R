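test_that("the center rule classifies within / near / distant", {
  rule <- proximity_rule(20, "full_3d")
  pm <- matrix(c(0, 0, 0, 10), 1) # plaque r = 10 at the origin
  pr <- make_probe_frame(x = c(0, 0, 0, 0), y = c(0, 25, 31, 9),
                         z_world = c(0, 0, 0, 0))
  cl <- classify_probes(pr, pm, rule)
  # center at plaque center; d* = 15 (near); d* = 21 (distant); inside edge
  expect_equal(cl$proximity, c("within", "near", "distant", "within"))
  expect_equal(cl$d_star, c(-10, 15, 21, -1))

  # probe overlapping the plaque but centered outside is near, never within
  pr2 <- classify_probes(make_probe_frame(0, 12, 0), pm, rule)
  expect_equal(pr2$proximity, "near")

  # empty plaque set: everything distant
  pr3 <- classify_probes(make_probe_frame(0, 0, 0),
                         matrix(numeric(0), ncol = 4), rule)
  expect_equal(pr3$proximity, "distant")

  expect_error(proximity_rule(0), "threshold_d")
})

test_that("classification equals the brute-force oracle in both modes", {
  roi <- small_roi(c(150, 150, 80))
  f <- generate_fiber_field(roi, 0.001, seed = 1)
  ss <- slice_sections(f, sampling_interval = 1, phase_seed = 2)
  set.seed(3)
  total <- 0L
  for (rep in 1:12) {
    k <- sample(0:6, 1)
    pm <- if (k == 0) matrix(numeric(0), ncol = 4) else
      cbind(matrix(runif(3 * k), k, 3) %*% diag(c(150, 150, 80)),
            runif(k, 3, 15))
    n <- 90
    pr <- make_probe_frame(runif(n, 0, 150), runif(n, 0, 150),
                           runif(n, 0, 80),
                           section = sample(1:2, n, replace = TRUE))
    for (mode in c("full_3d", "in_plane_2d")) {
      thr <- sample(c(10, 20), 1)
      rule <- proximity_rule(thr, mode)
      got <- classify_probes(pr, pm, rule, ss)$proximity
      want <- oracle_classify(pr, pm, thr, mode, ss)
      expect_identical(got, want)
      total <- total + n
    }
  }
  expect_gte(total, 1000)
})

test_that("classes partition probes and respect threshold monotonicity", {
  roi <- small_roi()
  set.seed(4)
  pm <- cbind(matrix(runif(9, 10, 90), 3, 3), runif(3, 5, 12))
  pr <- make_probe_frame(runif(200, 0, 100), runif(200, 0, 100),
                         runif(200, 0, 40))
  c10 <- classify_probes(pr, pm, proximity_rule(10, "full_3d"))$proximity
  c20 <- classify_probes(pr, pm, proximity_rule(20, "full_3d"))$proximity
  expect_true(all(c10 %in% c("within", "near", "distant")))
  # raising the threshold never sends a probe outward
  expect_false(any(c10 == "near" & c20 == "distant"))
  expect_false(any(c10 == "within" & c20 != "within"))
  # 'within' is threshold-independent
  expect_identical(c10 == "within", c20 == "within")
})

test_that("stratified densities exclude 'within' and flag empty strata", {
  pr <- make_probe_frame(1:6, 1:6, 1:6)
  pr$proximity <- c("near", "near", "near", "distant", "distant", "within")
  pr$Q <- c(2L, 0L, 1L, 4L, 4L, 9L)
  s <- stratified_density(pr)
  expect_equal(s$mean_Q[["near"]], 1)
  expect_equal(s$mean_Q[["distant"]], 4)
  expect_equal(unname(s$n_probes), c(3L, 2L, 1L))
  expect_equal(sum(s$n_probes), nrow(pr))

  # no plaques: near stratum empty-flagged, distant mean = overall mean
  pr2 <- make_probe_frame(1:4, 1:4, 1:4)
  pr2$proximity <- "distant"
  pr2$Q <- c(1L, 2L, 3L, 6L)
  s2 <- stratified_density(pr2)
  expect_true(is.na(s2$mean_Q[["near"]]))
  expect_equal(s2$n_probes[["near"]], 0L)
  expect_equal(s2$mean_Q[["distant"]], 3)

  pr3 <- make_probe_frame(1, 1, 1)
  pr3$proximity <- "within"
  pr3$Q <- 0L
  expect_error(stratified_density(pr3), "within")
  pr$proximity[1] <- "unset"
  expect_error(stratified_density(pr), "unclassified")
})

test_that("relative density rescales strata to a reference", {
  pr <- make_probe_frame(1:5, 1:5, 1:5)
  pr$proximity <- c(rep("near", 2), rep("distant", 3))
  pr$Q <- c(4L, 4L, 8L, 8L, 8L)
  s <- stratified_density(pr)
  r <- relative_density(s, 8)
  expect_equal(r$relative_to_reference[["near"]], 50)
  expect_equal(r$relative_to_reference[["distant"]], 100)
  s$mean_Q[["near"]] <- 0
  expect_equal(relative_density(s, 8)$relative_to_reference[["near"]], 0)
  expect_error(relative_density(s, 0), "reference")
})

test_that("measured stratum means match the surface-integration oracle", {
  # The probe has a 10 um footprint against 20 um zones, so stratum means
  # are a smeared version of the imposed survival profile; the independent
  # oracle integrates the expected local density over each probe's surface.
  roi <- small_roi(c(150, 150, 40))
  p <- get_preset("DG-12m")
  meas_near <- meas_dist <- pred_near <- pred_dist <- numeric(0)
  for (seed in 1:4) {
    s <- child_seeds(seed, 5)
    f <- generate_fiber_field(roi, 0.05, seed = s[1])
    plq <- generate_plaques(roi, 4, radius = c(7, 11),
                            min_edge_separation = 4, seed = s[2])
    d <- apply_depletion(f, plq, 20, survival_near = 0.4,
                         survival_distant = 1, seed = s[3])
    ss <- slice_sections(d, sampling_interval = 1, phase_seed = s[4])
    pr <- probe_crossings(place_probes(ss, roi, 250, seed = s[5]), ss)
    pr <- classify_probes(pr, plq, proximity_rule(20, "full_3d"), ss)
    eq <- vapply(seq_len(nrow(pr)), function(j)
      oracle_expected_Q(c(pr$x[j], pr$y[j], pr$z_world[j]), 5, 0.05,
                        plq, 20, 0.4, 1), 0)
    near <- pr$proximity == "near"; dist <- pr$proximity == "distant"
    meas_near <- c(meas_near, pr$Q[near]); pred_near <- c(pred_near, eq[near])
    meas_dist <- c(meas_dist, pr$Q[dist]); pred_dist <- c(pred_dist, eq[dist])
  }
  se_n <- sd(meas_near) / sqrt(length(meas_near))
  se_d <- sd(meas_dist) / sqrt(length(meas_dist))
  expect_lt(abs(mean(meas_near) - mean(pred_near)), 4 * se_n + 0.1)
  expect_lt(abs(mean(meas_dist) - mean(pred_dist)), 4 * se_d + 0.1)
  # the imposed contrast is recovered up to the predicted smearing
  ratio <- mean(meas_near) / mean(meas_dist)
  ratio_pred <- mean(pred_near) / mean(pred_dist)
  expect_lt(abs(ratio - ratio_pred), 0.06)
  expect_gt(ratio, 0.4 - 0.06) # never sharper than the imposed survival
})
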