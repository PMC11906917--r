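test_that("jitter-free spheres are exact and generation is deterministic", {
  spec <- synthetic_head_spec(shape = "sphere", semi_axes = 90,
                              n_surface_points = 500, surface_jitter_sd = 0)
  scan <- make_head(spec)
  r <- sqrt(rowSums(scan$points^2))
  expect_true(all(abs(r - 90) < 1e-9))
  expect_identical(make_head(spec), scan)
  spec_j <- synthetic_head_spec(n_surface_points = 500, surface_jitter_sd = 2,
                                seed = 5)
  expect_identical(make_head(spec_j), make_head(spec_j))
  expect_false(identical(make_head(spec_j)$points,
                         make_head(synthetic_head_spec(n_surface_points = 500,
                                                       surface_jitter_sd = 2,
                                                       seed = 6))$points))
})

test_that("fiducials sit exactly on the nominal surface", {
  spec <- synthetic_head_spec(semi_axes = c(80, 100, 95),
                              n_surface_points = 500, surface_jitter_sd = 2,
                              fiducial_ring_tilt = 8)
  scan <- make_head(spec)
  ax <- c(80, 100, 95)
  for (f in scan$fiducials)
    expect_equal(sum((f / ax)^2), 1, tolerance = 1e-12)
  # LPA/RPA stay on the x axis under the tilt
  expect_equal(scan$fiducials$LPA, c(-80, 0, 0), tolerance = 1e-12)
})

test_that("generated heads satisfy the mesh invariants", {
  for (seed in c(1, 9)) {
    scan <- make_head(synthetic_head_spec(n_surface_points = 500,
                                          surface_jitter_sd = 3, seed = seed))
    expect_no_error(validate_mesh(build_head_mesh(scan), full = TRUE))
  }
})

test_that("spec validation catches bad parameters", {
  expect_error(synthetic_head_spec(semi_axes = c(-1, 2, 3)),
               class = "scalplayout_input_error")
  expect_error(synthetic_head_spec(n_surface_points = 10),
               class = "scalplayout_input_error")
  expect_error(synthetic_head_spec(surface_jitter_sd = -1),
               class = "scalplayout_input_error")
})

test_that("sensor arrays respect standoff and coverage", {
  scan <- sphere_scan(1500, r = 100)
  mesh <- build_head_mesh(scan)
  on <- place_array(scan, 20, standoff = 0, seed = 2)
  d <- apply(as.matrix(on[, 2:4]), 1, function(p)
    abs(sqrt(sum(p^2)) - 100))
  expect_lt(max(d), 0.5)   # on the hull (within facet sagitta)
  off <- place_array(scan, 20, standoff = 6.5, seed = 2)
  r_off <- sqrt(rowSums(as.matrix(off[, 2:4])^2))
  expect_true(all(r_off > 100))
  cap <- place_array(scan, 30, coverage = "cap", seed = 2)
  expect_true(all(cap$z > 0))   # above the equatorial fiducial ring
  whole <- place_array(scan, 60, coverage = "whole_head", seed = 2)
  expect_identical(whole[1:10, "label"], sprintf("S%02d", 1:10))
})

test_that("synthetic fields peak at the target and grow with sigma", {
  scan <- sphere_scan(1500, r = 100)
  mesh <- build_head_mesh(scan)
  sensors <- place_array(scan, 20, seed = 3)
  target <- as.numeric(sensors[7, 2:4])
  f <- make_field(scan, sensors, target, sigma = 40, mesh = mesh)
  expect_equal(unname(f["S07"]), 1, tolerance = 1e-9)
  expect_true(all(f > 0 & f <= 1 + 1e-12))
  # monotone in arc distance from the target
  tp <- project_to_scalp(target, mesh)
  d <- vapply(seq_len(20), function(i)
    scalp_distance(mesh, tp, project_to_scalp(as.numeric(sensors[i, 2:4]), mesh)), 0)
  expect_equal(order(d), order(-f))
  f2 <- make_field(scan, sensors, target, sigma = 80, mesh = mesh)
  expect_true(all(f2 >= f - 1e-12))
  expect_error(make_field(scan, sensors, target, sigma = 0),
               class = "scalplayout_input_error")
})

test_that("cohorts are deterministic, sized, and share one device array", {
  spec <- synthetic_head_spec(n_surface_points = 400)
  c1 <- make_cohort(spec, 3, n_sensors = 12, seed = 4)
  c2 <- make_cohort(spec, 3, n_sensors = 12, seed = 4)
  expect_identical(c1, c2)
  expect_length(c1, 3)
  expect_false(identical(c1[[1]]$scan$points, c1[[2]]$scan$points))
  expect_identical(c1[[1]]$sensors$label, c1[[2]]$sensors$label)
  # undo each subject's recording-frame transform: sensor clouds should be
  # near-identical (same helmet), heads should differ
  d12 <- as.matrix(dist(rbind(
    as.numeric(c1[[1]]$sensors[1, 2:4]) - colMeans(as.matrix(c1[[1]]$sensors[, 2:4])),
    as.numeric(c1[[2]]$sensors[1, 2:4]) - colMeans(as.matrix(c1[[2]]$sensors[, 2:4])))))
  expect_lt(d12[1, 2], 30)   # same nominal channel, modest frame rotation
})
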