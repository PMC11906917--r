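test_that("initial Cz lands on the pole for equatorial fiducials", {
  mesh <- sphere_mesh(2000, r = 90)
  scan <- sphere_scan(2000, r = 90)
  cz0 <- estimate_cz_initial(mesh, scan$fiducials)
  expect_equal(cz0, c(0, 0, 90), tolerance = 0.02)
})

test_that("initial Cz follows a tilted fiducial ring", {
  scan <- sphere_scan(3000, r = 90, tilt = 10)
  mesh <- build_head_mesh(scan)
  cz0 <- estimate_cz_initial(mesh, scan$fiducials)
  # pole of the ring: +z rotated by the same 10 degrees about the x axis
  expected <- 90 * as.vector(rotation_about(c(1, 0, 0), 10) %*% c(0, 0, 1))
  expect_equal(cz0, expected, tolerance = 0.02)
})

test_that("initial Cz on an ellipsoid with equatorial fiducials is the top pole", {
  scan <- ellipsoid_scan(jitter = 0)
  mesh <- build_head_mesh(scan)
  cz0 <- estimate_cz_initial(mesh, scan$fiducials)
  expect_equal(cz0, c(0, 0, 95), tolerance = 0.05)
  expect_error(estimate_cz_initial(mesh, scan$fiducials[c("NAS", "LPA", "RPA")]),
               class = "scalplayout_input_error")
})

test_that("refine_cz returns an already-equidistant point unchanged", {
  mesh <- sphere_mesh(2000, r = 90)
  scan <- sphere_scan(2000, r = 90)
  pole <- project_to_scalp(c(0, 0, 90), mesh)
  cz <- refine_cz(mesh, scan$fiducials, pole)
  expect_equal(attr(cz, "iterations"), 0)
  expect_equal(as.numeric(cz), pole, tolerance = 1e-12)
})

test_that("refine_cz converges back from a 15 mm displacement", {
  mesh <- sphere_mesh(2000, r = 90)
  scan <- sphere_scan(2000, r = 90)
  cz0 <- project_to_scalp(c(-15, 0, 90), mesh)   # displaced towards LPA
  cz <- refine_cz(mesh, scan$fiducials, cz0, tol_cz = 1)
  expect_true(all(attr(cz, "residuals") <= 1))
  expect_lt(sqrt(sum((as.numeric(cz) - c(0, 0, 90))^2)), 5)
})

test_that("refine_cz meets the 1 mm contract on a jittered asymmetric head", {
  scan <- ellipsoid_scan(jitter = 2, seed = 7, tilt = 6)
  mesh <- build_head_mesh(scan)
  fid <- scalplayout:::.fiducials_on_scalp(mesh, scan$fiducials)
  cz0 <- estimate_cz_initial(mesh, fid)
  cz <- refine_cz(mesh, fid, cz0, tol_cz = 1)
  # re-measure from scratch
  r1 <- abs(scalp_distance(mesh, cz, fid$NAS) - scalp_distance(mesh, cz, fid$INI))
  r2 <- abs(scalp_distance(mesh, cz, fid$LPA) - scalp_distance(mesh, cz, fid$RPA))
  expect_lte(r1, 1)
  expect_lte(r2, 1)
})

test_that("estimate_inion mirrors the nasion", {
  mesh <- sphere_mesh(2000, r = 90)
  scan <- sphere_scan(2000, r = 90)
  ini <- estimate_inion(mesh, scan$fiducials[c("NAS", "LPA", "RPA")])
  expect_equal(ini, c(0, -90, 0), tolerance = 0.03)
  scan_e <- ellipsoid_scan(jitter = 0)
  mesh_e <- build_head_mesh(scan_e)
  ini_e <- estimate_inion(mesh_e, scan_e$fiducials[c("NAS", "LPA", "RPA")])
  expect_equal(ini_e, c(0, -100, 0), tolerance = 0.05)
})

test_that("estimated INI supports grid construction on jittered heads", {
  for (seed in c(3, 11, 27)) {
    scan <- make_head(synthetic_head_spec(n_surface_points = 800,
                                          surface_jitter_sd = 2, seed = seed))
    mesh <- build_head_mesh(scan)
    g <- build_grid(mesh, scan$fiducials[c("NAS", "LPA", "RPA")])
    expect_true(g$ini_estimated)
    expect_true(all(g$cz_residuals <= 1))
  }
})

test_that("sphere grid places landmarks at 72 degrees with equal arcs", {
  grid <- sphere_grid(3000, r = 100)
  expect_true(all(abs(grid$cz_arc_to_landmark - 0.8 * pi * 50) < 1))
  ang <- apply(grid$landmarks, 1, function(l)
    acos(sum(l * grid$cz) / sqrt(sum(l^2) * sum(grid$cz^2))) * 180 / pi)
  expect_true(all(abs(ang - 72) < 0.5))
  # all four quadrant arcs agree within 1%
  expect_lt(diff(range(grid$quadrant_arcs)) / mean(grid$quadrant_arcs), 0.01)
  expect_true(all(grid$quadrant_arcs > 0))
  # landmark placement: 0.8 of the Cz->fiducial arc, re-measured
  fid <- grid$fiducials
  for (lm in rownames(grid$landmarks)) {
    fi <- c(FPz = "NAS", T3 = "LPA", Oz = "INI", T4 = "RPA")[[lm]]
    d_lm <- scalp_distance(grid$mesh, grid$cz, grid$landmarks[lm, ])
    d_fi <- scalp_distance(grid$mesh, grid$cz, fid[[fi]])
    expect_lt(abs(d_lm - 0.8 * d_fi), 0.5)
  }
})

test_that("mirror-symmetric head gives symmetric landmark distances", {
  grid <- sphere_grid(3000, r = 100)
  d13 <- scalp_distance(grid$mesh, grid$landmarks["FPz", ], grid$landmarks["T3", ])
  d14 <- scalp_distance(grid$mesh, grid$landmarks["FPz", ], grid$landmarks["T4", ])
  expect_lt(abs(d13 - d14), 0.5)
})

test_that("grids round-trip through the JSON cache", {
  grid <- sphere_grid(2000, r = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_json(grid, path)
  back <- read_grid_json(path)
  expect_equal(back$cz, grid$cz, tolerance = 1e-12)
  expect_equal(back$landmarks, grid$landmarks, tolerance = 1e-12)
  expect_equal(back$quadrant_arcs, grid$quadrant_arcs, tolerance = 1e-12)
  expect_equal(back$circ_total, grid$circ_total, tolerance = 1e-12)
  # a reloaded grid drives the projection identically
  s <- c(40, 50, 70)
  expect_equal(locate_sensor(back, s), locate_sensor(grid, s),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("grid scales with the head and is deterministic", {
  scan <- sphere_scan(800)
  mesh <- build_head_mesh(scan)
  g1 <- build_grid(mesh, scan$fiducials)
  g2 <- build_grid(mesh, scan$fiducials)
  expect_identical(g1, g2)
  scan_k <- transform_scan(scan, scale = 1.3)
  gk <- build_grid(build_head_mesh(scan_k), scan_k$fiducials)
  expect_equal(gk$quadrant_arcs, 1.3 * g1$quadrant_arcs, tolerance = 1e-9)
  expect_equal(gk$cz_arc_to_landmark, 1.3 * g1$cz_arc_to_landmark,
               tolerance = 1e-9)
})
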