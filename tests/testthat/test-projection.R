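test_that("eccentricity and angle rules reproduce the worked example exactly", {
  expect_identical(eccentricity_from_arcs(18, 12), 1.5)
  expect_identical(as.numeric(angle_from_arcs(10, 15, "FPz")), 150)
  expect_equal(as.numeric(angle_from_arcs(0, 15, "T4")), 0)
  expect_equal(as.numeric(angle_from_arcs(15, 15, "Oz")), 0)   # wraps to 0
  expect_error(eccentricity_from_arcs(10, 0), class = "scalplayout_geometry_error")
  expect_error(angle_from_arcs(20, 15, "FPz"), class = "scalplayout_input_error")
})

test_that("landmarks and Cz are fixed points of the projection", {
  grid <- sphere_grid(3000, r = 100)
  at <- function(p) locate_sensor(grid, p * 1.05)
  fpz <- at(grid$landmarks["FPz", ])
  expect_equal(fpz$eccentricity, 1, tolerance = 1e-6)
  expect_equal(fpz$angle, 90, tolerance = 0.05)
  t3 <- at(grid$landmarks["T3", ])
  expect_equal(t3$eccentricity, 1, tolerance = 1e-6)
  expect_equal(t3$angle, 180, tolerance = 0.05)
  cz <- locate_sensor(grid, grid$cz * 1.2)
  expect_equal(cz$eccentricity, 0)
  expect_equal(cz$angle, 0)
})

test_that("sensors below the circumference map outside the unit circle", {
  grid <- sphere_grid(2000, r = 100)
  mouth <- locate_sensor(grid, c(0, 95, -60), "mouth")
  expect_gt(mouth$eccentricity, 1)
  expect_equal(mouth$angle, 90, tolerance = 1)
})

test_that("2D position is consistent with eccentricity and angle", {
  grid <- sphere_grid(2000, r = 100)
  s <- locate_sensor(grid, c(40, 55, 60))
  expect_equal(s$x, s$eccentricity * cos(s$angle * pi / 180), tolerance = 1e-12)
  expect_equal(s$y, s$eccentricity * sin(s$angle * pi / 180), tolerance = 1e-12)
})

test_that("layouts are exactly subset-independent", {
  scan <- make_head(synthetic_head_spec(n_surface_points = 1200,
                                        surface_jitter_sd = 2, seed = 5))
  sensors <- place_array(scan, 40, seed = 5)
  full <- make_layout(scan, sensors)
  for (k in c(20, 10, 5, 1)) {
    sub <- make_layout(scan, sensors[seq_len(k), , drop = FALSE])
    expect_identical(sub$x, full$x[seq_len(k)])
    expect_identical(sub$y, full$y[seq_len(k)])
  }
})

test_that("duplicate labels are rejected", {
  scan <- sphere_scan(500)
  sensors <- data.frame(label = c("a", "a"), x = c(0, 10), y = c(0, 10),
                        z = c(110, 100))
  expect_error(make_layout(scan, sensors), class = "scalplayout_input_error")
})

test_that("layouts are invariant to rigid motion and uniform scaling", {
  scan <- make_head(synthetic_head_spec(n_surface_points = 1200,
                                        surface_jitter_sd = 2, seed = 9))
  sensors <- place_array(scan, 12, seed = 9)
  base <- make_layout(scan, sensors)
  R <- rotation_about(c(2, -1, 4), 27)
  shift <- c(30, -12, 55)
  for (sc in c(1, 1.4)) {
    tl <- make_layout(transform_scan(scan, R, shift, sc),
                      transform_sensors(sensors, R, shift, sc))
    expect_equal(tl$x, base$x, tolerance = 1e-6)
    expect_equal(tl$y, base$y, tolerance = 1e-6)
  }
})

test_that("mirror-symmetric heads give mirror-symmetric layouts", {
  scan <- sphere_scan(2000, r = 95)
  sensors <- place_array(scan, 10, seed = 4)
  lay <- make_layout(scan, sensors)
  m_scan <- scan
  m_scan$points[, 1] <- -m_scan$points[, 1]
  m_fid <- lapply(scan$fiducials, function(p) c(-p[1], p[2], p[3]))
  # mirroring swaps the preauricular labels
  m_scan$fiducials <- list(NAS = m_fid$NAS, INI = m_fid$INI,
                           LPA = m_fid$RPA, RPA = m_fid$LPA)
  m_sensors <- sensors
  m_sensors$x <- -m_sensors$x
  m_lay <- make_layout(m_scan, m_sensors)
  expect_equal(m_lay$x, -lay$x, tolerance = 1e-5)
  expect_equal(m_lay$y, lay$y, tolerance = 1e-5)
})

test_that("angles are continuous across a quadrant border", {
  grid <- sphere_grid(3000, r = 100)
  # approach FPz (azimuth 90) from both adjacent quadrants, slightly below
  # the circumference latitude
  th <- 75 * pi / 180
  left <- locate_sensor(grid, 100 * c(sin(th) * cos(pi / 2 + 1e-4),
                                      sin(th) * sin(pi / 2 + 1e-4), cos(th)))
  right <- locate_sensor(grid, 100 * c(sin(th) * cos(pi / 2 - 1e-4),
                                       sin(th) * sin(pi / 2 - 1e-4), cos(th)))
  expect_equal(left$angle, right$angle, tolerance = 0.1)
  expect_equal(left$angle, 90, tolerance = 0.1)
})

test_that("single-sensor layouts work", {
  scan <- sphere_scan(800)
  lay <- make_layout(scan, data.frame(label = "only", x = 10, y = 10, z = 120))
  expect_equal(nrow(lay), 1)
  expect_true(is.finite(lay$eccentricity))
})
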