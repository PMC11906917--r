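# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  .fx[[name]]
}

sphere_scan <- function(n = 2000, r = 100, jitter = 0, seed = 1, tilt = 0) {
  make_head(synthetic_head_spec(shape = "sphere", semi_axes = r,
                                n_surface_points = n, surface_jitter_sd = jitter,
                                fiducial_ring_tilt = tilt, seed = seed))
}

sphere_mesh <- function(n = 2000, r = 100) {
  fixture(sprintf("sphere_mesh_%d_%d", n, r),
          function() build_head_mesh(sphere_scan(n, r)))
}

sphere_grid <- function(n = 2000, r = 100) {
  fixture(sprintf("sphere_grid_%d_%d", n, r), function() {
    scan <- sphere_scan(n, r)
    build_grid(build_head_mesh(scan), scan$fiducials)
  })
}

ellipsoid_scan <- function(jitter = 2, seed = 1, tilt = 0) {
  make_head(synthetic_head_spec(semi_axes = c(80, 100, 95),
                                n_surface_points = 3000,
                                surface_jitter_sd = jitter,
                                fiducial_ring_tilt = tilt, seed = seed))
}

# unit octahedron head: 6 axis-aligned points; fiducials at 4 of its vertices
octa_scan <- function(r = 100) {
  P <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
             c(0, 0, r), c(0, 0, -r))
  head_scan(P, list(NAS = c(0, r, 0), INI = c(0, -r, 0),
                    LPA = c(-r, 0, 0), RPA = c(r, 0, 0)))
}

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_scan <- function(scan, R = diag(3), shift = c(0, 0, 0), scale = 1) {
  scan$points <- sweep(scale * scan$points %*% t(R), 2, shift, `+`)
  scan$fiducials <- lapply(scan$fiducials,
                           function(p) as.vector(scale * (R %*% p)) + shift)
  scan
}

transform_sensors <- function(sensors, R = diag(3), shift = c(0, 0, 0), scale = 1) {
  X <- sweep(scale * as.matrix(sensors[, c("x", "y", "z")]) %*% t(R), 2, shift, `+`)
  sensors[, c("x", "y", "z")] <- X
  sensors
}
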