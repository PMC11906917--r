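# Synthetic head shapes, fiducials, sensor arrays and per-channel scalar
# fields. These stand in for real digitised OP-MEG geometry: parametric
# sphere/ellipsoid scalps with surface jitter, canonical fiducial rings,
# quasi-uniform sensor arrays with a scalp standoff, and Gaussian-of-arc-
# distance fields emulating leadfield magnitudes.

#' Specification of a synthetic head
#'
#' Defaults describe a plausible adult scalp: semi-axes 80 (left-right) x
#' 100 (anterior-posterior) x 95 (inferior-superior) mm, 2000 quasi-uniform
#' surface points with 2 mm radial digitisation jitter, and the fiducial
#' ring in the equatorial plane.
#'
#' @param shape `"ellipsoid"` or `"sphere"` (sphere forces equal semi-axes).
#' @param semi_axes numeric length-3, mm (for a sphere, the first entry is
#'   the radius).
#' @param n_surface_points number of scalp points (>= 100).
#' @param surface_jitter_sd radial Gaussian jitter sd, mm.
#' @param fiducial_ring_tilt tilt of the NAS/INI pair about the LPA-RPA
#'   axis, degrees.
#' @param seed RNG seed for the jitter.
#' @return A `synthetic_head_spec` list.
#' @export
synthetic_head_spec <- function(shape = c("ellipsoid", "sphere"),
                                semi_axes = c(80, 100, 95),
                                n_surface_points = 2000,
                                surface_jitter_sd = 2,
                                fiducial_ring_tilt = 0,
                                seed = 1) {
  shape <- match.arg(shape)
  if (shape == "sphere") semi_axes <- rep(semi_axes[1], 3)
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop_input("semi_axes must be three positive lengths (mm)")
  if (n_surface_points < 100) stop_input("need at least 100 surface points")
  if (surface_jitter_sd < 0) stop_input("surface_jitter_sd must be >= 0")
  structure(list(shape = shape, semi_axes = as.numeric(semi_axes),
                 n_surface_points = as.integer(n_surface_points),
                 surface_jitter_sd = surface_jitter_sd,
                 fiducial_ring_tilt = fiducial_ring_tilt,
                 seed = as.integer(seed)),
            class = "synthetic_head_spec")
}

# Quasi-uniform Fibonacci directions with z in (z_min, 1).
.fibonacci_dirs <- function(n, z_min = -1, phase = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - z_min) * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5)) + phase
  cbind(r * cos(phi), r * sin(phi), z)
}

# Scale a direction so it lies exactly on the ellipsoid surface.
.on_ellipsoid <- function(d, axes) {
  t <- 1 / sqrt(sum((d / axes)^2))
  t * d
}

#' Generate a synthetic head scan
#'
#' Places quasi-uniform points on the sphere/ellipsoid (Fibonacci lattice
#' mapped to the ellipsoid) and adds radial Gaussian jitter. Fiducials sit
#' exactly on the unjittered surface at canonical ring positions: NAS on +y,
#' INI on -y, LPA on -x, RPA on +x, with the NAS/INI pair optionally tilted
#' about the LPA-RPA axis. Deterministic for a given spec.
#'
#' @param spec a [synthetic_head_spec()].
#' @return A [head_scan()].
#' @export
make_head <- function(spec) {
  if (!inherits(spec, "synthetic_head_spec"))
    stop_input("spec must come from synthetic_head_spec()")
  ax <- spec$semi_axes
  dirs <- .fibonacci_dirs(spec$n_surface_points)
  P <- t(apply(dirs, 1, .on_ellipsoid, axes = ax))
  if (spec$surface_jitter_sd > 0) {
    P <- .with_seed(spec$seed, {
      jit <- rnorm(nrow(P), sd = spec$surface_jitter_sd)
      P + jit * P / sqrt(rowSums(P^2))
    })
  }
  th <- spec$fiducial_ring_tilt * pi / 180
  rot_x <- function(v) c(v[1], cos(th) * v[2] - sin(th) * v[3],
                         sin(th) * v[2] + cos(th) * v[3])
  fid <- list(NAS = .on_ellipsoid(rot_x(c(0, 1, 0)), ax),
              INI = .on_ellipsoid(rot_x(c(0, -1, 0)), ax),
              LPA = .on_ellipsoid(c(-1, 0, 0), ax),
              RPA = .on_ellipsoid(c(1, 0, 0), ax))
  head_scan(P, fid)
}

#' Place a quasi-uniform sensor array on a head
#'
#' Sensors are placed at quasi-uniform directions above a coverage latitude
#' in the fiducial-anchored frame, ray-cast onto the scalp hull, and offset
#' outward along the local face normal by `standoff` mm (OPM housings sit
#' off the scalp). The seed randomises the azimuthal phase of the lattice;
#' taking the first k rows of the result yields nested sub-arrays.
#'
#' @param scan a [head_scan()].
#' @param n_sensors number of sensors.
#' @param coverage `"whole_head"` (down to just below the fiducial ring) or
#'   `"cap"` (upper head only, excluding the ring).
#' @param standoff scalp-to-sensor distance, mm.
#' @param seed RNG seed for the azimuthal phase.
#' @param frame_tilt length-3 rotation (degrees, x/y/z in the anatomical
#'   frame) of the placement frame relative to the anatomy - how crookedly
#'   the helmet/cap sits on this head.
#' @return data.frame `label`, `x`, `y`, `z` (mm).
#' @export
place_array <- function(scan, n_sensors, coverage = c("whole_head", "cap"),
                        standoff = 6.5, seed = 1, frame_tilt = c(0, 0, 0)) {
  coverage <- match.arg(coverage)
  if (n_sensors < 1) stop_input("n_sensors must be >= 1")
  mesh <- build_head_mesh(scan)
  fr <- .anatomical_frame(scan, mesh)
  if (any(frame_tilt != 0)) {
    E <- cbind(fr$ex, fr$ey, fr$ez) %*% .rot_xyz(frame_tilt * pi / 180)
    fr <- list(ex = E[, 1], ey = E[, 2], ez = E[, 3])
  }
  z_min <- if (coverage == "cap") 0.3 else -0.05
  phase <- .with_seed(seed, runif(1, 0, 2 * pi))
  dirs <- .fibonacci_dirs(n_sensors, z_min = z_min, phase = phase)
  pos <- t(apply(dirs, 1, function(d) {
    v <- d[1] * fr$ex + d[2] * fr$ey + d[3] * fr$ez
    hit <- .raycast(mesh, mesh$origin + v * mesh$diag)
    hit$point + standoff * mesh$normals[hit$face, ]
  }))
  data.frame(label = sprintf("S%02d", seq_len(n_sensors)),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Synthetic per-channel field (leadfield-magnitude stand-in)
#'
#' Channel values decay as a Gaussian of the on-scalp arc distance between
#' the target point and each channel's scalp projection:
#' `exp(-d^2 / (2 sigma^2))`. Values lie in `(0, 1]`, peaking at the channel
#' nearest the target.
#'
#' @param scan a [head_scan()].
#' @param sensors labelled sensors (data.frame or matrix).
#' @param target_point 3D point; ray-projected onto the scalp.
#' @param sigma Gaussian width in mm of on-scalp arc distance.
#' @param mesh optional precomputed `head_mesh` for `scan`.
#' @return Named numeric vector of channel values.
#' @export
make_field <- function(scan, sensors, target_point, sigma = 40, mesh = NULL) {
  if (sigma <= 0) stop_input("sigma must be positive")
  sensors <- .sensor_table(sensors)
  if (is.null(mesh)) mesh <- build_head_mesh(scan)
  tp <- .raycast(mesh, .as_xyz(target_point, "target"))$point
  d <- vapply(seq_len(nrow(sensors)), function(i) {
    sp <- .raycast(mesh, c(sensors$x[i], sensors$y[i], sensors$z[i]))$point
    scalp_distance(mesh, tp, sp)
  }, 0)
  setNames(exp(-d^2 / (2 * sigma^2)), sensors$label)
}

#' Generate a multi-subject synthetic cohort
#'
#' Emulates a fixed whole-head sensor array (one generic helmet) worn by a
#' cohort of differing heads - the situation where polar projection breaks
#' down. One nominal array is placed once, in the device frame, on the
#' nominal head with a generous helmet standoff. Each subject then gets a
#' perturbed head (semi-axis jitter, fiducial-ring tilt) that sits slightly
#' differently inside the helmet (random head-fit rotation and shift), plus
#' small per-sensor mounting noise. Finally the whole dataset is moved by a
#' random rigid transform into an arbitrary recording frame. The anatomical
#' projection maps each fixed device channel to its true per-subject
#' anatomical position; the polar baseline sees (almost) the same sensor
#' cloud for every subject and cannot.
#'
#' @param base_spec a [synthetic_head_spec()] for the nominal head.
#' @param n_subjects number of subjects.
#' @param n_sensors sensors in the fixed array.
#' @param geometry_jitter sd of per-subject semi-axis perturbation, mm.
#' @param tilt_jitter sd of per-subject fiducial-ring tilt, degrees.
#' @param fit_tilt_sd sd (per axis, degrees) of how crookedly each head
#'   sits inside the helmet.
#' @param fit_shift_sd sd (per axis, mm) of the head position inside the
#'   helmet.
#' @param sensor_jitter sd of per-sensor mounting noise, mm.
#' @param standoff nominal scalp-to-sensor distance of the helmet, mm.
#' @param rotation_sd sd of the recording-frame rotation per axis, degrees.
#' @param translation_sd sd of the recording-frame translation per axis, mm.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return List of subjects: `list(scan = head_scan, sensors = data.frame)`.
#' @export
make_cohort <- function(base_spec, n_subjects, n_sensors = 56,
                        geometry_jitter = 4, tilt_jitter = 3,
                        fit_tilt_sd = 5, fit_shift_sd = 5,
                        sensor_jitter = 2, standoff = 12,
                        rotation_sd = 5, translation_sd = 10, seed = 1) {
  if (n_subjects < 1) stop_input("n_subjects must be >= 1")
  nominal <- make_head(base_spec)
  array0 <- place_array(nominal, n_sensors, coverage = "whole_head",
                        standoff = standoff, seed = seed)
  A0 <- as.matrix(array0[, c("x", "y", "z")])
  lapply(seq_len(n_subjects), function(si) {
    s <- .child_seed(seed, si)
    pars <- .with_seed(s, list(
      dax = rnorm(3, sd = geometry_jitter),
      tilt = rnorm(1, sd = tilt_jitter),
      fit_ang = rnorm(3, sd = fit_tilt_sd) * pi / 180,
      fit_shift = rnorm(3, sd = fit_shift_sd),
      ang = rnorm(3, sd = rotation_sd) * pi / 180,
      shift = rnorm(3, sd = translation_sd),
      sj = matrix(rnorm(3 * n_sensors, sd = sensor_jitter), ncol = 3)
    ))
    spec <- synthetic_head_spec(
      shape = base_spec$shape,
      semi_axes = pmax(base_spec$semi_axes + pars$dax, 40),
      n_surface_points = base_spec$n_surface_points,
      surface_jitter_sd = base_spec$surface_jitter_sd,
      fiducial_ring_tilt = base_spec$fiducial_ring_tilt + pars$tilt,
      seed = .child_seed(s, 1))
    scan <- make_head(spec)
    # head-fit transform: this head inside the common helmet
    Fm <- .rot_xyz(pars$fit_ang)
    fit <- function(P) sweep(P %*% t(Fm), 2, pars$fit_shift, `+`)
    scan$points <- fit(scan$points)
    scan$fiducials <- lapply(scan$fiducials, function(p) as.vector(fit(rbind(p))))
    sensors <- A0 + pars$sj

    # arbitrary recording frame for the whole dataset
    R <- .rot_xyz(pars$ang)
    rot <- function(P) sweep(P %*% t(R), 2, pars$shift, `+`)
    scan$points <- rot(scan$points)
    scan$fiducials <- lapply(scan$fiducials, function(p) as.vector(rot(rbind(p))))
    sensors <- rot(sensors)
    list(scan = scan,
         sensors = data.frame(label = array0$label, x = sensors[, 1],
                              y = sensors[, 2], z = sensors[, 3],
                              stringsAsFactors = FALSE))
  })
}

# Rotation matrix from intrinsic x, y, z rotations (radians).
.rot_xyz <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
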