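# Mapping 3D sensors to 2D polar coordinates on the head circle.
#
# Angle convention (nose-up, viewed from above, subject's left on the
# viewer's left): mathematical counter-clockwise angles with T4 (right ear)
# at 0 degrees, FPz (front) at 90, T3 (left ear) at 180, Oz (back) at 270.

.quadrant_offsets <- c(FPz = 90, T3 = 180, Oz = 270, T4 = 0)

#' Eccentricity from a pair of on-scalp distances
#'
#' The 2D radial coordinate of a sensor is the ratio of the on-scalp
#' distance from Cz to the sensor's scalp point over the on-scalp distance
#' from Cz to the circumference, both measured in the sensor's measurement
#' plane. A ratio above 1 places the sensor outside the head circle (e.g.
#' face or mouth sensors).
#'
#' @param d_cz_sensor on-scalp distance Cz to sensor scalp point.
#' @param d_cz_circ on-scalp distance Cz to circumference crossing.
#' @return Eccentricity in units of the head-circle radius.
#' @export
eccentricity_from_arcs <- function(d_cz_sensor, d_cz_circ) {
  if (d_cz_circ <= 0) stop_geometry("Cz-to-circumference distance must be positive")
  if (d_cz_sensor < 0) stop_input("distances must be non-negative")
  d_cz_sensor / d_cz_circ
}

#' Polar angle from circumference arc lengths
#'
#' The 2D angle is the quadrant offset of the reference landmark plus 90
#' degrees times the ratio of the arc from that landmark to the crossing
#' point over the full quadrant arc, following the circumference traversal
#' FPz -> T3 -> Oz -> T4 (counter-clockwise, nose up).
#'
#' @param arc_to_crossing arc length from the reference landmark to the
#'   circumference crossing point, along the traversal direction.
#' @param quadrant_arc full arc length of that quadrant.
#' @param reference the quadrant's starting landmark.
#' @return Angle in degrees in `[0, 360)`.
#' @export
angle_from_arcs <- function(arc_to_crossing, quadrant_arc,
                            reference = c("FPz", "T3", "Oz", "T4")) {
  reference <- match.arg(reference)
  if (quadrant_arc <= 0) stop_geometry("quadrant arc must be positive")
  if (arc_to_crossing < 0 || arc_to_crossing > quadrant_arc * (1 + 1e-9))
    stop_input("arc to crossing must lie within the quadrant")
  (.quadrant_offsets[[reference]] + 90 * arc_to_crossing / quadrant_arc) %% 360
}

# Crossings of an origin-crossing plane with the circumference polyline.
# Returns a list of (point, arc) pairs: 3D crossing point and its arc
# position along the circumference (FPz at 0).
.circ_crossings <- function(grid, normal) {
  circ <- grid$circumference
  m <- nrow(circ)
  s <- as.vector(circ %*% normal) - sum(normal * grid$mesh$origin)
  eps <- 1e-9 * grid$mesh$diag
  out <- list()
  on_pt <- abs(s) <= eps
  for (k in which(on_pt))
    out[[length(out) + 1L]] <- list(point = circ[k, ], arc = grid$circ_cum[k])
  nxt <- c(2:m, 1L)
  chg <- which(!on_pt & !on_pt[nxt] & (s * s[nxt] < 0))
  for (k in chg) {
    j <- nxt[k]
    t <- s[k] / (s[k] - s[j])
    p <- circ[k, ] + t * (circ[j, ] - circ[k, ])
    arc <- grid$circ_cum[k] + t * ((if (j == 1L) grid$circ_total else grid$circ_cum[j]) -
                                     grid$circ_cum[k])
    out[[length(out) + 1L]] <- list(point = p, arc = arc %% grid$circ_total)
  }
  out
}

# Angle (degrees) for a crossing at circumference arc position `arc`.
.angle_at_circ_arc <- function(grid, arc) {
  la <- grid$landmark_arcs            # FPz, T3, Oz, T4 positions
  bounds <- c(la, grid$circ_total)
  k <- max(which(arc >= bounds[1:4] - 1e-9))
  ref <- names(la)[k]
  angle_from_arcs(arc - la[k], bounds[k + 1] - la[k], reference = ref)
}

#' Locate one sensor on the 2D head circle
#'
#' Implements the anatomical projection of a single sensor: the sensor is
#' ray-cast onto the scalp, its measurement plane (through the scalp point,
#' Cz and the origin) is intersected with the mesh, and two on-scalp
#' distances are taken in that plane - Cz to the scalp point, and Cz to the
#' point where the plane crosses the head circumference on the sensor's
#' side. Their ratio is the eccentricity. The crossing point's position
#' along the circumference, expressed as a fraction of its quadrant arc,
#' gives the polar angle. The result depends only on this sensor and the
#' anatomy, never on other channels.
#'
#' @param grid a `grid_1020` from [build_grid()].
#' @param sensor 3D sensor position (mm); need not be on the scalp.
#' @param label channel label carried through to the output.
#' @return A one-row data.frame: `label`, `eccentricity`, `angle` (degrees),
#'   `x`, `y`, with attributes `scalp_point` and `circumference_point`.
#' @export
locate_sensor <- function(grid, sensor, label = "S1") {
  mesh <- grid$mesh
  scalp <- .raycast(mesh, .as_xyz(sensor, "sensor"))$point
  if (.vnorm(scalp - grid$cz) < 1e-7 * mesh$diag) {
    out <- data.frame(label = label, eccentricity = 0, angle = 0, x = 0, y = 0,
                      stringsAsFactors = FALSE)
    attr(out, "scalp_point") <- scalp
    return(out)
  }
  pl <- plane_intersection(mesh, grid$cz, scalp)
  theta_s <- pl$theta[pl$idx_b]
  ccw_side <- theta_s <= pi
  d_cz_s <- if (ccw_side) pl$cum[pl$idx_b] else pl$total - pl$cum[pl$idx_b]

  cr <- .circ_crossings(grid, pl$normal)
  if (!length(cr))
    stop_geometry("measurement plane does not cross the head circumference")
  th <- vapply(cr, function(x) .plane_theta(pl, x$point), 0)
  side_ok <- (th <= pi) == ccw_side
  cand <- which(side_ok)
  if (!length(cand)) cand <- seq_along(cr)
  # same side as the sensor; nearest in angle if several
  j <- cand[which.min(abs(th[cand] - theta_s))]
  C <- cr[[j]]
  arc_ccw_c <- .arc_at_point(pl, C$point)
  d_cz_c <- if (ccw_side) arc_ccw_c else pl$total - arc_ccw_c

  ecc <- eccentricity_from_arcs(d_cz_s, d_cz_c)
  ang <- as.numeric(.angle_at_circ_arc(grid, C$arc))
  out <- data.frame(label = label, eccentricity = ecc, angle = ang,
                    x = ecc * cos(ang * pi / 180),
                    y = ecc * sin(ang * pi / 180),
                    stringsAsFactors = FALSE)
  attr(out, "scalp_point") <- scalp
  attr(out, "circumference_point") <- C$point
  out
}

.sensor_table <- function(sensors) {
  if (is.matrix(sensors)) {
    labels <- rownames(sensors)
    if (is.null(labels)) labels <- sprintf("S%02d", seq_len(nrow(sensors)))
    sensors <- data.frame(label = labels, x = sensors[, 1], y = sensors[, 2],
                          z = sensors[, 3], stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sensors) || !all(c("label", "x", "y", "z") %in% names(sensors)))
    stop_input("sensors must be a matrix or a data.frame with columns label, x, y, z")
  if (anyDuplicated(sensors$label))
    stop_input("duplicate sensor labels: %s",
               paste(unique(sensors$label[duplicated(sensors$label)]), collapse = ", "))
  if (nrow(sensors) < 1) stop_input("need at least one sensor")
  sensors
}

.layout_from_rows <- function(rows, method, grid = NULL) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "outline") <- list(circle_radius = 1, nose_angle = 90,
                               ear_angles = c(180, 0))
  if (!is.null(grid)) attr(out, "grid") <- grid
  class(out) <- c("layout_2d", class(out))
  out
}

#' Anatomical (or polar) 2D layout for a sensor array
#'
#' Single entry point of the method: builds the convex scalp mesh from the
#' head scan, constructs the 10-20 reference frame (estimating INI when it
#' is missing), and locates every sensor independently. Because each channel
#' is mapped without reference to the rest of the array, any subset of
#' sensors yields exactly the same 2D positions as the full array.
#'
#' @param scan a [head_scan()].
#' @param sensors matrix with rownames, or data.frame with columns
#'   `label`, `x`, `y`, `z` (mm).
#' @param method `"anatomical"` (default) or `"polar"` (the baseline;
#'   ignores `scan`).
#' @param tol_cz Cz refinement tolerance, mm.
#' @param grid optionally a precomputed `grid_1020` to reuse.
#' @return A `layout_2d` data.frame (`label`, `eccentricity`, `angle`, `x`,
#'   `y`) with outline metadata; for the anatomical method the `grid_1020`
#'   used is attached as attribute `grid`.
#' @export
make_layout <- function(scan, sensors, method = c("anatomical", "polar"),
                        tol_cz = 1, grid = NULL) {
  method <- match.arg(method)
  sensors <- .sensor_table(sensors)
  if (method == "polar") return(polar_projection(sensors))
  if (is.null(grid)) {
    mesh <- build_head_mesh(scan)
    grid <- build_grid(mesh, scan$fiducials, tol_cz = tol_cz)
  }
  rows <- lapply(seq_len(nrow(sensors)), function(i)
    locate_sensor(grid, c(sensors$x[i], sensors$y[i], sensors$z[i]),
                  label = sensors$label[i]))
  .layout_from_rows(rows, "anatomical", grid)
}

#' @export
print.layout_2d <- function(x, ...) {
  cat(sprintf("<layout_2d> %d channels (%s projection)\n",
              nrow(x), attr(x, "method")))
  print.data.frame(head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat(sprintf("  ... %d more\n", nrow(x) - 8))
  invisible(x)
}
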