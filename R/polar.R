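#' Standard polar (azimuthal equidistant) projection baseline
#'
#' Reference implementation of the conventional array-centred flattening
#' used for fixed MEG arrays: sensors are centred on their own centroid, a
#' best-fit superior axis is taken as the principal axis of the sensor cloud
#' closest to +z, each sensor is mapped by azimuthal equidistant projection
#' (2D radius proportional to the polar angle from that axis, azimuth
#' preserved), and the layout is rescaled so the maximum radius is 1. The 2D
#' position of every channel therefore depends on the whole array - the
#' property the anatomical method is designed to avoid.
#'
#' @param sensors matrix with rownames or data.frame with columns `label`,
#'   `x`, `y`, `z`; at least 3 non-collinear sensors.
#' @return A `layout_2d` data.frame.
#' @export
polar_projection <- function(sensors) {
  sensors <- .sensor_table(sensors)
  if (nrow(sensors) < 3) stop_input("polar projection needs at least 3 sensors")
  X <- as.matrix(sensors[, c("x", "y", "z")])
  X <- sweep(X, 2, colMeans(X))
  pc <- prcomp(X, center = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1))
    stop_input("sensors are collinear; polar projection undefined")
  # principal axis closest to +z as the superior axis
  al <- abs(pc$rotation[3, ])
  k <- which.max(al)
  zax <- pc$rotation[, k]
  if (zax[3] < 0) zax <- -zax
  xax <- c(1, 0, 0) - sum(c(1, 0, 0) * zax) * zax
  if (.vnorm(xax) < 1e-6) xax <- c(0, 1, 0) - sum(c(0, 1, 0) * zax) * zax
  xax <- .unit(xax)
  yax <- .cross(zax, xax)

  zc <- as.vector(X %*% zax)
  xc <- as.vector(X %*% xax)
  yc <- as.vector(X %*% yax)
  r3 <- sqrt(xc^2 + yc^2 + zc^2)
  polar <- acos(pmin(1, pmax(-1, zc / r3)))   # angle from the superior axis
  azim <- atan2(yc, xc)
  rad <- polar / max(polar)
  ang <- (azim * 180 / pi) %% 360
  rows <- lapply(seq_len(nrow(sensors)), function(i) {
    data.frame(label = sensors$label[i], eccentricity = rad[i], angle = ang[i],
               x = rad[i] * cos(azim[i]), y = rad[i] * sin(azim[i]),
               stringsAsFactors = FALSE)
  })
  .layout_from_rows(rows, "polar")
}
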