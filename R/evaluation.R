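# Group-statistics evaluation pipeline: per-subject topographic images from
# channel values, within-subject z-scoring, across-subject one-sample t-maps
# and sparse/focal channel-subselection experiments.

#' Delaunay triangulation of 2D points
#'
#' Computed via the classic paraboloid lifting: points are lifted to
#' `z = x^2 + y^2` and the lower faces of the 3D convex hull are the Delaunay
#' triangles. Degenerate inputs (all collinear, or all concyclic) raise a
#' geometry error.
#'
#' @param xy n x 2 numeric matrix, n >= 3.
#' @return Integer matrix (m x 3) of triangle vertex indices.
#' @export
delaunay2d <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3) stop_input("need an n x 2 matrix with n >= 3")
  n <- nrow(xy)
  if (n == 3) {
    ar <- (xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
      (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2])
    if (abs(ar) < 1e-12 * max(abs(xy), 1)^2)
      stop_geometry("points are collinear; triangulation undefined")
    return(matrix(1:3, nrow = 1))
  }
  lifted <- cbind(xy, rowSums(xy^2))
  faces <- tryCatch(.qhull3d(lifted)$faces,
                    error = function(e)
                      stop_geometry("degenerate channel configuration: %s",
                                    conditionMessage(e)))
  a <- lifted[faces[, 1], , drop = FALSE]
  b <- lifted[faces[, 2], , drop = FALSE]
  cc <- lifted[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  # hull faces are CCW from outside; downward-facing ones form the lower hull
  lower <- nz > 1e-14
  tri <- faces[lower, , drop = FALSE]
  if (!nrow(tri)) stop_geometry("no lower-hull faces; degenerate configuration")
  tri
}

#' Interpolate channel values into a topographic image
#'
#' Linear (barycentric) interpolation on the Delaunay triangulation of the
#' 2D channel positions, rasterised on a square grid over
#' `[-extent, extent]^2`. Pixels outside the convex hull of the channels, or
#' outside the plotting circle of radius `extent`, are masked (`NA`).
#' Linear interpolation reproduces affine fields exactly and constants
#' trivially.
#'
#' @param layout a `layout_2d`.
#' @param values per-channel scalars: named by channel label, or unnamed in
#'   layout order.
#' @param resolution pixels per side (default 67, so the unit circle spans
#'   roughly 56 pixels).
#' @param extent half-width of the raster in head-circle units.
#' @param extrapolate `"none"` (default): mask pixels outside the channel
#'   hull; `"perimeter"`: extend the field to the whole plot disc by adding
#'   anchor points around the rim carrying the nearest channel's value
#'   (the usual topoplot convention, and required when comparing group maps
#'   across layouts whose channel hulls differ).
#' @return An object of class `topo_image`: `values` (resolution x
#'   resolution, `NA` where masked), `mask`, `xgrid`, `ygrid`.
#' @export
interpolate_topo <- function(layout, values, resolution = 67, extent = 1.2,
                             extrapolate = c("none", "perimeter")) {
  extrapolate <- match.arg(extrapolate)
  if (nrow(layout) < 3) stop_input("need at least 3 channels to interpolate")
  if (!is.null(names(values))) {
    missing <- setdiff(layout$label, names(values))
    if (length(missing))
      stop_input("no value for channel(s): %s", paste(missing, collapse = ", "))
    values <- values[layout$label]
  }
  if (length(values) != nrow(layout))
    stop_input("values must match the layout channels")
  xy <- cbind(layout$x, layout$y)
  if (extrapolate == "perimeter") {
    k <- 24
    ang <- (seq_len(k) - 1) * 2 * pi / k
    # just outside the plot circle (and any channel): the rim polygon's
    # inscribed circle must cover the disc, with a radius wobble so the rim
    # points are not concyclic (which would degenerate the lifted hull)
    rim_r <- max(extent, max(sqrt(rowSums(xy^2)))) * 1.03 *
      (1 + 0.002 * rep_len(c(1, -1), k))
    rim <- cbind(rim_r * cos(ang), rim_r * sin(ang))
    nearest <- vapply(seq_len(k), function(i)
      which.min((xy[, 1] - rim[i, 1])^2 + (xy[, 2] - rim[i, 2])^2), 0L)
    xy <- rbind(xy, rim)
    values <- c(values, values[nearest])
  }
  tri <- delaunay2d(xy)
  g <- seq(-extent, extent, length.out = resolution)
  px <- rep(g, times = resolution)          # column-major: x varies fastest
  py <- rep(g, each = resolution)
  out <- rep(NA_real_, resolution^2)
  tol <- 1e-12
  for (k in seq_len(nrow(tri))) {
    i1 <- tri[k, 1]; i2 <- tri[k, 2]; i3 <- tri[k, 3]
    x1 <- xy[i1, 1]; y1 <- xy[i1, 2]
    x2 <- xy[i2, 1]; y2 <- xy[i2, 2]
    x3 <- xy[i3, 1]; y3 <- xy[i3, 2]
    den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(den) < 1e-300) next
    cand <- which(px >= min(x1, x2, x3) - tol & px <= max(x1, x2, x3) + tol &
                  py >= min(y1, y2, y3) - tol & py <= max(y1, y2, y3) + tol)
    if (!length(cand)) next
    l1 <- ((y2 - y3) * (px[cand] - x3) + (x3 - x2) * (py[cand] - y3)) / den
    l2 <- ((y3 - y1) * (px[cand] - x3) + (x1 - x3) * (py[cand] - y3)) / den
    l3 <- 1 - l1 - l2
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    idx <- cand[inside]
    out[idx] <- l1[inside] * values[i1] + l2[inside] * values[i2] +
      l3[inside] * values[i3]
  }
  r2 <- px^2 + py^2
  out[r2 > extent^2] <- NA_real_
  vals <- matrix(out, resolution, resolution)
  structure(list(values = vals, mask = !is.na(vals),
                 xgrid = g, ygrid = g, resolution = resolution,
                 extent = extent),
            class = "topo_image")
}

#' Z-score a topographic image within subject
#'
#' Centres and scales the valid pixels to mean 0 and standard deviation 1
#' (population form, i.e. divisor `n`); the mask is unchanged. Affine
#' transformations of the input leave the output unchanged.
#'
#' @param img a `topo_image`.
#' @return A `topo_image` with standardised values.
#' @export
zscore_image <- function(img) {
  v <- img$values[img$mask]
  if (length(v) < 2) stop_input("need at least 2 valid pixels to z-score")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma <= 0) stop_geometry("zero spread: z-score undefined")
  img$values <- (img$values - mu) / sigma
  img
}

#' Pixel-wise one-sample t-map across subjects
#'
#' For each pixel, computes `t = mean / (sd / sqrt(n))` over the subjects
#' for which that pixel is valid (sample standard deviation). Pixels with
#' fewer than two contributing subjects are masked; pixels where the values
#' are identical across subjects (zero variance) are masked and flagged in
#' `degenerate` rather than propagated as infinities.
#'
#' @param images list of `topo_image` objects on a common raster.
#' @return An object of class `group_stat_map`: `t`, `n_effective`, `mask`,
#'   `degenerate`.
#' @export
group_t_map <- function(images) {
  if (length(images) < 2) stop_input("need at least 2 images")
  res <- images[[1]]$resolution
  for (im in images)
    if (im$resolution != res || !identical(im$xgrid, images[[1]]$xgrid))
      stop_input("images must share a common raster")
  A <- vapply(images, function(im) im$values, matrix(0, res, res))
  M <- !is.na(A)
  A0 <- A
  A0[!M] <- 0
  n_eff <- rowSums(M, dims = 2)
  s1 <- rowSums(A0, dims = 2)
  s2 <- rowSums(A0^2, dims = 2)
  mu <- s1 / n_eff
  varv <- pmax(s2 - n_eff * mu^2, 0) / pmax(n_eff - 1, 1)
  # identical values across subjects give (numerically) zero variance:
  # flag rather than emit infinities
  degenerate <- n_eff >= 2 & varv <= (1e-7 * abs(mu))^2 + 1e-30
  t <- mu / sqrt(varv / n_eff)
  t[n_eff < 2 | degenerate | !is.finite(t)] <- NA_real_
  mask <- !is.na(t)
  if (!any(mask)) stop_input("no pixel is valid in two or more images")
  structure(list(t = t, n_effective = n_eff, mask = mask,
                 degenerate = degenerate,
                 xgrid = images[[1]]$xgrid, ygrid = images[[1]]$ygrid,
                 resolution = res),
            class = "group_stat_map")
}

#' Mean (absolute) t over the valid pixels of a group map
#'
#' @param map a `group_stat_map`.
#' @param signed if `TRUE` average signed t instead of `|t|`.
#' @return A scalar.
#' @export
mean_abs_t <- function(map, signed = FALSE) {
  v <- map$t[map$mask]
  if (signed) mean(v) else mean(abs(v))
}

#' Deterministic random removal order for sparse subselection
#'
#' @param labels channel labels.
#' @param seed RNG seed.
#' @return `labels` permuted; removing them one at a time from the front
#'   yields nested sparse subsets.
#' @export
removal_order <- function(labels, seed) {
  .with_seed(seed, sample(labels))
}

#' Select a channel subset (sparse or focal)
#'
#' Sparse mode removes channels uniformly at random, one at a time, so that
#' subsets at decreasing `n_keep` are nested for a given seed. Focal mode
#' keeps the channel with the peak value plus its `n_keep - 1` nearest
#' neighbours by 3D Euclidean distance.
#'
#' @param sensors labelled 3D sensors (matrix with rownames or data.frame).
#' @param n_keep number of channels to keep.
#' @param mode `"sparse"` or `"focal"`.
#' @param values per-channel scalars (required for focal mode).
#' @param seed RNG seed (sparse mode).
#' @return Character vector of kept labels.
#' @export
subselect_channels <- function(sensors, n_keep, mode = c("sparse", "focal"),
                               values = NULL, seed = 1) {
  mode <- match.arg(mode)
  sensors <- .sensor_table(sensors)
  N <- nrow(sensors)
  if (!is.numeric(n_keep) || n_keep < 1) stop_input("n_keep must be >= 1")
  if (n_keep > N) stop_input("n_keep exceeds the number of channels")
  if (mode == "sparse") {
    removed <- removal_order(sensors$label, seed)[seq_len(N - n_keep)]
    return(sensors$label[!(sensors$label %in% removed)])
  }
  if (is.null(values)) stop_input("focal mode needs per-channel values")
  if (!is.null(names(values))) values <- values[sensors$label]
  peak <- which.max(values)
  X <- as.matrix(sensors[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(X, 2, X[peak, ])^2))
  sensors$label[order(d)][seq_len(n_keep)]
}

#' Compare anatomical and polar projection under channel subselection
#'
#' The full evaluation pipeline: for every combination of projection method,
#' subselection mode and channel count, per-subject layouts are built for
#' the kept channels, channel values for each field target are interpolated
#' into topographic images, z-scored within subject, combined into a group
#' t-map, and summarised as the mean `|t|` over valid pixels. Anatomical
#' layouts are computed once per subject from the full array and subset
#' (2D positions are subset-independent); polar layouts are recomputed for
#' every subset, as the method requires.
#'
#' @param cohort list of subjects, each `list(scan = head_scan, sensors =
#'   data.frame)`, e.g. from [make_cohort()].
#' @param n_keep_schedule integer vector of channel counts.
#' @param modes subset of `c("sparse", "focal")`.
#' @param methods subset of `c("anatomical", "polar")`.
#' @param n_targets number of synthetic field targets (anatomically
#'   corresponding across subjects).
#' @param sigma Gaussian width (mm, on-scalp arc) of the synthetic fields.
#' @param value_noise_sd sd of i.i.d. per-channel measurement noise added to
#'   the field values of every subject/target (real leadfield estimates
#'   carry coregistration and model error; without a noise floor,
#'   pixel-wise t statistics on noiseless synthetic fields degenerate).
#' @param resolution raster resolution per side.
#' @param seed RNG seed for the sparse removal order and the value noise.
#' @param signed average signed t instead of `|t|`.
#' @return Long-format data.frame: `method`, `mode`, `n_keep`, `target`,
#'   `mean_t`.
#' @export
run_comparison <- function(cohort, n_keep_schedule, modes = c("sparse", "focal"),
                           methods = c("anatomical", "polar"),
                           n_targets = 6, sigma = 40, value_noise_sd = 0.02,
                           resolution = 67, seed = 1, signed = FALSE) {
  if (length(cohort) < 2) stop_input("need at least 2 subjects")
  if (!length(n_keep_schedule)) stop_usage("empty n_keep_schedule")
  modes <- match.arg(modes, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)

  # per-subject geometry, full anatomical layout and per-target field values
  prep <- lapply(seq_along(cohort), function(si) {
    subj <- cohort[[si]]
    mesh <- build_head_mesh(subj$scan)
    grid <- build_grid(mesh, subj$scan$fiducials)
    full <- make_layout(subj$scan, subj$sensors, grid = grid)
    targets <- .target_points(subj$scan, mesh, n_targets)
    fields <- lapply(seq_along(targets), function(ti) {
      f <- make_field(subj$scan, subj$sensors, targets[[ti]],
                      sigma = sigma, mesh = mesh)
      if (value_noise_sd > 0)
        f <- f + .with_seed(.child_seed(seed, si * 1000 + ti),
                            rnorm(length(f), sd = value_noise_sd))
      f
    })
    list(sensors = subj$sensors, layout = full, fields = fields)
  })
  labels <- prep[[1]]$sensors$label
  rem <- removal_order(labels, seed)

  rows <- list()
  for (mode in modes) for (nk in n_keep_schedule) for (tg in seq_len(n_targets)) {
    keep_for <- lapply(prep, function(p) {
      if (mode == "sparse") {
        labels[!(labels %in% rem[seq_len(length(labels) - nk)])]
      } else {
        subselect_channels(p$sensors, nk, "focal", values = p$fields[[tg]])
      }
    })
    for (method in methods) {
      imgs <- lapply(seq_along(prep), function(si) {
        p <- prep[[si]]
        keep <- keep_for[[si]]
        lay <- if (method == "anatomical") {
          p$layout[p$layout$label %in% keep, , drop = FALSE]
        } else {
          polar_projection(p$sensors[p$sensors$label %in% keep, , drop = FALSE])
        }
        zscore_image(interpolate_topo(lay, p$fields[[tg]][keep],
                                      resolution = resolution,
                                      extrapolate = "perimeter"))
      })
      tm <- group_t_map(imgs)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, mode = mode, n_keep = nk,
                   target = tg, mean_t = mean_abs_t(tm, signed = signed),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Anatomically corresponding field targets: fixed directions in the
# fiducial-anchored frame of each subject, projected onto their scalp.
.target_points <- function(scan, mesh, n_targets) {
  fr <- .anatomical_frame(scan, mesh)
  ga <- pi * (3 - sqrt(5))
  lapply(seq_len(n_targets), function(i) {
    z <- 0.85 - 0.6 * (i - 0.5) / n_targets    # upper head band
    r <- sqrt(max(0, 1 - z^2))
    phi <- (i - 1) * ga
    d <- r * cos(phi) * fr$ex + r * sin(phi) * fr$ey + z * fr$ez
    .raycast(mesh, mesh$origin + d * mesh$diag)$point
  })
}

# Orthonormal frame anchored on the fiducials: ex to the right (RPA), ey
# anterior (NAS), ez superior.
.anatomical_frame <- function(scan, mesh) {
  fid <- scan$fiducials
  ex <- .unit(fid$RPA - fid$LPA)
  w <- fid$NAS - mesh$origin
  ey <- .unit(w - sum(w * ex) * ex)
  ez <- .cross(ex, ey)
  list(ex = ex, ey = ey, ez = ez)
}
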