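#' Digitised head shape with labelled fiducials
#'
#' Bundles a digitised head-shape point cloud with the anatomical fiducial
#' landmarks used to anchor the 10-20 construction: nasion (`NAS`), inion
#' (`INI`), left and right preauricular points (`LPA`, `RPA`). All
#' coordinates must be in millimetres and share one coordinate frame; `INI`
#' may be absent and can later be estimated with [estimate_inion()].
#'
#' @param points numeric matrix (n x 3) of head-surface points, mm.
#' @param fiducials named list or 3-column matrix with rownames giving the
#'   fiducial coordinates. `NAS`, `LPA` and `RPA` are mandatory.
#' @return An object of class `head_scan`.
#' @examples
#' pts <- matrix(rnorm(300), ncol = 3) * 10 + 90
#' scan <- head_scan(pts, list(NAS = c(0, 95, 0), LPA = c(-90, 0, 0),
#'                             RPA = c(90, 0, 0)))
#' @export
head_scan <- function(points, fiducials) {
  points <- .as_matrix3(points, "head points")
  if (is.matrix(fiducials)) {
    fiducials <- setNames(lapply(seq_len(nrow(fiducials)),
                                 function(i) as.numeric(fiducials[i, ])),
                          rownames(fiducials))
  }
  if (!is.list(fiducials) || is.null(names(fiducials)))
    stop_input("fiducials must be a named list or a matrix with rownames")
  fiducials <- lapply(fiducials, .as_xyz, what = "fiducial")
  needed <- c("NAS", "LPA", "RPA")
  missing <- setdiff(needed, names(fiducials))
  if (length(missing))
    stop_input("missing mandatory fiducial(s): %s", paste(missing, collapse = ", "))
  fiducials <- fiducials[intersect(c("NAS", "INI", "LPA", "RPA"), names(fiducials))]
  if (nrow(points) + length(fiducials) < 4)
    stop_input("need at least 4 points overall to build a 3D scalp surface")
  structure(list(points = points, fiducials = fiducials), class = "head_scan")
}

#' @export
print.head_scan <- function(x, ...) {
  cat(sprintf("<head_scan> %d head points, fiducials: %s\n",
              nrow(x$points), paste(names(x$fiducials), collapse = ", ")))
  invisible(x)
}

.mesh_finalise <- function(vertices, faces, origin) {
  # outward-facing normals and plane offsets, with the origin inside
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  if (any(len < 1e-300)) stop_geometry("mesh contains a zero-area face")
  nrm <- nrm / len
  off <- rowSums(nrm * a)
  inward <- rowSums(nrm * matrix(origin, nrow(faces), 3, byrow = TRUE)) - off
  flip <- inward > 0
  if (any(flip)) {  # defensive: enforce outward orientation
    faces[flip, 2:3] <- faces[flip, 3:2]
    nrm[flip, ] <- -nrm[flip, ]
    off[flip] <- -off[flip]
    inward[flip] <- -inward[flip]
  }
  diag <- .bbox_diag(vertices)
  eps_hull <- 1e-6 * diag
  if (any(inward > -eps_hull))
    stop_geometry("origin is not strictly inside the scalp mesh")
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  edges <- unique(ed)
  structure(list(vertices = vertices, faces = faces, origin = origin,
                 normals = nrm, offsets = off, edges = edges,
                 diag = diag, eps_hull = eps_hull),
            class = "head_mesh")
}

#' Build the convex scalp mesh from a head scan
#'
#' Computes the convex hull of the head points plus the fiducials, yielding a
#' watertight triangular scalp surface. Working on the hull discards local
#' concavities and irregularities in the digitised shape, which mimics how a
#' physical tape measure spans them. The mesh origin is the midpoint of the
#' LPA-RPA segment (the centre of the head) and is guaranteed to lie strictly
#' inside the surface.
#'
#' Inputs that look like metres (bounding box smaller than 2 units) are
#' rejected rather than silently rescaled; all geometry here is in mm.
#'
#' @param scan a [head_scan()].
#' @return An object of class `head_mesh` with fields `vertices`, `faces`
#'   (outward-oriented triangles), `origin`, per-face `normals`/`offsets`,
#'   the undirected `edges` list and the hull tolerance `eps_hull`
#'   (`1e-6` of the bounding-box diagonal).
#' @export
build_head_mesh <- function(scan) {
  if (!inherits(scan, "head_scan")) stop_input("scan must be a head_scan object")
  P <- rbind(scan$points, do.call(rbind, scan$fiducials))
  if (.bbox_diag(P) < 2)
    stop_input(paste0("head coordinates span < 2 units; they look like metres. ",
                      "All geometry must be supplied in millimetres."))
  hull <- tryCatch(.qhull3d(P), error = function(e)
    stop_geometry("cannot build scalp hull: %s", conditionMessage(e)))
  faces_raw <- hull$faces
  used <- sort(unique(as.vector(faces_raw)))
  remap <- integer(nrow(P))
  remap[used] <- seq_along(used)
  vertices <- P[used, , drop = FALSE]
  faces <- matrix(remap[faces_raw], ncol = 3)
  origin <- (scan$fiducials$LPA + scan$fiducials$RPA) / 2
  mesh <- .mesh_finalise(vertices, faces, origin)
  # every input point must be inside or on the hull
  dmax <- .max_halfspace_excess(mesh, P)
  if (dmax > mesh$eps_hull)
    stop_geometry("convex hull construction failed: input point %.3g mm outside hull", dmax)
  mesh
}

# Largest signed distance of any point in P above any face half-space,
# computed in chunks to bound memory.
.max_halfspace_excess <- function(mesh, P) {
  P <- .as_matrix3(P)
  worst <- -Inf
  step <- max(1L, floor(2e6 / nrow(mesh$normals)))
  for (i0 in seq(1L, nrow(P), by = step)) {
    idx <- i0:min(i0 + step - 1L, nrow(P))
    D <- P[idx, , drop = FALSE] %*% t(mesh$normals)
    D <- sweep(D, 2, mesh$offsets)
    worst <- max(worst, max(D))
  }
  worst
}

#' Validate scalp-mesh invariants
#'
#' Checks that the mesh is watertight (every edge shared by exactly two
#' faces, Euler characteristic 2), that the origin is strictly inside, and -
#' optionally, as it is quadratic in mesh size - that the mesh is convex
#' within `eps_hull`.
#'
#' @param mesh a `head_mesh`.
#' @param full if `TRUE`, run the full convexity check over all vertices.
#' @return `TRUE` invisibly; errors describe the violated invariant.
#' @export
validate_mesh <- function(mesh, full = FALSE) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) stop_geometry("mesh is not watertight: edge not shared by exactly 2 faces")
  V <- length(unique(as.vector(f)))
  E <- length(cnt)
  Fn <- nrow(f)
  if (V - E + Fn != 2)
    stop_geometry("Euler characteristic is %d, expected 2", V - E + Fn)
  verts <- mesh$vertices
  if (!full && nrow(verts) > 600)
    verts <- verts[seq(1, nrow(verts), length.out = 600), , drop = FALSE]
  if (.max_halfspace_excess(mesh, verts) > mesh$eps_hull)
    stop_geometry("mesh is not convex within eps_hull")
  invisible(TRUE)
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("<head_mesh> %d vertices, %d faces, origin (%.1f, %.1f, %.1f) mm\n",
              nrow(x$vertices), nrow(x$faces), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Total surface area of the mesh (mm^2)
#' @param mesh a `head_mesh`.
#' @return Total area of all triangular faces.
#' @export
mesh_surface_area <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Ray cast from the origin through p; returns the exit point and face index.
.raycast <- function(mesh, p) {
  d <- p - mesh$origin
  L <- .vnorm(d)
  if (L < mesh$eps_hull)
    stop_geometry("cannot project a point located at the mesh origin")
  d <- d / L
  nd <- as.vector(mesh$normals %*% d)
  num <- mesh$offsets - as.vector(mesh$normals %*% mesh$origin)
  # origin strictly inside => num > 0 for all faces; exit where nd > 0
  ok <- nd > 1e-12
  t <- num[ok] / nd[ok]
  j <- which.min(t)
  face <- which(ok)[j]
  list(point = mesh$origin + t[j] * d, face = face, t = t[j])
}

#' Project a point onto the scalp surface
#'
#' Casts a ray from the mesh origin through `p` and returns its intersection
#' with the scalp surface. Points outside the head are pulled inward onto the
#' scalp; points inside (including below the circumference) are pushed
#' outward along the same origin ray. The result, `p` and the origin are
#' collinear, and projection is idempotent.
#'
#' @param p a 3D coordinate, or an n x 3 matrix of coordinates (mm).
#' @param mesh a `head_mesh`.
#' @return Projected coordinate(s), same shape as `p`.
#' @export
project_to_scalp <- function(p, mesh) {
  if (is.matrix(p)) {
    P <- .as_matrix3(p, "points")
    out <- t(apply(P, 1, function(q) .raycast(mesh, q)$point))
    dimnames(out) <- dimnames(p)
    return(out)
  }
  .raycast(mesh, .as_xyz(p))$point
}

# Barycentric coordinates of point q (assumed on the face plane) in face fi.
.face_barycentric <- function(mesh, fi, q) {
  tri <- mesh$vertices[mesh$faces[fi, ], , drop = FALSE]
  v0 <- tri[2, ] - tri[1, ]
  v1 <- tri[3, ] - tri[1, ]
  v2 <- q - tri[1, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

#' Insert a surface point as a mesh vertex
#'
#' Adds a point lying on the scalp surface to the mesh vertex set by
#' splitting its containing face (or the two faces sharing an edge, when the
#' point falls on an edge). Used after Cz refinement so that the vertex point
#' becomes part of the mesh; convexity and watertightness are preserved.
#'
#' @param mesh a `head_mesh`.
#' @param p a 3D point on (or near) the surface; it is ray-projected first.
#' @return A new `head_mesh` containing `p` as a vertex.
#' @export
add_surface_vertex <- function(mesh, p) {
  hit <- .raycast(mesh, .as_xyz(p))
  q <- hit$point
  bc <- .face_barycentric(mesh, hit$face, q)
  tol <- 1e-9
  onv <- bc > 1 - tol
  if (any(onv)) return(mesh)  # coincides with an existing vertex
  vertices <- rbind(mesh$vertices, q)
  vi <- nrow(vertices)
  f <- mesh$faces
  tri <- f[hit$face, ]
  zero <- which(bc < tol)
  if (length(zero) == 1) {
    # point on an edge: split the two faces sharing it
    e <- tri[-zero]
    sharing <- which(apply(f, 1, function(r) all(e %in% r)))
    newf <- do.call(rbind, lapply(sharing, function(fi) {
      t3 <- f[fi, ]
      rbind(ifelse(t3 == e[1], vi, t3),
            ifelse(t3 == e[2], vi, t3))
    }))
    f <- rbind(f[-sharing, , drop = FALSE], newf)
  } else {
    f <- rbind(f[-hit$face, , drop = FALSE],
               c(tri[1], tri[2], vi),
               c(tri[2], tri[3], vi),
               c(tri[3], tri[1], vi))
  }
  .mesh_finalise(vertices, f, mesh$origin)
}
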