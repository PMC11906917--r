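#' Intersect an origin-crossing plane with the scalp mesh
#'
#' Any two scalp points together with the head origin define a unique plane.
#' Because the mesh is convex, intersecting that plane with the surface
#' yields a closed convex planar loop; ordering the intersection points by
#' their polar angle about the plane normal gives a strict indexing along
#' the loop, which is the basis of all on-scalp measurements.
#'
#' Both anchors are first ray-projected onto the surface (a no-op when they
#' already lie on it) and injected into the loop as exact points, so that
#' measurements start and end exactly at them. The angular origin is at `a`.
#'
#' @param mesh a `head_mesh`.
#' @param a,b 3D surface points (mm). Must not be collinear with the origin.
#' @return An object of class `measurement_plane`: unit `normal`, in-plane
#'   basis (`e1` towards `a`, `e2`), the ordered loop `path` (k x 3), the
#'   angles `theta` in `[0, 2*pi)`, cumulative arc length `cum` from `a`,
#'   total loop length `total`, and anchor indices `idx_a`, `idx_b`.
#' @export
plane_intersection <- function(mesh, a, b) {
  a <- .raycast(mesh, .as_xyz(a, "a"))$point
  b <- .raycast(mesh, .as_xyz(b, "b"))$point
  o <- mesh$origin
  va <- a - o
  vb <- b - o
  n <- .cross(va, vb)
  if (.vnorm(n) < 1e-9 * .vnorm(va) * .vnorm(vb))
    stop_geometry(paste0("the two points and the origin are collinear; ",
                         "the measurement plane is not unique"))
  n <- n / .vnorm(n)

  eps_plane <- 1e-9 * mesh$diag
  s <- as.vector(mesh$vertices %*% n) - sum(n * o)

  V <- mesh$vertices
  ed <- mesh$edges
  s1 <- s[ed[, 1]]
  s2 <- s[ed[, 2]]
  on1 <- abs(s1) <= eps_plane
  on2 <- abs(s2) <= eps_plane
  crossing <- (s1 > eps_plane & s2 < -eps_plane) | (s1 < -eps_plane & s2 > eps_plane)
  P <- NULL
  if (any(crossing)) {
    t <- s1[crossing] / (s1[crossing] - s2[crossing])
    P <- V[ed[crossing, 1], , drop = FALSE] +
      t * (V[ed[crossing, 2], , drop = FALSE] - V[ed[crossing, 1], , drop = FALSE])
  }
  onv <- unique(c(ed[on1, 1], ed[on2, 2]))
  if (length(onv)) P <- rbind(P, V[onv, , drop = FALSE])
  P <- rbind(P, a, b)
  dimnames(P) <- NULL

  e1 <- .unit(va)
  e2 <- .cross(n, e1)
  rel <- sweep(P, 2, o)
  theta <- atan2(as.vector(rel %*% e2), as.vector(rel %*% e1)) %% (2 * pi)
  ord <- order(theta)
  P <- P[ord, , drop = FALSE]
  theta <- theta[ord]

  # de-duplicate points closer than eps (plane through a vertex produces the
  # same point from several edges), always keeping the exact anchors
  na <- nrow(P)
  ia <- which.min(pmin(theta, 2 * pi - theta))          # a sits at theta = 0
  ib <- which.min(abs(rowSums(sweep(P, 2, b)^2)))
  keep <- rep(TRUE, na)
  dup_tol <- max(1e-7 * mesh$diag, 1e-9)
  for (i in seq_len(na)) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= na && .vnorm(P[j, ] - P[i, ]) < dup_tol) {
      # keep anchors over generic crossings
      if (j == ia || j == ib) { keep[i] <- FALSE } else { keep[j] <- FALSE }
      j <- j + 1L
    }
  }
  # wrap-around duplicate
  first <- which(keep)[1]
  last <- rev(which(keep))[1]
  if (last != first && .vnorm(P[last, ] - P[first, ]) < dup_tol) {
    if (last == ia || last == ib) keep[first] <- FALSE else keep[last] <- FALSE
  }
  P <- P[keep, , drop = FALSE]
  theta <- theta[keep]

  idx_a <- which.min(pmin(theta, 2 * pi - theta))
  idx_b <- which.min(abs(rowSums(sweep(P, 2, b)^2)))
  # exact anchor injection
  P[idx_a, ] <- a
  P[idx_b, ] <- b
  theta[idx_a] <- 0

  seg <- sqrt(rowSums((P[c(2:nrow(P), 1), , drop = FALSE] - P)^2))
  cum <- c(0, cumsum(seg))[seq_len(nrow(P))]
  # rotate so the loop starts at a
  if (idx_a != 1L) {
    shift <- c(idx_a:nrow(P), seq_len(idx_a - 1L))
    P <- P[shift, , drop = FALSE]
    theta <- theta[shift]
    seg <- seg[shift]
    cum <- c(0, cumsum(seg))[seq_len(nrow(P))]
    idx_b <- which(shift == idx_b)
    idx_a <- 1L
  }
  structure(list(normal = n, origin = o, e1 = e1, e2 = e2,
                 path = P, theta = theta, cum = cum,
                 total = sum(seg), idx_a = idx_a, idx_b = idx_b,
                 eps_plane = eps_plane),
            class = "measurement_plane")
}

# Arc length along the loop from index i to index j in the increasing-theta
# ("ccw") direction.
.arc_ccw <- function(plane, i, j) {
  (plane$cum[j] - plane$cum[i]) %% plane$total
}

#' Arc length between the two anchors of a measurement plane
#'
#' @param plane a `measurement_plane`.
#' @param direction `"shorter"` (default, tape-measure convention), `"ccw"`
#'   (increasing polar angle about the stored normal) or `"cw"`.
#' @return Arc length in mm.
#' @export
arc_length <- function(plane, direction = c("shorter", "ccw", "cw")) {
  direction <- match.arg(direction)
  d_ccw <- .arc_ccw(plane, plane$idx_a, plane$idx_b)
  switch(direction,
         shorter = min(d_ccw, plane$total - d_ccw),
         ccw = d_ccw,
         cw = plane$total - d_ccw)
}

#' On-scalp distance between two surface points
#'
#' Measures the piecewise-linear arc length along the intersection of the
#' origin-crossing plane through `a` and `b` with the scalp mesh - the
#' digital analogue of running a tape measure over the head. By default the
#' shorter of the two arcs around the section loop is returned.
#'
#' @inheritParams plane_intersection
#' @param direction see [arc_length()].
#' @return Distance in mm. Symmetric in `a`, `b`; zero when `a == b`;
#'   never less than the straight-line distance.
#' @export
scalp_distance <- function(mesh, a, b, direction = "shorter") {
  a <- .as_xyz(a, "a"); b <- .as_xyz(b, "b")
  if (.vnorm(a - b) < 1e-12 * mesh$diag) return(0)
  arc_length(plane_intersection(mesh, a, b), direction)
}

#' Point at a fraction of the arc between the two anchors
#'
#' Walks the section loop from one anchor towards the other and returns the
#' surface point at arc length `f` times the anchor-to-anchor distance. With
#' `f = 0.8` this implements the 10-20 rule that shortens the vertex-to-
#' fiducial measurement by 20% to place the circumference landmarks.
#'
#' @param plane a `measurement_plane`.
#' @param f fraction in `[0, 1]`.
#' @param from `"a"` or `"b"`: anchor to start from.
#' @param direction see [arc_length()]; the arc used is the one measured.
#' @return A 3D surface point (on the section polyline).
#' @export
point_at_fraction <- function(plane, f, from = c("a", "b"),
                              direction = c("shorter", "ccw", "cw")) {
  from <- match.arg(from)
  direction <- match.arg(direction)
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop_input("f must be a single number in [0, 1]")
  i <- if (from == "a") plane$idx_a else plane$idx_b
  j <- if (from == "a") plane$idx_b else plane$idx_a
  d_ccw <- .arc_ccw(plane, i, j)
  dir_ccw <- switch(direction,
                    ccw = from == "a",
                    cw = from != "a",
                    shorter = if (from == "a") d_ccw <= plane$total - d_ccw
                              else .arc_ccw(plane, i, j) <= plane$total / 2)
  span <- if (dir_ccw) .arc_ccw(plane, i, j) else plane$total - .arc_ccw(plane, i, j)
  .walk_loop(plane, i, f * span, ccw = dir_ccw)
}

# Walk `dist` mm along the loop from index i in the given direction and
# return the interpolated 3D point.
.walk_loop <- function(plane, i, dist, ccw = TRUE) {
  P <- plane$path
  np <- nrow(P)
  remaining <- dist
  cur <- i
  repeat {
    nxt <- if (ccw) (cur %% np) + 1L else ((cur - 2L) %% np) + 1L
    seg <- .vnorm(P[nxt, ] - P[cur, ])
    if (remaining <= seg || seg == 0) {
      if (seg == 0) return(P[cur, ])
      return(P[cur, ] + (remaining / seg) * (P[nxt, ] - P[cur, ]))
    }
    remaining <- remaining - seg
    cur <- nxt
  }
}

# Angle of an arbitrary (near-)in-plane point, in [0, 2*pi) from anchor a.
.plane_theta <- function(plane, p) {
  rel <- p - plane$origin
  atan2(sum(rel * plane$e2), sum(rel * plane$e1)) %% (2 * pi)
}

# Arc length from anchor a (theta = 0) to the loop point at angle `theta`,
# walking ccw. `p` must lie on (within tolerance of) the loop.
.arc_at_point <- function(plane, p) {
  th <- .plane_theta(plane, p)
  k <- findInterval(th, plane$theta)
  if (k < 1L) k <- nrow(plane$path)
  plane$cum[k] + .vnorm(p - plane$path[k, ])
}
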