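# Ellipse geometry primitives shared by the synthetic-data generators, the
# placement Monte Carlo and the parametric branch of the distance metrics.
#
# An ellipse is the numeric vector (x, y, a, b, theta): center in nm,
# semi-major/minor axes in nm, rotation in degrees (counter-clockwise about
# the +x axis in the y-down image frame). Tibbles of ellipses carry these as
# columns.

deg2rad <- function(d) d * pi / 180

# 3x3 conic matrix with the interior-negative convention:
# X^T A X < 0 inside, = 0 on the boundary (X homogeneous).
ellipse_conic <- function(x, y, a, b, theta_deg) {
  th <- deg2rad(theta_deg)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  M <- R %*% diag(c(1 / a^2, 1 / b^2)) %*% t(R)
  c0 <- c(x, y)
  A <- matrix(0, 3, 3)
  A[1:2, 1:2] <- M
  A[1:2, 3] <- -M %*% c0
  A[3, 1:2] <- A[1:2, 3]
  A[3, 3] <- sum(c0 * (M %*% c0)) - 1
  A
}

# Interpolation nodes for recovering the cubic det(l*A + B) from four
# evaluations; the inverse Vandermonde is constant so it is precomputed.
.conic_nodes <- c(-2, -1, 0, 1)
.conic_vinv <- solve(outer(.conic_nodes, 0:3, "^"))

#' Test whether two ellipses overlap
#'
#' Exact algebraic test via the pencil of the two conics: with the
#' interior-negative normalization, the cubic `det(lambda * A + B)` has two
#' distinct positive real roots exactly when the ellipses are separated
#' (externally tangent pairs give a positive double root and are counted as
#' non-overlapping, i.e. edge-to-edge distance zero).
#'
#' @param e1,e2 Numeric vectors `(x, y, a, b, theta)`: center (nm),
#'   semi-axes (nm), rotation (degrees).
#' @return `TRUE` if the interiors intersect.
#' @export
ellipses_overlap <- function(e1, e2) {
  # cheap bounding-circle screens
  dx <- e1[1] - e2[1]; dy <- e1[2] - e2[2]
  d2 <- dx * dx + dy * dy
  rsum <- max(e1[3], e1[4]) + max(e2[3], e2[4])
  if (d2 > rsum * rsum) return(FALSE)
  rmin <- min(e1[3], e1[4]) + min(e2[3], e2[4])
  if (d2 < rmin * rmin) return(TRUE)
  # work in a local frame (midpoint origin, unit mean semi-axis) so the
  # conic determinants stay well conditioned at nm coordinate scales
  mx <- (e1[1] + e2[1]) / 2; my <- (e1[2] + e2[2]) / 2
  sc <- (e1[3] + e1[4] + e2[3] + e2[4]) / 4
  A <- ellipse_conic((e1[1] - mx) / sc, (e1[2] - my) / sc,
                     e1[3] / sc, e1[4] / sc, e1[5])
  B <- ellipse_conic((e2[1] - mx) / sc, (e2[2] - my) / sc,
                     e2[3] / sc, e2[4] / sc, e2[5])
  v <- vapply(.conic_nodes, function(l) det(l * A + B), numeric(1))
  co <- as.vector(.conic_vinv %*% v)
  r <- polyroot(co)
  scale <- max(Mod(r), 1)
  pos <- Re(r)[abs(Im(r)) < 1e-7 * scale & Re(r) > 0]
  length(pos) != 2
}

#' Sample points on an ellipse boundary
#'
#' @param e Ellipse vector `(x, y, a, b, theta)`.
#' @param n Number of boundary points.
#' @return An `n x 2` matrix of coordinates (nm).
#' @export
ellipse_boundary <- function(e, n = 128) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- deg2rad(e[5])
  ct <- cos(t) * e[3]; st <- sin(t) * e[4]
  cbind(e[1] + ct * cos(th) - st * sin(th),
        e[2] + ct * sin(th) + st * cos(th))
}

#' Test points against an ellipse interior
#'
#' @param px,py Point coordinates (nm), vectorized.
#' @param e Ellipse vector.
#' @return Logical vector; `TRUE` when the point is inside or on the boundary.
#' @export
point_in_ellipse <- function(px, py, e) {
  th <- deg2rad(e[5])
  dx <- px - e[1]; dy <- py - e[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / e[3])^2 + (v / e[4])^2 <= 1
}

# min pairwise distance between two point sets (rows of matrices)
min_pointset_distance <- function(p1, p2) {
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  sqrt(min(d2))
}

#' Edge-to-edge distance between two parametric ellipses
#'
#' Positive when the ellipses are disjoint (minimum boundary-to-boundary
#' distance, approximated on `n`-point boundary polygons), zero at tangency,
#' and negative when they overlap. The negative value is the maximal mutual
#' penetration: the largest distance from a boundary point of one ellipse
#' lying inside the other to that other ellipse's boundary.
#'
#' @param e1,e2 Ellipse vectors `(x, y, a, b, theta)`.
#' @param n Boundary points per ellipse used in the polygonal evaluation.
#' @return Signed distance in nm.
#' @export
ellipse_edge_distance <- function(e1, e2, n = 128) {
  b1 <- ellipse_boundary(e1, n)
  b2 <- ellipse_boundary(e2, n)
  if (!ellipses_overlap(e1, e2)) {
    return(min_pointset_distance(b1, b2))
  }
  in2 <- point_in_ellipse(b1[, 1], b1[, 2], e2)
  in1 <- point_in_ellipse(b2[, 1], b2[, 2], e1)
  pen <- 0
  if (any(in2)) {
    d2 <- outer(b1[in2, 1, drop = FALSE][, 1], b2[, 1], "-")^2 +
      outer(b1[in2, 2, drop = FALSE][, 1], b2[, 2], "-")^2
    pen <- max(pen, max(sqrt(apply(d2, 1, min))))
  }
  if (any(in1)) {
    d2 <- outer(b2[in1, 1, drop = FALSE][, 1], b1[, 1], "-")^2 +
      outer(b2[in1, 2, drop = FALSE][, 1], b1[, 2], "-")^2
    pen <- max(pen, max(sqrt(apply(d2, 1, min))))
  }
  # one ellipse fully inside the other: no boundary point of either is
  # inside the other is impossible then; containment always marks points
  -pen
}

#' Distance from points to a polyline
#'
#' Minimum euclidean distance from each point to any segment of the
#' polyline (point-to-segment distances).
#'
#' @param px,py Point coordinates (nm), vectorized.
#' @param line A data frame or matrix with columns `x`, `y` (polyline
#'   vertices in order, at least 2).
#' @return Numeric vector of distances (nm).
#' @export
point_polyline_distance <- function(px, py, line) {
  if (is.data.frame(line)) line <- cbind(line$x, line$y)
  if (nrow(line) < 2) abort("polyline needs at least 2 vertices")
  best <- rep(Inf, length(px))
  for (k in seq_len(nrow(line) - 1)) {
    x1 <- line[k, 1]; y1 <- line[k, 2]
    x2 <- line[k + 1, 1]; y2 <- line[k + 1, 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
    d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
    best <- pmin(best, d)
  }
  best
}
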