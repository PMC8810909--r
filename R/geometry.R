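#' Planar polygon utilities
#'
#' Polygons are two-column numeric matrices (x, y) of vertices in order,
#' without a repeated closing vertex. Coordinates are meters in a planar
#' (projected) system; [project_aeqd()] converts geographic coordinates
#' to such a system.
#'
#' @name polygon-utils
#' @keywords internal
NULL

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L || !is.numeric(poly))
    stop("a polygon must be a numeric matrix with >= 3 rows and 2 columns")
  # drop a repeated closing vertex if present
  n <- nrow(poly)
  if (isTRUE(all(poly[1L, ] == poly[n, ]))) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("degenerate polygon")
  poly
}

#' Signed area of a polygon (shoelace formula)
#' @param poly two-column vertex matrix
#' @return signed area; positive for counter-clockwise vertex order
#' @keywords internal
polygon_area_signed <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Area of a polygon
#' @param poly two-column vertex matrix
#' @return area in squared coordinate units
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(as_polygon(poly)))

#' Centroid of a polygon
#' @param poly two-column vertex matrix
#' @return length-2 numeric (x, y)
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  i2 <- c(2:n, 1L)
  cross <- x * y[i2] - x[i2] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) stop("degenerate polygon: zero area")
  cx <- sum((x + x[i2]) * cross) / (6 * a)
  cy <- sum((y + y[i2]) * cross) / (6 * a)
  c(cx, cy)
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray-casting rule; points on the boundary may fall on either
#' side at floating-point precision.
#'
#' @param x,y point coordinates (vectorized)
#' @param poly two-column vertex matrix
#' @return logical vector
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points (x, y) to segment (ax, ay)-(bx, by)
dist_point_segment <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
  sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
}

#' Distance from points to a polygon (0 inside)
#' @param x,y point coordinates (vectorized)
#' @param poly two-column vertex matrix
#' @return numeric vector of distances; 0 for interior points
#' @export
dist_to_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  d <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_point_segment(x, y, poly[j, 1L], poly[j, 2L],
                                    poly[i, 1L], poly[i, 2L]))
    j <- i
  }
  d[point_in_polygon(x, y, poly)] <- 0
  d
}

#' Dilate a convex polygon by a fixed distance
#'
#' Minkowski sum of a convex polygon with a disc of radius `dist`,
#' approximated by the convex hull of circles of radius `dist` sampled
#' at `n_arc` points around each vertex. Edges are offset exactly; the
#' rounded corners are inscribed polylines, so the result underestimates
#' the true buffer area by O(1/n_arc^2).
#'
#' @param poly two-column vertex matrix of a convex polygon
#' @param dist buffer distance (> 0), same units as the coordinates
#' @param n_arc arc sample count per vertex
#' @return two-column vertex matrix of the buffered polygon
#' @export
buffer_polygon <- function(poly, dist, n_arc = 48L) {
  poly <- as_polygon(poly)
  if (!is.finite(dist) || dist <= 0) stop("buffer distance must be > 0")
  if (polygon_area(poly) <= 0) stop("degenerate polygon: zero area")
  theta <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  cx <- rep(poly[, 1L], each = n_arc) + dist * cos(theta)
  cy <- rep(poly[, 2L], each = n_arc) + dist * sin(theta)
  pts <- cbind(cx, cy)
  hull <- grDevices::chull(pts)
  unname(pts[hull, , drop = FALSE])
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping; the subject polygon may be non-convex
#' (the clip window is convex), so the clipped area is exact for simple
#' polygons.
#'
#' @param poly two-column vertex matrix
#' @param xmin,xmax,ymin,ymax rectangle bounds
#' @return clipped vertex matrix (possibly with 0 rows)
#' @export
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  poly <- as.matrix(poly)
  # clip against one half-plane sign * coord[, axis] >= sign * val;
  # vectorized Sutherland-Hodgman step
  clip_half <- function(p, axis, val, sign) {
    m <- nrow(p)
    if (m == 0L) return(p)
    inside <- sign * p[, axis] >= sign * val
    nxt <- c(2:m, 1L)
    cross <- inside != inside[nxt]
    t <- (val - p[, axis]) / (p[nxt, axis] - p[, axis])
    inter <- p + t * (p[nxt, , drop = FALSE] - p)
    all_pts <- matrix(0, 2L * m, 2L)
    all_pts[seq(1L, 2L * m, 2L), ] <- p
    all_pts[seq(2L, 2L * m, 2L), ] <- inter
    keep <- as.vector(rbind(inside, cross))
    all_pts[keep, , drop = FALSE]
  }
  poly <- clip_half(poly, 1L, xmin, 1)
  poly <- clip_half(poly, 1L, xmax, -1)
  poly <- clip_half(poly, 2L, ymin, 1)
  poly <- clip_half(poly, 2L, ymax, -1)
  poly
}

#' Regular polygon approximating a disc
#' @param x,y center
#' @param radius disc radius
#' @param n number of vertices
#' @return two-column vertex matrix
#' @keywords internal
disc_polygon <- function(x, y, radius, n = 64L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x + radius * cos(theta), y + radius * sin(theta))
}

#' Azimuthal equidistant projection (spherical)
#'
#' Projects geographic coordinates (degrees) onto a plane centered at
#' `center`, preserving distance and azimuth from the center. Used to
#' move per-city geometry into meters before metric operations.
#'
#' @param lonlat two-column matrix of (longitude, latitude) in degrees
#' @param center length-2 (longitude, latitude) of the projection center
#' @param radius_m sphere radius in meters
#' @return two-column matrix of planar (x, y) in meters
#' @export
project_aeqd <- function(lonlat, center, radius_m = 6371008.8) {
  lonlat <- matrix(as.numeric(lonlat), ncol = 2L)
  lam <- lonlat[, 1L] * pi / 180; phi <- lonlat[, 2L] * pi / 180
  lam0 <- center[1L] * pi / 180; phi0 <- center[2L] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- radius_m * k * cos(phi) * sin(lam - lam0)
  y <- radius_m * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x, y)
}
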