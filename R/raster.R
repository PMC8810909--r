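#' In-memory planar grid raster
#'
#' A minimal regular-grid raster: a numeric matrix of cell values on a
#' square-cell grid with a planar origin. `values[i, j]` is the cell
#' whose center is at `(xmin + (i - 0.5) * cellsize,
#' ymin + (j - 0.5) * cellsize)`. Missing cells are `NA`.
#'
#' @param values numeric matrix (x index by y index)
#' @param xmin,ymin coordinates of the grid's lower-left corner (meters)
#' @param cellsize cell edge length in meters (> 0)
#' @return an object of class `grid_raster`
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("invalid config: cellsize must be > 0")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("grid_raster: %d x %d cells, %g m resolution\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("extent: x [%g, %g], y [%g, %g]\n", e[1], e[2], e[3], e[4]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("values: %g .. %g (mean %g)\n",
                             min(v), max(v), mean(v)))
  invisible(x)
}

#' Extent of a grid raster
#' @param r a `grid_raster`
#' @return numeric (xmin, xmax, ymin, ymax)
#' @export
raster_extent <- function(r) {
  c(r$xmin, r$xmin + nrow(r$values) * r$cellsize,
    r$ymin, r$ymin + ncol(r$values) * r$cellsize)
}

#' Raster value at point locations (nearest cell)
#' @param r a `grid_raster`
#' @param x,y point coordinates
#' @return numeric vector; `NA` outside the raster
#' @export
raster_value_at <- function(r, x, y) {
  i <- floor((x - r$xmin) / r$cellsize) + 1L
  j <- floor((y - r$ymin) / r$cellsize) + 1L
  ok <- i >= 1L & i <= nrow(r$values) & j >= 1L & j <= ncol(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(i[ok], j[ok])]
  out
}

#' Bilinear interpolation of a grid raster at point locations
#' @param r a `grid_raster`
#' @param x,y point coordinates (clamped to the cell-center lattice)
#' @return numeric vector
#' @export
raster_bilinear <- function(r, x, y) {
  nx <- nrow(r$values); ny <- ncol(r$values)
  fx <- (x - r$xmin) / r$cellsize - 0.5
  fy <- (y - r$ymin) / r$cellsize - 0.5
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx) + 1L, nx - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fy) + 1L, ny - 1L); j0 <- pmax(j0, 1L)
  tx <- fx - (i0 - 1L); ty <- fy - (j0 - 1L)
  v00 <- r$values[cbind(i0, j0)]
  v10 <- r$values[cbind(i0 + 1L, j0)]
  v01 <- r$values[cbind(i0, j0 + 1L)]
  v11 <- r$values[cbind(i0 + 1L, j0 + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

# indices of cells whose rectangle intersects the bbox [x0,x1]x[y0,y1]
cells_in_bbox <- function(r, x0, x1, y0, y1) {
  i0 <- max(1L, floor((x0 - r$xmin) / r$cellsize) + 1L)
  i1 <- min(nrow(r$values), ceiling((x1 - r$xmin) / r$cellsize))
  j0 <- max(1L, floor((y0 - r$ymin) / r$cellsize) + 1L)
  j1 <- min(ncol(r$values), ceiling((y1 - r$ymin) / r$cellsize))
  if (i0 > i1 || j0 > j1) return(NULL)
  list(i = i0:i1, j = j0:j1)
}

# area-weighted mean of raster cells over a polygon, exact
# cell-rectangle intersection weights; NA cells dropped from both sums
polygon_weighted_mean <- function(r, poly) {
  poly <- as_polygon(poly)
  bb <- cells_in_bbox(r, min(poly[, 1L]), max(poly[, 1L]),
                      min(poly[, 2L]), max(poly[, 2L]))
  if (is.null(bb)) stop("polygon does not overlap the raster")
  cs <- r$cellsize
  num <- 0; den <- 0
  for (j in bb$j) {
    ylo <- r$ymin + (j - 1L) * cs; yhi <- ylo + cs
    for (i in bb$i) {
      xlo <- r$xmin + (i - 1L) * cs; xhi <- xlo + cs
      v <- r$values[i, j]
      if (is.na(v)) next
      clipped <- clip_polygon_rect(poly, xlo, xhi, ylo, yhi)
      if (nrow(clipped) < 3L) next
      w <- abs(polygon_area_signed(clipped))
      num <- num + w * v
      den <- den + w
    }
  }
  if (den <= 0) stop("polygon does not overlap any non-missing raster cell")
  num / den
}

#' Mean raster value in a disc around a point
#'
#' Area-weighted mean of the cells intersecting the disc of the given
#' radius. Cell weights are exact rectangle intersections with a
#' 64-gon approximation of the disc; cells wholly inside the disc get
#' full weight without clipping. Missing cells are excluded from both
#' numerator and denominator.
#'
#' @param r a `grid_raster`
#' @param x,y disc center
#' @param radius disc radius in meters (> 0)
#' @param n_arc vertex count of the disc polygon
#' @return area-weighted mean (scalar)
#' @export
extract_point_buffer <- function(r, x, y, radius, n_arc = 64L) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  bb <- cells_in_bbox(r, x - radius, x + radius, y - radius, y + radius)
  if (is.null(bb)) stop("buffer disc entirely outside the raster")
  cs <- r$cellsize
  disc <- disc_polygon(x, y, radius, n_arc)
  # inscribed-circle radius of the disc polygon: cells within it are
  # wholly inside and need no clipping
  r_in <- radius * cos(pi / n_arc)
  xc <- r$xmin + (bb$i - 0.5) * cs
  yc <- r$ymin + (bb$j - 0.5) * cs
  num <- 0; den <- 0
  half_diag <- cs * sqrt(2) / 2
  for (jj in seq_along(bb$j)) {
    for (ii in seq_along(bb$i)) {
      v <- r$values[bb$i[ii], bb$j[jj]]
      if (is.na(v)) next
      d <- sqrt((xc[ii] - x)^2 + (yc[jj] - y)^2)
      if (d + half_diag <= r_in) {
        w <- cs * cs
      } else if (d - half_diag >= radius) {
        next
      } else {
        xlo <- r$xmin + (bb$i[ii] - 1L) * cs
        ylo <- r$ymin + (bb$j[jj] - 1L) * cs
        clipped <- clip_polygon_rect(disc, xlo, xlo + cs, ylo, ylo + cs)
        if (nrow(clipped) < 3L) next
        w <- abs(polygon_area_signed(clipped))
        if (w <= 0) next
      }
      num <- num + w * v
      den <- den + w
    }
  }
  if (den <= 0) stop("buffer disc covers no non-missing raster cell")
  num / den
}

#' Write / read a grid raster as plain text
#'
#' Header lines (`xmin`, `ymin`, `cellsize`, `nx`, `ny`) followed by
#' values in column-major order, one y-row per line. `NA` encodes
#' missing cells.
#'
#' @param r a `grid_raster`
#' @param path file path
#' @return `read_grid_raster` returns a `grid_raster`
#' @export
write_grid_raster <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("xmin %.10g", r$xmin), con)
  writeLines(sprintf("ymin %.10g", r$ymin), con)
  writeLines(sprintf("cellsize %.10g", r$cellsize), con)
  writeLines(sprintf("nx %d", nrow(r$values)), con)
  writeLines(sprintf("ny %d", ncol(r$values)), con)
  for (j in seq_len(ncol(r$values)))
    writeLines(paste(format(r$values[, j], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_grid_raster
#' @export
read_grid_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:5], " ", fixed = TRUE)
  get <- function(k) {
    m <- vapply(hdr, `[`, "", 1L) == k
    as.numeric(hdr[[which(m)]][2L])
  }
  nx <- as.integer(get("nx")); ny <- as.integer(get("ny"))
  vals <- vapply(lines[5L + seq_len(ny)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    out <- rep(NA_real_, length(tok))
    ok <- tok != "NA"
    out[ok] <- as.numeric(tok[ok])
    out
  }, numeric(nx))
  grid_raster(matrix(vals, nrow = nx, ncol = ny),
              xmin = get("xmin"), ymin = get("ymin"),
              cellsize = get("cellsize"))
}
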