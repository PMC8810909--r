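#' Spatial neighbor search, weights, and autocorrelation diagnostics
#'
#' Distance-based machinery used for spatial thinning, the residual
#' autocovariate, and Moran's I correlograms. Coordinates are planar
#' meters. Neighbor search uses grid binning so only near pairs are
#' enumerated; distances are exact Euclidean.
#'
#' @name spatial
NULL

# all index pairs (i < j) with distance <= radius, as a list of
# integer vectors i, j and numeric d; grid-binned, chunked so no
# full n x n matrix is formed
pairs_within <- function(x, y, radius, chunk = 2e6) {
  n <- length(x)
  stopifnot(length(y) == n, radius > 0)
  if (n < 2L)
    return(list(i = integer(0), j = integer(0), d = numeric(0)))
  cx <- floor(x / radius); cy <- floor(y / radius)
  key <- paste(cx, cy, sep = ",")
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(strsplit(names(cells), ",", fixed = TRUE),
                                   as.numeric))
  cell_id <- stats::setNames(seq_along(cells), names(cells))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  emit <- function(ii, jj, dd) {
    k <<- k + 1L
    out_i[[k]] <<- ii; out_j[[k]] <<- jj; out_d[[k]] <<- dd
  }
  cross_pairs <- function(a, b) {
    # pairs between disjoint index sets a, b within radius
    step <- max(1L, floor(chunk / length(b)))
    for (s in seq(1L, length(a), by = step)) {
      aa <- a[s:min(s + step - 1L, length(a))]
      dx <- outer(x[aa], x[b], "-"); dy <- outer(y[aa], y[b], "-")
      d2 <- dx * dx + dy * dy
      hit <- which(d2 <= radius^2, arr.ind = TRUE)
      if (nrow(hit)) {
        ii <- aa[hit[, 1L]]; jj <- b[hit[, 2L]]
        sw <- ii > jj
        tmp <- ii[sw]; ii[sw] <- jj[sw]; jj[sw] <- tmp
        emit(ii, jj, sqrt(d2[hit]))
      }
    }
  }
  within_pairs <- function(a) {
    m <- length(a)
    if (m < 2L) return()
    step <- max(1L, floor(chunk / m))
    for (s in seq(1L, m, by = step)) {
      rows <- s:min(s + step - 1L, m)
      dx <- outer(x[a[rows]], x[a], "-"); dy <- outer(y[a[rows]], y[a], "-")
      d2 <- dx * dx + dy * dy
      hit <- which(d2 <= radius^2, arr.ind = TRUE)
      if (nrow(hit)) {
        ii <- a[rows][hit[, 1L]]; jj <- a[hit[, 2L]]
        keep <- ii < jj
        if (any(keep)) emit(ii[keep], jj[keep], sqrt(d2[hit])[keep])
      }
    }
  }
  # forward neighbor offsets so each cell pair is visited once
  offsets <- rbind(c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (c_idx in seq_along(cells)) {
    within_pairs(cells[[c_idx]])
    for (o in seq_len(nrow(offsets))) {
      nb_key <- paste(cell_xy[c_idx, 1L] + offsets[o, 1L],
                      cell_xy[c_idx, 2L] + offsets[o, 2L], sep = ",")
      nb <- cell_id[nb_key]
      if (!is.na(nb)) cross_pairs(cells[[c_idx]], cells[[nb]])
    }
  }
  list(i = unlist(out_i), j = unlist(out_j), d = unlist(out_d))
}

#' Greatest nearest-neighbor distance
#'
#' For each point, the distance to its nearest neighbor; returns the
#' maximum of these. Used as the default neighborhood radius for the
#' residual autocovariate.
#'
#' @param x,y point coordinates (>= 2 points)
#' @return scalar distance in meters
#' @export
max_nn_distance <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  bbox_diag <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  radius <- max(bbox_diag / sqrt(n), bbox_diag * 1e-6)
  nn <- rep(Inf, n)
  repeat {
    pr <- pairs_within(x, y, radius)
    if (length(pr$i)) {
      nn_i <- tapply(pr$d, factor(pr$i, levels = seq_len(n)), min)
      nn_j <- tapply(pr$d, factor(pr$j, levels = seq_len(n)), min)
      nn <- pmin(ifelse(is.na(nn_i), Inf, nn_i),
                 ifelse(is.na(nn_j), Inf, nn_j))
    }
    if (all(is.finite(nn)) || radius > 2 * bbox_diag) break
    radius <- radius * 2
  }
  max(nn)
}

#' Inverse-distance spatial weights within a radius
#'
#' Symmetric binary-style ("B") inverse-distance weights: every pair
#' of points within `radius` gets weight `1/d` (no row
#' standardization). Coincident points are assigned the distance floor
#' `eps` = half the minimum nonzero pairwise distance so the weight is
#' finite. Points with no neighbor are flagged isolated.
#'
#' @param x,y point coordinates
#' @param radius neighborhood radius in meters (> 0)
#' @return object of class `spatial_weights`: triplet pairs
#'   (`i`, `j`, `d`, `w` with `i < j`), `n`, `radius`, `style`,
#'   logical `isolated`
#' @export
build_weights <- function(x, y, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  pr <- pairs_within(x, y, radius)
  d <- pr$d
  if (any(d == 0)) {
    nz <- d[d > 0]
    eps <- if (length(nz)) min(nz) / 2 else radius / 2
    d[d == 0] <- eps
  }
  n <- length(x)
  isolated <- !(seq_len(n) %in% c(pr$i, pr$j))
  structure(list(i = pr$i, j = pr$j, d = d, w = 1 / d, n = n,
                 radius = radius, style = "B", isolated = isolated),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf(
    "spatial_weights: %d points, %d pairs within %g m (style %s), %d isolated\n",
    x$n, length(x$i), x$radius, x$style, sum(x$isolated)))
  invisible(x)
}

#' Spatial autocovariate: weighted mean of neighbors' values
#'
#' For each point, the inverse-distance weighted mean of the values at
#' its neighbors: `a_i = sum_j w_ij v_j / sum_j w_ij`. Isolated points
#' get 0.
#'
#' @param values numeric vector aligned with the weights' points
#' @param weights a [build_weights()] object
#' @return numeric vector of autocovariate values
#' @export
autocovariate <- function(values, weights) {
  if (length(values) != weights$n)
    stop("values length does not match the number of points in weights")
  num <- numeric(weights$n); den <- numeric(weights$n)
  if (length(weights$i)) {
    num <- tapply2(weights$w * values[weights$j], weights$i, weights$n) +
           tapply2(weights$w * values[weights$i], weights$j, weights$n)
    den <- tapply2(weights$w, weights$i, weights$n) +
           tapply2(weights$w, weights$j, weights$n)
  }
  out <- numeric(weights$n)
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

# sum `v` into bins given by integer index `g` over 1..n
tapply2 <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Moran's I correlogram over distance bins
#'
#' For each distance bin `(lo, hi]`, Moran's I with binary weights
#' over the point pairs whose separation falls in the bin:
#' `I = (n / S0) * sum_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the number of (ordered) neighbor pairs. Bins with no
#' pairs get `NA`.
#'
#' @param values numeric vector (non-constant)
#' @param x,y point coordinates
#' @param bin_edges increasing numeric vector of bin edges in meters
#'   (the first bin is `(edges[1], edges[2]]`; use 0 as the first edge)
#' @return data.frame with `bin_lo`, `bin_hi`, `I`, `n_pairs`
#' @export
morans_i <- function(values, x, y, bin_edges) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 points")
  if (stats::var(values) == 0) stop("Moran's I undefined for constant values")
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  z <- values - mean(values)
  denom <- sum(z^2)
  pr <- pairs_within(x, y, max(bin_edges))
  bin <- findInterval(pr$d, bin_edges, left.open = TRUE)
  ok <- bin >= 1L & bin <= length(bin_edges) - 1L & pr$d > bin_edges[1L]
  nb <- length(bin_edges) - 1L
  cross <- numeric(nb); np <- integer(nb)
  if (any(ok)) {
    s <- rowsum(cbind(z[pr$i[ok]] * z[pr$j[ok]], 1), bin[ok])
    idx <- as.integer(rownames(s))
    cross[idx] <- s[, 1L]
    np[idx] <- as.integer(s[, 2L])
  }
  I <- ifelse(np > 0, (n / np) * cross / denom, NA_real_)
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1L],
             I = I, n_pairs = np)
}
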