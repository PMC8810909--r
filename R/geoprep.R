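#' Study-region construction and predictor assembly
#'
#' From city footprints to the per-observation model frame: buffered
#' study regions, city selection and de-overlap, spatial thinning of
#' records, covariate extraction, within-city impervious rescaling and
#' global standardization.
#'
#' @name geoprep
NULL

#' Build a buffered study region from a city footprint
#'
#' The footprint's centroid is computed, then the distance from the
#' centroid to the footprint's maximum extent (bounding-box edge) in
#' each of the four cardinal directions; the buffer distance is
#' `buffer_fraction` times the mean of those four distances, and the
#' buffered polygon is the footprint dilated by that distance.
#' Geographic footprints (longitude/latitude) are first projected to an
#' azimuthal equidistant plane centered on the footprint's vertex mean.
#'
#' @param footprint two-column vertex matrix (planar meters, or
#'   degrees with `geographic = TRUE`)
#' @param city_id identifier for the city
#' @param buffer_fraction fraction of the mean cardinal-extent
#'   distance used as buffer (default 0.25)
#' @param geographic is the footprint in longitude/latitude degrees?
#' @return object of class `study_region` with the footprint and
#'   buffered polygons (planar meters), centroid, buffer and area
#'   metadata; covariates are filled by [extract_region_covariates()]
#' @export
buffer_city <- function(footprint, city_id = "city", buffer_fraction = 0.25,
                        geographic = FALSE) {
  footprint <- as_polygon(footprint)
  proj_center <- NULL
  if (geographic) {
    proj_center <- colMeans(footprint)
    footprint <- project_aeqd(footprint, proj_center)
  }
  if (polygon_area(footprint) <= 0) stop("degenerate polygon: zero area")
  ctr <- polygon_centroid(footprint)
  d_e <- max(footprint[, 1L]) - ctr[1L]
  d_w <- ctr[1L] - min(footprint[, 1L])
  d_n <- max(footprint[, 2L]) - ctr[2L]
  d_s <- ctr[2L] - min(footprint[, 2L])
  buf <- buffer_fraction * mean(c(d_n, d_s, d_e, d_w))
  structure(list(
    city_id = city_id,
    footprint = footprint,
    buffered = buffer_polygon(footprint, buf),
    centroid = ctr,
    buffer_distance = buf,
    city_area_ha = polygon_area(footprint) / 1e4,
    proj_center = proj_center,
    forest_pct = NA_real_, winter_temp = NA_real_),
    class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf(
    "study_region %s: area %.0f ha, buffer %.0f m, forest %.3g%%, winter %.3g degC\n",
    x$city_id, x$city_area_ha, x$buffer_distance, x$forest_pct,
    x$winter_temp))
  invisible(x)
}

# planar coordinates of points in a region's projection
region_coords <- function(region, x, y) {
  if (is.null(region$proj_center)) return(cbind(x, y))
  project_aeqd(cbind(x, y), region$proj_center)
}

#' Membership of points in a region's buffered polygon
#' @param region a [buffer_city()] region
#' @param x,y point coordinates (same system the footprint arrived in)
#' @return logical vector
#' @export
region_contains <- function(region, x, y) {
  xy <- region_coords(region, x, y)
  point_in_polygon(xy[, 1L], xy[, 2L], region$buffered)
}

#' Select study cities and assign observations
#'
#' Each (already thinned) observation is matched to every buffered
#' region containing it. Regions with fewer than `min_obs`
#' observations are dropped. When two retained regions overlap (share
#' at least one observation or intersect geometrically), the one with
#' the larger sample is kept; samples within 5% of each other are
#' broken by the convex-hull area of the assigned observations
#' (larger spatial spread wins). Observations lying in two retained
#' non-overlapping regions go to the region with the nearer centroid.
#'
#' @param regions list of [buffer_city()] regions
#' @param obs data.frame with columns `x`, `y`
#' @param min_obs minimum observations to retain a region (default 100)
#' @return list with `regions` (retained) and `city_id` (character
#'   vector aligned with `obs` rows; `NA` for unassigned records)
#' @export
select_cities <- function(regions, obs, min_obs = 100L) {
  m <- vapply(regions, function(r) region_contains(r, obs$x, obs$y),
              logical(nrow(obs)))
  m <- matrix(m, nrow = nrow(obs))
  counts <- colSums(m)
  keep <- counts >= min_obs
  hull_area <- function(k) {
    pts <- cbind(obs$x[m[, k]], obs$y[m[, k]])
    if (nrow(pts) < 3L) return(0)
    polygon_area(pts[grDevices::chull(pts), , drop = FALSE])
  }
  overlapping <- function(a, b) {
    if (any(m[, a] & m[, b])) return(TRUE)
    pa <- regions[[a]]$buffered; pb <- regions[[b]]$buffered
    any(region_contains(regions[[b]], pa[, 1L], pa[, 2L])) ||
      any(region_contains(regions[[a]], pb[, 1L], pb[, 2L]))
  }
  repeat {
    idx <- which(keep)
    dropped <- FALSE
    for (a in idx) {
      for (b in idx[idx > a]) {
        if (!keep[a] || !keep[b]) next
        if (!overlapping(a, b)) next
        na <- counts[a]; nb <- counts[b]
        loser <- if (abs(na - nb) > 0.05 * max(na, nb)) {
          if (na >= nb) b else a
        } else {
          if (hull_area(a) >= hull_area(b)) b else a
        }
        keep[loser] <- FALSE
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  retained <- regions[keep]
  mk <- m[, keep, drop = FALSE]
  city_id <- rep(NA_character_, nrow(obs))
  if (length(retained)) {
    ctrs <- t(vapply(retained, `[[`, numeric(2), "centroid"))
    for (i in seq_len(nrow(obs))) {
      hits <- which(mk[i, ])
      if (length(hits) == 0L) next
      if (length(hits) > 1L) {
        d2 <- (ctrs[hits, 1L] - obs$x[i])^2 + (ctrs[hits, 2L] - obs$y[i])^2
        hits <- hits[which.min(d2)]
      }
      city_id[i] <- retained[[hits]]$city_id
    }
  }
  list(regions = retained, city_id = city_id)
}

#' Spatially thin points to a minimum separation
#'
#' Retains a maximal subset of points such that no two retained points
#' are closer than `min_dist` (an independent set of the proximity
#' graph). The conflict graph decomposes into connected components;
#' each component of at most `exact_limit` points is solved to a
#' maximum independent set exactly by branch and bound, while larger
#' components use greedy thinning: repeatedly remove the point with
#' the most remaining conflicts, breaking ties uniformly at random
#' (seeded), over `reps` replicates, keeping the replicate that
#' retains the most points.
#'
#' @param x,y point coordinates (meters)
#' @param min_dist minimum allowed separation; pairs at exactly
#'   `min_dist` do not conflict
#' @param seed integer seed for the greedy tie-breaks
#' @param reps greedy replicates for large components
#' @param exact_limit largest component solved exactly
#' @return integer indices of retained points, increasing
#' @export
thin_points <- function(x, y, min_dist, seed = 1L, reps = 10L,
                        exact_limit = 25L) {
  n <- length(x)
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (n < 2L || min_dist == 0) return(seq_len(n))
  pr <- pairs_within(x, y, min_dist)
  conflict <- pr$d < min_dist
  if (!any(conflict)) return(seq_len(n))
  ei <- pr$i[conflict]; ej <- pr$j[conflict]
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  # connected components of the conflict graph
  comp <- integer(n); nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L || length(adj[[s]]) == 0L) next
    nc <- nc + 1L
    queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  keep <- comp == 0L  # isolated points are always retained
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (cc in seq_len(nc)) {
    verts <- which(comp == cc)
    sel <- if (length(verts) <= exact_limit) {
      mis_exact(verts, adj)
    } else {
      mis_greedy(verts, adj, reps)
    }
    keep[sel] <- TRUE
  }
  which(keep)
}

# exact maximum independent set by branch and bound on a small
# vertex set; branches on the highest-degree vertex
mis_exact <- function(verts, adj) {
  solve <- function(active) {
    if (length(active) == 0L) return(integer(0))
    deg <- vapply(active, function(v) sum(adj[[v]] %in% active), 0L)
    if (all(deg == 0L)) return(active)
    v <- active[which.max(deg)]
    # exclude v
    a <- solve(setdiff(active, v))
    # include v, drop its neighborhood
    b <- c(v, solve(setdiff(active, c(v, adj[[v]]))))
    if (length(b) >= length(a)) b else a
  }
  solve(verts)
}

# greedy max-conflict removal with random tie-breaks over replicates
mis_greedy <- function(verts, adj, reps) {
  best <- NULL
  for (rep in seq_len(reps)) {
    alive <- structure(rep(TRUE, length(verts)), names = verts)
    deg <- vapply(verts, function(v) length(adj[[v]]), 0L)
    names(deg) <- verts
    while (any(deg[alive] > 0L)) {
      mx <- max(deg[alive])
      cand <- which(alive & deg == mx)
      pick <- if (length(cand) == 1L) cand
              else cand[sample.int(length(cand), 1L)]
      alive[pick] <- FALSE
      v <- verts[pick]
      nb <- as.character(adj[[v]])
      nb <- nb[!is.na(alive[nb]) & alive[nb]]
      deg[nb] <- deg[nb] - 1L
      deg[as.character(v)] <- 0L
    }
    if (is.null(best) || sum(alive) > length(best))
      best <- verts[alive]
  }
  best
}

# evaluate expr under a local RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Region-level covariates from rasters
#'
#' Area-weighted means of the forest and temperature rasters over the
#' region's buffered polygon, with exact cell-intersection weights.
#'
#' @param region a [buffer_city()] region
#' @param forest_raster,temp_raster `grid_raster` objects in the
#'   region's planar system
#' @return the region with `forest_pct` and `winter_temp` filled
#' @export
extract_region_covariates <- function(region, forest_raster, temp_raster) {
  region$forest_pct <- polygon_weighted_mean(forest_raster, region$buffered)
  region$winter_temp <- polygon_weighted_mean(temp_raster, region$buffered)
  region
}

# center/scale a column, guarding a zero-variance degenerate case
standardize_col <- function(v) {
  m <- mean(v); s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant predictor")
  list(x = (v - m) / s, center = m, scale = s)
}

#' Assemble the per-observation model frame
#'
#' Builds the response and transformed predictors the model is fit to:
#' `melanic` is 1 for melanic records and 0 for gray and rare other
#' morphs; raw impervious cover is min-max rescaled within each city to
#' \[0, 1\] (a city whose records all share one impervious value gets 0
#' with a warning — it carries no within-city cline information); the
#' rescaled impervious, winter temperature, forest cover, and
#' log(city area) are then standardized to mean 0, SD 1 over the full
#' frame. The standardization statistics and per-city impervious
#' ranges are stored in the `"scaling"` attribute for prediction-time
#' reuse.
#'
#' @param obs data.frame with `obs_id`, `x`, `y`, `color`, `city_id`
#'   (rows with `NA` city are dropped)
#' @param regions list of regions with covariates filled, named or
#'   searchable by `city_id`
#' @param imperv numeric vector of raw impervious cover (percent) per
#'   observation row
#' @param standardize_imperv standardize the rescaled impervious
#'   variable (default) or use the raw \[0, 1\] rescaled value
#' @return data.frame of class `model_frame` with columns `obs_id`,
#'   `city_id`, `x`, `y`, `melanic`, `imperv_raw`, `imperv_rescaled`,
#'   `x_imperv`, `x_temp`, `x_forest`, `x_logsize`
#' @export
build_model_frame <- function(obs, regions, imperv,
                              standardize_imperv = TRUE) {
  stopifnot(nrow(obs) == length(imperv))
  keep <- !is.na(obs$city_id)
  obs <- obs[keep, , drop = FALSE]
  imperv <- imperv[keep]
  ids <- vapply(regions, `[[`, "", "city_id")
  ri <- match(obs$city_id, ids)
  if (anyNA(ri)) stop("observation assigned to an unknown city_id")
  forest <- vapply(regions, `[[`, 0, "forest_pct")[ri]
  wtemp <- vapply(regions, `[[`, 0, "winter_temp")[ri]
  area <- vapply(regions, `[[`, 0, "city_area_ha")[ri]
  if (anyNA(forest) || anyNA(wtemp))
    stop("regions are missing covariates; run extract_region_covariates first")
  resc <- numeric(nrow(obs))
  rng <- list()
  for (cid in unique(obs$city_id)) {
    sel <- obs$city_id == cid
    lo <- min(imperv[sel]); hi <- max(imperv[sel])
    if (hi - lo <= 0) {
      warning("city ", cid, " has constant impervious cover; ",
              "rescaled value set to 0")
      resc[sel] <- 0
    } else {
      resc[sel] <- (imperv[sel] - lo) / (hi - lo)
    }
    rng[[cid]] <- c(lo = lo, hi = hi)
  }
  imp_in <- if (standardize_imperv) standardize_col(resc)
            else list(x = resc, center = 0, scale = 1)
  tmp <- standardize_col(wtemp)
  fst <- standardize_col(forest)
  lsz <- standardize_col(log(area))
  frame <- data.frame(
    obs_id = obs$obs_id, city_id = obs$city_id,
    x = obs$x, y = obs$y,
    melanic = as.integer(obs$color == "melanic"),
    imperv_raw = imperv, imperv_rescaled = resc,
    x_imperv = imp_in$x, x_temp = tmp$x, x_forest = fst$x,
    x_logsize = lsz$x,
    stringsAsFactors = FALSE)
  attr(frame, "scaling") <- list(
    imperv = c(center = imp_in$center, scale = imp_in$scale),
    temp = c(center = tmp$center, scale = tmp$scale),
    forest = c(center = fst$center, scale = fst$scale),
    logsize = c(center = lsz$center, scale = lsz$scale),
    imperv_range = rng)
  class(frame) <- c("model_frame", "data.frame")
  frame
}
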