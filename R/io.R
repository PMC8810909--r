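#' GeoJSON footprint I/O
#'
#' City footprints travel as a GeoJSON FeatureCollection of Polygons
#' with a `city_id` property. Coordinates may be planar meters or
#' longitude/latitude degrees; [buffer_city()] handles either.
#'
#' @param polys named list of two-column vertex matrices
#' @param path file path
#' @return `read_footprints_geojson` returns a named list of vertex
#'   matrices
#' @export
write_footprints_geojson <- function(polys, path) {
  feats <- lapply(names(polys), function(id) {
    ring <- rbind(polys[[id]], polys[[id]][1L, ])
    list(type = "Feature",
         properties = list(city_id = id),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_footprints_geojson
#' @export
read_footprints_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("expected Polygon geometries")
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    id <- f$properties$city_id
    if (is.null(id)) id <- paste0("city", length(out) + 1L)
    out[[id]] <- as_polygon(m)
  }
  out
}

#' Write a run report's artifacts to a directory
#'
#' Writes the analysis frame and per-city table as CSV, the consensus
#' stage counts and fit summaries (term, estimate, SE, z, p, the
#' random-intercept SD, log-likelihood, convergence) as JSON, and the
#' before/after Moran correlograms as CSV when the autocovariate refit
#' ran.
#'
#' @param report a [run_pipeline()] report
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$frame, file.path(dir, "frame.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_city, file.path(dir, "per_city.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$consensus,
                       file.path(dir, "consensus_report.json"),
                       auto_unbox = TRUE, digits = NA)
  fit_json <- function(fit) list(
    coefficients = wald_tests(fit),
    sigma_city = fit$sigma,
    loglik = fit$loglik,
    converged = fit$converged)
  out <- list(initial = fit_json(report$fit))
  if (!is.null(report$rac)) {
    out$rac <- fit_json(report$rac$fit)
    out$rac_radius_m <- report$rac$radius
    if (!is.null(report$rac$moran_before)) {
      utils::write.csv(report$rac$moran_before,
                       file.path(dir, "moran_before.csv"),
                       row.names = FALSE)
      utils::write.csv(report$rac$moran_after,
                       file.path(dir, "moran_after.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(out, file.path(dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
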