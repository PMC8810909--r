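#' Pipeline configuration
#'
#' Defaults are the study-design values: 80% consensus agreement with
#' a minimum of 10 votes, 10 m spatial thinning, 1 km impervious
#' buffer, at least 100 observations per city, buffer fraction 0.25,
#' and sensitivity grids of 10/50/100 m thinning by 500 m/1 km/10 km
#' impervious radii.
#'
#' @param threshold,min_votes consensus agreement rule
#' @param thin_dist_m spatial thinning distance (meters)
#' @param imperv_radius_m impervious extraction radius (meters)
#' @param min_obs_per_city city retention threshold
#' @param buffer_fraction city buffer fraction
#' @param autocov refit with the residual autocovariate?
#' @param rac_radius `"auto"` (greatest nearest-neighbor distance) or
#'   meters
#' @param thin_dists,imperv_radii sensitivity grids
#' @param seed root seed for the thinning tie-breaks
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(threshold = 0.8, min_votes = 10L,
                            thin_dist_m = 10, imperv_radius_m = 1000,
                            min_obs_per_city = 100L,
                            buffer_fraction = 0.25,
                            autocov = TRUE, rac_radius = "auto",
                            thin_dists = c(10, 50, 100),
                            imperv_radii = c(500, 1000, 10000),
                            seed = 1L) {
  structure(list(threshold = threshold, min_votes = min_votes,
                 thin_dist_m = thin_dist_m,
                 imperv_radius_m = imperv_radius_m,
                 min_obs_per_city = min_obs_per_city,
                 buffer_fraction = buffer_fraction,
                 autocov = autocov, rac_radius = rac_radius,
                 thin_dists = thin_dists, imperv_radii = imperv_radii,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stage 1-2: votes -> retained observations (with a stage report)
stage_consensus <- function(study, config) {
  obs <- study$observations
  images <- data.frame(image_id = obs$obs_id, x = obs$x, y = obs$y,
                       in_native_range = TRUE)
  rv <- resolve_votes(study$votes, images, config$threshold,
                      config$min_votes)
  fl <- filter_observations(rv$observations, rv$report)
  merged <- merge_sources(fl$observations,
                          fl$observations[0, , drop = FALSE])
  list(observations = merged, report = fl$report)
}

# stages 3-6: thin, select cities, extract covariates, build frame
stage_frame <- function(study, obs, config,
                        thin_dist = config$thin_dist_m,
                        imperv_radius = config$imperv_radius_m) {
  keep <- thin_points(obs$x, obs$y, thin_dist, seed = config$seed)
  obs <- obs[keep, , drop = FALSE]
  regions <- lapply(study$landscapes, function(L) {
    r <- buffer_city(L$footprint, city_id = L$city_id,
                     buffer_fraction = config$buffer_fraction)
    if (!is.null(L$forest)) {
      r <- extract_region_covariates(r, L$forest, L$temp)
    } else {
      r$forest_pct <- L$params$forest_pct
      r$winter_temp <- L$params$winter_temp
    }
    r
  })
  sel <- select_cities(regions, obs, min_obs = config$min_obs_per_city)
  obs$city_id <- sel$city_id
  assigned <- which(!is.na(obs$city_id))
  obs <- obs[assigned, , drop = FALSE]
  by_city <- match(obs$city_id,
                   vapply(study$landscapes, `[[`, "", "city_id"))
  imperv <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    L <- study$landscapes[[by_city[i]]]
    imperv[i] <- if (!is.null(L$imperv)) {
      extract_point_buffer(L$imperv, obs$x[i], obs$y[i], imperv_radius)
    } else {
      d <- sqrt((obs$x[i] - L$center[1L])^2 + (obs$y[i] - L$center[2L])^2)
      imperv_decay(d, L$params)
    }
  }
  list(frame = build_model_frame(obs, sel$regions, imperv),
       regions = sel$regions, n_thinned = length(keep))
}

#' Run the full analysis pipeline
#'
#' Consensus aggregation of votes, source merging, spatial thinning,
#' city buffering/selection, covariate extraction, model-frame
#' assembly, the global GLMM fit, and (optionally) the residual
#' autocovariate refit with Moran's I correlograms. Deterministic
#' given the study and configuration.
#'
#' @param study a [simulate_study()] object, or a list with the same
#'   elements (`observations`, `votes`, `landscapes`)
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, stage artifacts are
#'   written as CSV/JSON via [write_run_report()]
#' @return object of class `run_report`
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         out_dir = NULL) {
  stage <- "consensus"
  report <- tryCatch({
    cons <- stage_consensus(study, config)
    stage <- "geoprep"
    fr <- stage_frame(study, cons$observations, config)
    frame <- fr$frame
    stage <- "fit"
    fit <- fit_melanism_model(frame)
    rac <- NULL
    if (isTRUE(config$autocov)) {
      stage <- "rac"
      rac <- rac_refit(frame, fit, radius = config$rac_radius)
    }
    stage <- "report"
    per_city <- do.call(rbind, lapply(split(frame, frame$city_id),
      function(d) data.frame(city_id = d$city_id[1L],
                             n_obs = nrow(d),
                             melanic_fraction = mean(d$melanic))))
    cov_tab <- data.frame(
      city_id = vapply(fr$regions, `[[`, "", "city_id"),
      city_area_ha = vapply(fr$regions, `[[`, 0, "city_area_ha"),
      forest_pct = vapply(fr$regions, `[[`, 0, "forest_pct"),
      winter_temp = vapply(fr$regions, `[[`, 0, "winter_temp"))
    per_city <- merge(per_city, cov_tab, by = "city_id")
    structure(list(
      consensus = cons$report,
      n_thinned = fr$n_thinned,
      per_city = per_city,
      frame = frame,
      fit = fit,
      rac = rac,
      config = config),
      class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  consensus: %d images submitted, %d observations retained\n",
              x$consensus$submitted, x$consensus$final))
  cat(sprintf("  %d cities, %d observations in the analysis frame\n",
              nrow(x$per_city), nrow(x$frame)))
  cat(sprintf("  melanism prevalence: %.3f\n", mean(x$frame$melanic)))
  print(if (is.null(x$rac)) x$fit else x$rac)
  invisible(x)
}

#' Sensitivity of the fit to thinning and impervious-buffer choices
#'
#' Refits the global model over the Cartesian grid of thinning
#' distances by impervious extraction radii and tabulates every
#' coefficient and SE per cell. Per-cell failures are recorded, not
#' fatal. The base model (no autocovariate) is fit in each cell.
#'
#' @param study as [run_pipeline()]
#' @param config a [pipeline_config()]; `thin_dists` and
#'   `imperv_radii` define the grid
#' @return data.frame with `thin_dist`, `imperv_radius`, `term`,
#'   `estimate`, `se` (and an `error` column when any cell failed)
#' @export
sensitivity_analysis <- function(study, config = pipeline_config()) {
  grid <- expand.grid(thin_dist = config$thin_dists,
                      imperv_radius = config$imperv_radii)
  if (nrow(grid) == 0L) stop("empty sensitivity grid")
  cons <- stage_consensus(study, config)
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    out[[k]] <- tryCatch({
      fr <- stage_frame(study, cons$observations, config,
                        thin_dist = grid$thin_dist[k],
                        imperv_radius = grid$imperv_radius[k])
      fit <- fit_melanism_model(fr$frame)
      cbind(grid[k, ], wald_tests(fit)[c("term", "estimate", "se")],
            row.names = NULL)
    }, error = function(e)
      cbind(grid[k, ], term = NA, estimate = NA, se = NA,
            error = conditionMessage(e), row.names = NULL))
  }
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    d[setdiff(nm, names(d))] <- NA
    d[nm]
  })
  do.call(rbind, out)
}
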