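#' The global melanism model
#'
#' The fixed-effect structure of the cline analysis: standardized
#' impervious cover, winter temperature, forest cover and log city
#' size, the three two-way interactions of impervious cover with the
#' city-level covariates, optionally the standardized residual
#' autocovariate, plus a random intercept per city.
#'
#' @param autocov include the `x_autocov` term?
#' @return a model formula
#' @export
melanism_formula <- function(autocov = FALSE) {
  rhs <- paste(c("x_imperv", "x_temp", "x_forest", "x_logsize",
                 "x_imperv:x_temp", "x_imperv:x_forest",
                 "x_imperv:x_logsize",
                 if (autocov) "x_autocov"),
               collapse = " + ")
  stats::as.formula(paste("melanic ~", rhs), env = globalenv())
}

#' Fit the global melanism GLMM to a model frame
#'
#' @param frame a [build_model_frame()] frame (needs `x_autocov` when
#'   `autocov = TRUE`)
#' @param autocov include the residual autocovariate term?
#' @param ... passed to [fit_glmm()]
#' @return a `glmm_fit` carrying the frame's scaling attribute
#' @export
fit_melanism_model <- function(frame, autocov = FALSE, ...) {
  fit <- fit_glmm(melanism_formula(autocov), frame, cluster = "city_id",
                  ...)
  fit$scaling <- attr(frame, "scaling")
  fit
}

#' Predicted urban-rural cline at chosen city characteristics
#'
#' Population-level predictions (random effect at zero) of the
#' probability of melanism over a grid of within-city rescaled
#' impervious cover, holding the city-level covariates at stated raw
#' values, e.g. winter temperature -5 vs 5 degC, city size 25,000 vs
#' 350,000 ha, forest cover 15 vs 45%. Raw values are converted to the
#' standardized scale with the statistics stored at fit time; settings
#' outside the training range give a warning.
#'
#' @param fit a [fit_melanism_model()] fit (must carry scaling)
#' @param imperv grid of rescaled impervious cover in \[0, 1\]
#' @param winter_temp winter temperature in degC
#' @param forest_pct forest cover percent
#' @param city_area_ha city footprint area in hectares
#' @param autocov autocovariate value on the standardized scale
#'   (default 0, its mean)
#' @return data.frame with `imperv` and `prob`
#' @export
predict_cline <- function(fit, imperv = seq(0, 1, length.out = 50),
                          winter_temp = -5, forest_pct = 30,
                          city_area_ha = 1e5, autocov = 0) {
  sc <- fit$scaling
  if (is.null(sc)) stop("fit carries no standardization statistics")
  std <- function(v, key)
    unname((v - sc[[key]][["center"]]) / sc[[key]][["scale"]])
  if (any(imperv < 0 | imperv > 1))
    warning("imperv grid outside [0, 1], the rescaled training range")
  newdata <- data.frame(
    x_imperv = std(imperv, "imperv"),
    x_temp = std(winter_temp, "temp"),
    x_forest = std(forest_pct, "forest"),
    x_logsize = std(log(city_area_ha), "logsize"))
  for (key in c("temp", "forest", "logsize")) {
    if (abs(newdata[[paste0("x_", key)]][1L]) > 3)
      warning("covariate setting for ", key,
              " is far outside the training range (|z| > 3)")
  }
  if ("x_autocov" %in% names(fit$beta)) newdata$x_autocov <- autocov
  data.frame(imperv = imperv,
             prob = predict(fit, newdata, type = "response", re = "zero"))
}

#' Refit the model with a residual spatial autocovariate
#'
#' Implements the residual-autocovariate correction for spatial
#' autocorrelation: response-scale residuals are extracted from the
#' initial fit; symmetric inverse-distance weights are built within
#' `radius` (default: the greatest nearest-neighbor distance of the
#' thinned data); each observation's autocovariate is the weighted
#' mean of its neighbors' residuals, standardized like the other
#' predictors; and the global model is refit with the autocovariate as
#' an additional fixed effect. Moran's I correlograms (1-km distance
#' rings up to the radius) of the residuals before and after the refit
#' are returned alongside.
#'
#' @param frame the model frame the initial fit used
#' @param fit the initial [fit_melanism_model()] fit
#' @param radius neighborhood radius in meters, or `"auto"`
#' @param residual_type residuals used for the autocovariate
#' @param bin_width correlogram ring width in meters
#' @param ... passed to [fit_glmm()] for the refit
#' @return object of class `rac_fit`: `fit` (the refit), `initial`
#'   (the input fit), `radius`, `autocov` (standardized values),
#'   `moran_before`, `moran_after`
#' @export
rac_refit <- function(frame, fit, radius = "auto",
                      residual_type = c("response", "pearson"),
                      bin_width = 1000, ...) {
  residual_type <- match.arg(residual_type)
  if (identical(radius, "auto")) radius <- max_nn_distance(frame$x, frame$y)
  res <- residuals(fit, type = residual_type)
  w <- build_weights(frame$x, frame$y, radius)
  ac <- autocovariate(res, w)
  if (stats::sd(ac) == 0) {
    # no pair within the radius: the autocovariate carries no signal
    frame$x_autocov <- ac
    refit <- fit
    moran_b <- moran_a <- NULL
  } else {
    frame$x_autocov <- (ac - mean(ac)) / stats::sd(ac)
    refit <- fit_melanism_model(frame, autocov = TRUE, ...)
    edges <- unique(c(seq(0, radius, by = bin_width), radius))
    moran_b <- morans_i(res, frame$x, frame$y, edges)
    moran_a <- morans_i(residuals(refit, type = residual_type),
                        frame$x, frame$y, edges)
  }
  structure(list(fit = refit, initial = fit, radius = radius,
                 autocov = frame$x_autocov,
                 moran_before = moran_b, moran_after = moran_a),
            class = "rac_fit")
}

#' @export
print.rac_fit <- function(x, ...) {
  cat(sprintf("rac_fit: autocovariate radius %.0f m\n", x$radius))
  if (!is.null(x$moran_before)) {
    fb <- x$moran_before$I[!is.na(x$moran_before$I)][1L]
    fa <- x$moran_after$I[!is.na(x$moran_after$I)][1L]
    mb <- max(x$moran_before$I, na.rm = TRUE)
    ma <- max(x$moran_after$I, na.rm = TRUE)
    cat(sprintf("residual Moran's I: first bin %.3f -> %.3f, max %.3f -> %.3f\n",
                fb, fa, mb, ma))
  }
  print(x$fit)
  invisible(x)
}
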