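test_that("sigma = 0 fit reproduces plain IRLS logistic regression", {
  d <- make_toy_frame(n_per_city = 250, n_cities = 8, seed = 11)
  f0 <- fit_glmm(y ~ x1, d, cluster = "city_id", sigma = 0)
  gl <- glm(y ~ x1, binomial, d)
  expect_lt(max(abs(coef(f0) - coef(gl))), 1e-6)
  expect_lt(max(abs(f0$se - summary(gl)$coefficients[, 2])), 1e-6)
  expect_equal(f0$loglik, as.numeric(logLik(gl)), tolerance = 1e-8)
})

test_that("intercept-only balanced outcome gives a zero intercept", {
  d <- data.frame(y = rep(c(0, 1), 100), city_id = "one")
  f <- fit_glmm(y ~ 1, d, cluster = "city_id", sigma = 0)
  expect_lt(abs(coef(f)[1]), 1e-8)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- make_toy_frame(n_per_city = 300, n_cities = 12, seed = 21,
                      beta = c(-0.8, 0.6), sigma = 0.8)
  f <- fit_glmm(y ~ x1, d, cluster = "city_id")
  m <- lme4::glmer(y ~ x1 + (1 | city_id), d, binomial)
  expect_lt(max(abs(coef(f) - lme4::fixef(m)) / f$se), 0.1)
  expect_equal(f$sigma, sqrt(unlist(lme4::VarCorr(m))[[1]]),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-3)
  expect_lt(max(abs(f$se - sqrt(diag(as.matrix(vcov(m)))))) , 0.005)
})

test_that("the Laplace objective collapses to the GLM log-likelihood as sigma -> 0", {
  d <- make_toy_frame(n_per_city = 100, n_cities = 5, seed = 3)
  ll_glm <- as.numeric(logLik(glm(y ~ x1, binomial, d)))
  lls <- vapply(c(0.3, 0.1, 0.01, 0.001), function(s)
    fit_glmm(y ~ x1, d, cluster = "city_id", sigma = s)$loglik, 0)
  gaps <- abs(lls - ll_glm)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 3e-4)
})

test_that("flipping a predictor's sign flips its coefficient, not its |z|", {
  d <- make_toy_frame(seed = 7)
  f1 <- fit_glmm(y ~ x1, d, cluster = "city_id")
  d2 <- d; d2$x1 <- -d2$x1
  f2 <- fit_glmm(y ~ x1, d2, cluster = "city_id")
  expect_equal(unname(coef(f2)["x1"]), -unname(coef(f1)["x1"]),
               tolerance = 1e-6)
  expect_equal(abs(wald_tests(f1)$z), abs(wald_tests(f2)$z),
               tolerance = 1e-6)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- make_toy_frame(seed = 2)
  d$x2 <- 2 * d$x1
  expect_error(fit_glmm(y ~ x1 + x2, d, cluster = "city_id"), "x2")
})

test_that("Wald arithmetic matches the normal reference", {
  f <- list(beta = c(a = 0, b = 0.196, c = 0.58),
            se = c(a = 1, b = 0.1, c = 0.28))
  class(f) <- "glmm_fit"
  tab <- wald_tests(f)
  expect_equal(tab$p[1], 1)
  expect_equal(tab$p[2], 0.05, tolerance = 1e-3)
  # estimate 0.58, SE 0.28: two-sided p in [0.037, 0.038]
  expect_gt(tab$p[3], 0.037)
  expect_lt(tab$p[3], 0.0385)
})

test_that("binned residuals partition correctly at the extremes", {
  d <- make_toy_frame(n_per_city = 64, n_cities = 4, seed = 13)
  f <- fit_glmm(y ~ x1, d, cluster = "city_id")
  n <- length(f$y)
  # n_bins = n: each bin is one residual, y_i - p_i exactly
  br <- binned_residuals(f, n_bins = n)
  ord <- order(f$fitted, seq_len(n))
  expect_equal(br$mean_resid, unname((f$y - f$fitted)[ord]))
  expect_true(all(br$n == 1L))
  # single bin: overall mean residual
  br1 <- binned_residuals(f, n_bins = 1)
  expect_equal(br1$mean_resid, mean(f$y - f$fitted))
  expect_error(binned_residuals(f, n_bins = n + 1), "n_bins")
})

test_that("binned residuals of a calibrated model stay inside the 2SE band", {
  # simulate directly from a fitted model class: fitted probabilities
  # are the truth, so about 95% of bins should sit inside the band
  set.seed(42)
  inside <- 0L; total <- 0L
  for (r in 1:40) {
    n <- 1600
    p <- plogis(rnorm(n, -1, 1))
    y <- rbinom(n, 1, p)
    f <- structure(list(y = y, fitted = p), class = "glmm_fit")
    br <- binned_residuals(f)
    inside <- inside + sum(abs(br$mean_resid) <= br$se2)
    total <- total + nrow(br)
  }
  expect_gte(inside / total, 0.93)
})

test_that("population-level cline predictions follow the link algebra", {
  d <- make_toy_frame(n_per_city = 150, n_cities = 6, seed = 17)
  names(d) <- c("melanic", "x1", "city_id")
  d$x_imperv <- d$x1
  d$x_temp <- rnorm(nrow(d)); d$x_forest <- rnorm(nrow(d))
  d$x_logsize <- rnorm(nrow(d))
  fit <- fit_glmm(melanism_formula(), d, cluster = "city_id")
  fit$scaling <- list(imperv = c(center = 0.5, scale = 0.25),
                      temp = c(center = 0, scale = 5),
                      forest = c(center = 30, scale = 10),
                      logsize = c(center = log(1e5), scale = 1))
  # at standardized covariates 0, the curve is plogis(b0 + b1 * x)
  pc <- predict_cline(fit, imperv = seq(0, 1, 0.25), winter_temp = 0,
                      forest_pct = 30, city_area_ha = 1e5)
  xg <- (seq(0, 1, 0.25) - 0.5) / 0.25
  expect_equal(pc$prob,
               plogis(coef(fit)["(Intercept)"] + coef(fit)["x_imperv"] * xg),
               ignore_attr = TRUE)
  # zeroed slopes give a flat curve at plogis(intercept)
  fit2 <- fit
  fit2$beta[-1] <- 0
  pc2 <- predict_cline(fit2, winter_temp = 0, forest_pct = 30,
                       city_area_ha = 1e5)
  expect_equal(pc2$prob, rep(plogis(coef(fit)[["(Intercept)"]]), 50))
  # positive impervious slope with zero interactions: strictly increasing
  fit3 <- fit
  fit3$beta[] <- c(-2, 1, 0, 0, 0, 0, 0, 0)
  pc3 <- predict_cline(fit3, winter_temp = 0, forest_pct = 30,
                       city_area_ha = 1e5)
  expect_true(all(diff(pc3$prob) > 0))
  expect_warning(predict_cline(fit, winter_temp = 1000), "training range")
})
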