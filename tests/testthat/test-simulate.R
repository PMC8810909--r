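test_that("configuration invariants are validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(city_area_range = c(10, 5)), "min")
  expect_error(sim_config(sigma_city = -1), "sigma_city")
  expect_error(sim_config(vote_error_rate = 1.2), "vote_error_rate")
  expect_error(sim_config(n_voters = 0), "n_voters")
  expect_error(sim_config(raster_cell_size = 0), "cell size")
  expect_error(sim_config(spatial_noise = list(range_m = -1, sd = 1)),
               "spatial_noise")
})

test_that("landscapes have exact-area footprints and a monotone urban core", {
  cfg <- sim_config(n_cities = 3, city_area_range = c(5000, 35000),
                    seed = 23)
  L <- simulate_landscape(cfg, 1, rasters = TRUE)
  # polygon area matches the drawn city size within 1%
  expect_lt(abs(polygon_area(L$footprint) / 1e4 - L$params$area_ha) /
              L$params$area_ha, 0.01)
  # expected impervious is strictly greater at the centroid than far out
  expect_gt(imperv_decay(0, L$params), imperv_decay(10000, L$params))
  expect_true(all(diff(imperv_decay(seq(0, 2e4, 500), L$params)) <= 0))
  # zero decay amplitude: the surface is the baseline everywhere
  prm0 <- L$params; prm0$imp_amp <- 0
  expect_equal(imperv_decay(c(0, 5e3, 1e4), prm0), rep(prm0$imp_base, 3))
  # raster values respect percent bounds
  expect_true(all(L$imperv$values >= 0 & L$imperv$values <= 100))
  # observations fall inside the buffered study region
  obs <- simulate_observations(cfg, list(L))
  expect_true(all(region_contains(L$region, obs$x, obs$y)))
})

test_that("observation counts respect the configured range and seed", {
  cfg <- sim_config(n_cities = 4, n_obs_per_city_range = c(100, 100),
                    city_area_range = c(5000, 20000), seed = 5)
  ls <- lapply(1:4, function(i)
    simulate_landscape(cfg, i, c(i * 1e5, 0), rasters = FALSE))
  obs <- simulate_observations(cfg, ls)
  expect_equal(unname(table(obs$city_id)), rep(100L, 4L),
               ignore_attr = TRUE)
  # seeded determinism: identical point sets on a rerun
  obs2 <- simulate_observations(cfg, ls)
  expect_identical(obs, obs2)
  # counts bounded by n_cities x range
  cfg2 <- sim_config(n_cities = 5, n_obs_per_city_range = c(101, 4731),
                     city_area_range = c(5000, 20000), seed = 6)
  ls2 <- lapply(1:5, function(i)
    simulate_landscape(cfg2, i, c(i * 1e5, 0), rasters = FALSE))
  n2 <- nrow(simulate_observations(cfg2, ls2))
  expect_gte(n2, 5 * 101); expect_lte(n2, 5 * 4731)
})

test_that("melanism outcomes follow the logistic model", {
  cfg <- sim_config(n_cities = 6, n_obs_median = 2000, n_obs_sdlog = 0,
                    city_area_range = c(5000, 40000),
                    beta = rep(0, 8), sigma_city = 0, seed = 41)
  fr <- simulate_frame(cfg)
  n <- nrow(fr)
  # all-zero coefficients: prevalence 1/2 within binomial error
  expect_lt(abs(mean(fr$melanic) - 0.5), 4 * sqrt(0.25 / n))
  # intercept logit(0.1): prevalence about 0.1
  b <- rep(0, 8); b[1] <- qlogis(0.1)
  cfg2 <- sim_config(n_cities = 6, n_obs_median = 2000, n_obs_sdlog = 0,
                     city_area_range = c(5000, 40000),
                     beta = b, sigma_city = 0, seed = 42)
  fr2 <- simulate_frame(cfg2)
  expect_lt(abs(mean(fr2$melanic) - 0.1), 4 * sqrt(0.09 / nrow(fr2)))
  # positive impervious effect: top impervious quartile beats bottom
  b3 <- rep(0, 8); b3[1] <- qlogis(0.2); b3[2] <- 0.8
  cfg3 <- sim_config(n_cities = 6, n_obs_median = 2000, n_obs_sdlog = 0,
                     city_area_range = c(5000, 40000),
                     beta = b3, sigma_city = 0, seed = 43)
  fr3 <- simulate_frame(cfg3)
  q <- quantile(fr3$x_imperv, c(0.25, 0.75))
  expect_gt(mean(fr3$melanic[fr3$x_imperv >= q[2]]),
            mean(fr3$melanic[fr3$x_imperv <= q[1]]))
  # dimension mismatch raises
  bad <- cfg3; bad$beta <- bad$beta[1:5]
  expect_error(simulate_melanism(bad, fr3), "dimension mismatch")
})

test_that("vote records have the configured shape and error behavior", {
  fx <- make_vote_fixture(200, error_rate = 0, seed = 55)
  per_q <- table(fx$votes$image_id, fx$votes$question)
  expect_true(all(per_q == 10L))
  expect_true(all(fx$votes$label[fx$votes$question == "count"] == "one"))
  # error rate 0.5 with threshold 0.8: most images unresolved, and the
  # resolution rate matches exact multinomial enumeration
  fx2 <- make_vote_fixture(2000, error_rate = 0.5, seed = 56)
  rv <- resolve_votes(fx2$votes)
  # count question: correct w.p. 0.5, each wrong label w.p. 0.25;
  # resolution needs a unique mode with >= 8/10 share
  p_resolve <- 0
  for (a in 0:10) for (b in 0:(10 - a)) {
    cnt <- c(a, b, 10 - a - b)
    if (max(cnt) >= 8 && sum(cnt == max(cnt)) == 1)
      p_resolve <- p_resolve +
        dmultinom(cnt, prob = c(0.5, 0.25, 0.25))
  }
  frac <- rv$report$met_count_threshold / rv$report$submitted
  expect_lt(frac, 0.5)
  expect_lt(abs(frac - p_resolve), 4 * sqrt(p_resolve / 2000) + 0.01)
})

test_that("a full synthetic study is internally consistent and reproducible", {
  cfg <- sim_config(n_cities = 3, n_obs_median = 150, n_obs_sdlog = 0.2,
                    city_area_range = c(4000, 15000), seed = 77)
  st <- simulate_study(cfg, rasters = FALSE)
  expect_s3_class(st, "synthetic_study")
  expect_equal(nrow(st$frame), nrow(st$observations))
  expect_true(all(st$observations$color %in% c("gray", "melanic", "other")))
  expect_true(all(st$frame$melanic %in% 0:1))
  # byte-identical rerun under the same config
  st2 <- simulate_study(cfg, rasters = FALSE)
  expect_identical(st$observations, st2$observations)
  expect_identical(st$votes, st2$votes)
})

test_that("fitted city-intercept spread tracks the generative sigma", {
  sds <- c(0.05, 0.5, 1.5, 3)
  est <- vapply(seq_along(sds), function(k) {
    cfg <- sim_config(n_cities = 12, n_obs_median = 400, n_obs_sdlog = 0.1,
                      city_area_range = c(5000, 40000),
                      sigma_city = sds[k], seed = 900 + k)
    fr <- simulate_frame(cfg)
    fit <- fit_melanism_model(fr)
    sd(fit$u)
  }, 0)
  expect_equal(cor(est, sds, method = "spearman"), 1)
})
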