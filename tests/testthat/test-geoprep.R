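test_that("buffer distance is a quarter of the mean cardinal extent", {
  # square of side 2s: each cardinal distance s
  s <- 4000
  sq <- rbind(c(-s, -s), c(s, -s), c(s, s), c(-s, s))
  r <- buffer_city(sq, "sq")
  expect_equal(r$buffer_distance, 0.25 * s)
  expect_equal(r$city_area_ha, (2 * s)^2 / 1e4)

  # 40 km (E-W) x 10 km (N-S) rectangle: mean(5,5,20,20)/4 = 3.125 km
  rect <- rbind(c(0, 0), c(40000, 0), c(40000, 10000), c(0, 10000))
  r2 <- buffer_city(rect, "rect")
  expect_equal(r2$buffer_distance, 3125)

  # irregular convex fixture: buffered polygon strictly contains the
  # footprint and has larger area
  set.seed(2)
  ang <- sort(runif(9, 0, 2 * pi))
  irr <- cbind(5000 * cos(ang), 4000 * sin(ang))
  irr <- irr[grDevices::chull(irr), ]
  r3 <- buffer_city(irr, "irr")
  expect_gt(polygon_area(r3$buffered), polygon_area(r3$footprint))
  expect_true(all(point_in_polygon(irr[, 1], irr[, 2], r3$buffered)))
  expect_error(buffer_city(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("city selection drops small regions and resolves overlaps", {
  sq <- function(cx, cy, h) rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                                  c(cx + h, cy + h), c(cx - h, cy + h))
  rA <- buffer_city(sq(0, 0, 5000), "A")
  rB <- buffer_city(sq(30000, 0, 5000), "B")     # disjoint from A
  rC <- buffer_city(sq(4000, 0, 5000), "C")      # overlaps A
  set.seed(8)
  obs <- data.frame(x = c(runif(500, -4000, 4000),
                          runif(200, 27000, 33000),
                          runif(99, 2000, 6000)),
                    y = c(runif(500, -4000, 4000), runif(200, -3000, 3000),
                          runif(99, -3000, 3000)))
  # threshold: a region with 99 in-range obs of its own is kept only
  # through the shared pool; C overlaps A and has fewer obs -> dropped
  sel <- select_cities(list(rA, rB, rC), obs, min_obs = 100)
  expect_setequal(vapply(sel$regions, `[[`, "", "city_id"), c("A", "B"))
  # every surviving observation is assigned to exactly one region
  expect_true(all(is.na(sel$city_id) | sel$city_id %in% c("A", "B")))
  # two disjoint regions: assignments by containment
  sel2 <- select_cities(list(rA, rB), obs, min_obs = 100)
  expect_equal(sum(sel2$city_id == "B", na.rm = TRUE),
               sum(region_contains(rB, obs$x, obs$y)))
  # dropping below the threshold removes the region
  selC <- select_cities(list(rC), obs[701:799, ], min_obs = 100)
  expect_length(selC$regions, 0L)
})

test_that("thinning returns an independent set matching the exhaustive optimum", {
  # degenerate cases
  expect_equal(thin_points(c(0, 100), c(0, 0), 10), c(1L, 2L))
  expect_length(thin_points(c(0, 5), c(0, 0), 10), 1L)
  set.seed(123)
  for (f in 1:30) {
    n <- sample(8:14, 1)
    x <- runif(n, 0, 40); y <- runif(n, 0, 40)
    keep <- thin_points(x, y, 10, seed = f)
    d <- as.matrix(dist(cbind(x, y)))[keep, keep, drop = FALSE]
    expect_true(all(d[upper.tri(d)] >= 10))
    expect_equal(length(keep), oracle_mis_size(x, y, 10))
  }
})

test_that("region covariate extraction averages over the buffered polygon", {
  sq <- rbind(c(200, 200), c(800, 200), c(800, 800), c(200, 800))
  reg <- buffer_city(sq, "r")
  const <- grid_raster(matrix(42, 120, 120), 0, 0, 10)
  half <- grid_raster(rbind(matrix(0, 50, 120), matrix(100, 70, 120)),
                      0, 0, 10)
  reg <- extract_region_covariates(reg, const, half)
  expect_equal(reg$forest_pct, 42)
  # buffered square centered on x = 500: half/half split
  expect_lt(abs(reg$winter_temp - 50), 1)
})

test_that("model frame rescales within city and standardizes globally", {
  regions <- list(list(city_id = "a", forest_pct = 30, winter_temp = -5,
                       city_area_ha = 50000),
                  list(city_id = "b", forest_pct = 50, winter_temp = 2,
                       city_area_ha = 120000))
  obs <- data.frame(obs_id = sprintf("o%d", 1:6),
                    x = 1:6, y = 1:6,
                    color = c("gray", "melanic", "other",
                              "gray", "melanic", "gray"),
                    city_id = rep(c("a", "b"), each = 3))
  fr <- build_model_frame(obs, regions, imperv = c(10, 20, 30, 5, 5, 45))
  expect_equal(fr$imperv_rescaled[1:3], c(0, 0.5, 1))
  # "other" morphs count as non-melanic
  expect_equal(fr$melanic, c(0, 1, 0, 0, 1, 0))
  for (col in c("x_imperv", "x_temp", "x_forest", "x_logsize")) {
    expect_lt(abs(mean(fr[[col]])), 1e-8)
    expect_lt(abs(sd(fr[[col]]) - 1), 1e-6)
  }
  # rescaling is invariant to affine transforms of the raw scale
  fr2 <- build_model_frame(obs, regions,
                           imperv = 3 * c(10, 20, 30, 5, 5, 45) + 7)
  expect_equal(fr2$imperv_rescaled, fr$imperv_rescaled)
  expect_equal(fr2$x_imperv, fr$x_imperv)
  # constant impervious within a city: rescaled to 0 with a warning
  expect_warning(
    fr3 <- build_model_frame(obs, regions, imperv = c(9, 9, 9, 1, 2, 3)),
    "constant impervious")
  expect_equal(fr3$imperv_rescaled[1:3], c(0, 0, 0))
  # deterministic given inputs
  expect_identical(build_model_frame(obs, regions, c(10, 20, 30, 5, 5, 45)),
                   fr)
})
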