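test_that("consensus_label applies the agreement rule at the boundary", {
  expect_equal(consensus_label(rep("melanic", 10)), "melanic")
  # 8/10 equals the threshold exactly: retained
  expect_equal(consensus_label(c(rep("one", 8), rep("zero", 2))), "one")
  # 7/10 with unclear votes in the denominator: unresolved
  expect_true(is.na(consensus_label(c(rep("gray", 7), rep("unclear", 3)))))
  # below the minimum vote count: unresolved
  expect_true(is.na(consensus_label(rep("gray", 9), min_votes = 10)))
  # tie at the mode: unresolved
  expect_true(is.na(consensus_label(rep(c("gray", "melanic"), 5),
                                    threshold = 0.51)))
  expect_error(consensus_label(character(0)), "empty")
  expect_error(consensus_label("gray", threshold = 0.4), "threshold")
})

test_that("resolve_image handles counts, colors, and multi-morph images", {
  rec <- list(image_id = "a", count_votes = rep("one", 10),
              color_votes = list(rep("melanic", 10)), x = 1, y = 2)
  r <- resolve_image(rec)
  expect_equal(r$stage, "retained")
  expect_equal(nrow(r$observations), 1L)
  expect_equal(r$observations$color, "melanic")

  # two squirrels of different morphs yield two observations
  rec2 <- list(image_id = "b", count_votes = rep("two_or_more", 10),
               color_votes = list(rep("gray", 10), rep("melanic", 10)))
  r2 <- resolve_image(rec2)
  expect_equal(sort(r2$observations$color), c("gray", "melanic"))

  # unresolved count: dropped with the right flag
  rec3 <- list(image_id = "c",
               count_votes = c(rep("one", 6), rep("zero", 4)),
               color_votes = list(rep("gray", 10)))
  expect_equal(resolve_image(rec3)$stage, "failed_count")
  expect_equal(nrow(resolve_image(rec3)$observations), 0L)

  # count zero: dropped
  rec4 <- list(image_id = "d", count_votes = rep("zero", 10),
               color_votes = list())
  expect_equal(resolve_image(rec4)$stage, "count_zero")

  # an image whose only resolvable color is "unclear" is dropped
  rec5 <- list(image_id = "e", count_votes = rep("one", 10),
               color_votes = list(rep("unclear", 10)))
  expect_equal(resolve_image(rec5)$stage, "failed_color")
})

test_that("filter_observations tallies location and range drops", {
  obs <- data.frame(obs_id = sprintf("o%d", 1:100),
                    x = c(rep(NA, 10), runif(90)),
                    y = c(rep(NA, 10), runif(90)),
                    color = "gray", source = "votes",
                    in_native_range = c(rep(TRUE, 50), rep(FALSE, 5),
                                        rep(TRUE, 45)))
  f <- filter_observations(obs)
  expect_equal(f$report$dropped_no_location, 10L)
  expect_equal(f$report$dropped_out_of_range, 5L)
  expect_equal(f$report$final, 85L)
  expect_equal(nrow(f$observations), 85L)
  # all-valid: final equals input
  ok <- obs[11:100, ]; ok$in_native_range <- TRUE
  expect_equal(filter_observations(ok)$report$final, 90L)
})

test_that("merge_sources concatenates and rejects id collisions", {
  a <- data.frame(obs_id = c("v1", "v2", "v3"), x = 1:3, y = 1:3,
                  color = "gray", source = "votes")
  b <- data.frame(obs_id = c("d1", "d2"), x = 4:5, y = 4:5,
                  color = "melanic", source = "direct_report")
  m <- merge_sources(a, b)
  expect_equal(nrow(m), 5L)
  expect_equal(sort(unique(m$source)), c("direct_report", "votes"))
  expect_identical(merge_sources(a, b[0, ]), a)
  b2 <- b; b2$obs_id[1] <- "v2"
  expect_error(merge_sources(a, b2), "duplicate")
})

test_that("zero vote error recovers every true label exactly", {
  fx <- make_vote_fixture(400, error_rate = 0, seed = 31)
  images <- data.frame(image_id = fx$obs$obs_id, x = fx$obs$x,
                       y = fx$obs$y, in_native_range = TRUE)
  rv <- resolve_votes(fx$votes, images)
  expect_equal(nrow(rv$observations), 400L)
  got <- rv$observations$color[match(paste0(fx$obs$obs_id, "/",
                                            fx$obs$color),
                                     rv$observations$obs_id)]
  expect_identical(got, fx$obs$color)
})

test_that("raising the threshold never increases retention", {
  fx <- make_vote_fixture(300, error_rate = 0.25, seed = 77)
  kept <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(th) {
    rv <- resolve_votes(fx$votes, threshold = th)
    nrow(rv$observations)
  }, 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("stage counts are internally consistent and match a brute-force reapplication", {
  fx <- make_vote_fixture(250, error_rate = 0.3, seed = 5)
  images <- data.frame(image_id = fx$obs$obs_id, x = fx$obs$x,
                       y = fx$obs$y, in_native_range = TRUE)
  rv <- resolve_votes(fx$votes, images)
  fl <- filter_observations(rv$observations, rv$report)
  rep <- fl$report
  expect_lte(rep$met_count_threshold, rep$submitted)
  expect_lte(rep$met_color_threshold, rep$met_count_threshold)
  expect_equal(rep$final, rep$resolved_observations -
                 rep$dropped_no_location - rep$dropped_out_of_range)
  # independent oracle: reapply the rules per image from the raw votes
  n_ok <- 0L
  for (id in unique(fx$votes$image_id)) {
    vv <- fx$votes[fx$votes$image_id == id, ]
    cnt <- table(vv$label[vv$question == "count"])
    if (max(cnt) / sum(cnt) < 0.8 || sum(cnt == max(cnt)) > 1) next
    if (names(cnt)[which.max(cnt)] == "zero") next
    col <- table(vv$label[vv$question == "color"])
    if (max(col) / sum(col) < 0.8 || sum(col == max(col)) > 1) next
    if (names(col)[which.max(col)] == "unclear") next
    n_ok <- n_ok + 1L
  }
  expect_equal(rep$final, n_ok)
})
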