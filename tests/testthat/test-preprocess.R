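test_that("percentage-jump rules flag long and short artifacts", {
  rep1 <- detect_artifacts(rr_series(c(800, 800, 1200, 800)))
  expect_equal(rep1$flags, c("clean", "clean", "artifact_long", "clean"))
  expect_equal(rep1$n_flagged, 1L)
  expect_equal(rep1$fraction_flagged, 0.25)

  # 1000 = 1.25 * 800 and 800 = 0.8 * 1000: inside the 30% band, no flags
  rep2 <- detect_artifacts(rr_series(c(800, 1000, 800)))
  expect_equal(rep2$n_flagged, 0L)

  rep3 <- detect_artifacts(rr_series(c(800, 500, 800)))
  expect_equal(rep3$flags[2], "artifact_short")

  expect_equal(detect_artifacts(rr_series(rep(900, 50)))$n_flagged, 0L)
  expect_error(detect_artifacts(rr_series(800)), "at least 2")
})

test_that("the reference is the previous accepted interval, so one ectopic beat does not cascade", {
  # after the short beat at index 2, index 3 is compared against 800 (accepted),
  # not against 500 -- so it stays clean
  rep <- detect_artifacts(rr_series(c(800, 500, 810, 820)))
  expect_equal(rep$flags, c("clean", "artifact_short", "clean", "clean"))
})

test_that("threshold comparisons are strict", {
  # exactly 1.3x and 0.7x the previous interval must NOT be flagged
  rep <- detect_artifacts(rr_series(c(1000, 1300, 910)))
  expect_equal(rep$n_flagged, 0L)
})

test_that("no flags on series whose successive ratios stay inside the band", {
  withr::local_seed(7)
  for (i in 1:20) {
    x <- constrained_walk(300)
    expect_equal(detect_artifacts(rr_series(x))$n_flagged, 0L)
  }
})

test_that("interpolation replaces flagged beats from clean neighbours", {
  rep <- detect_artifacts(rr_series(c(800, 1200, 800)))
  expect_equal(rep$flags[2], "artifact_long")
  fixed <- correct_artifacts(rep)
  expect_equal(fixed$intervals_ms, c(800, 800, 800))
  expect_equal(fixed$labels, c("clean", "corrected", "clean"))

  # zero flags: identity
  clean <- correct_artifacts(detect_artifacts(rr_series(c(800, 820, 810))))
  expect_equal(clean$intervals_ms, c(800, 820, 810))

  # remove policy drops flagged intervals
  removed <- correct_artifacts(detect_artifacts(rr_series(c(800, 1200, 800))),
                               policy = "remove")
  expect_equal(length(removed), 2L)
})

test_that("correction is idempotent and clears the replaced positions", {
  withr::local_seed(11)
  x <- runif(200, 780, 820)
  pos <- c(50, 120)
  x[pos] <- x[pos] / 2
  x[pos + 1] <- x[pos + 1] * 2
  fixed <- correct_artifacts(detect_artifacts(rr_series(x)))
  refl <- detect_artifacts(fixed)
  expect_true(all(refl$flags[c(pos, pos + 1)] == "clean"))
  fixed2 <- correct_artifacts(refl)
  expect_equal(fixed2$intervals_ms, fixed$intervals_ms)
})

test_that("stable-segment selection minimizes the window SD, earliest tie wins", {
  withr::local_seed(3)
  x <- 850 + runif(300, -50, 50)
  x[20:275] <- 850
  sel <- select_stable_segment(rr_series(x), length = 256)
  expect_gte(sel$start_index, 20)
  expect_lte(sel$start_index, 275 - 256 + 1)
  expect_equal(sel$stability_score, 0)
  expect_equal(length(sel$segment), 256L)

  # exactly one candidate window
  sel2 <- select_stable_segment(rr_series(x[1:256]), length = 256)
  expect_equal(sel2$start_index, 1L)

  expect_error(select_stable_segment(rr_series(x[1:100]), length = 256),
               "need 256 intervals, have 100")
})

test_that("stable-segment selection agrees with an exhaustive brute-force scan", {
  withr::local_seed(5)
  for (i in 1:5) {
    x <- 800 + cumsum(rnorm(400, 0, 10))
    x <- pmax(x, 300)
    sel <- select_stable_segment(rr_series(x), length = 64)
    ora <- oracle_stable_window(x, 64)
    expect_equal(sel$start_index, ora$start)
    expect_equal(sel$stability_score, ora$sd, tolerance = 1e-8)
  }
  x <- 900 + cumsum(rnorm(1000, 0, 8))
  x <- pmax(x, 300)
  sel <- select_stable_segment(rr_series(x), length = 256)
  ora <- oracle_stable_window(x, 256)
  expect_equal(sel$start_index, ora$start)
  expect_equal(sel$stability_score, ora$sd, tolerance = 1e-8)
})
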