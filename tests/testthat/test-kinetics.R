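test_that("noiseless on-transient parameters are recovered to 1e-6", {
  f <- fit_on(on_traj(60, 50, 30, 5, 0:300))
  expect_equal(f$baseline_bpm, 60, tolerance = 1e-6)
  expect_equal(f$amplitude_bpm, 50, tolerance = 1e-6)
  expect_equal(f$tau_s, 30, tolerance = 1e-6)
  expect_equal(f$delay_s, 5, tolerance = 1e-6)
  expect_equal(f$r, 1, tolerance = 1e-9)
  expect_true(f$accepted)
})

test_that("noiseless off-transient parameters are recovered to 1e-6", {
  f <- fit_off(off_traj(90, 90, 100, 0, 0:600))
  expect_equal(f$baseline_bpm, 90, tolerance = 1e-6)
  expect_equal(f$amplitude_bpm, 90, tolerance = 1e-6)
  expect_equal(f$tau_s, 100, tolerance = 1e-6)
  expect_equal(f$delay_s, 0, tolerance = 1e-5)
  expect_true(f$accepted)
})

test_that("the off-transient honours the pre-decay plateau", {
  f <- fit_off(off_traj(85, 70, 60, 8, seq(0, 400, by = 0.5)))
  expect_equal(f$delay_s, 8, tolerance = 1e-4)
  expect_equal(f$tau_s, 60, tolerance = 1e-4)
})

test_that("degenerate trajectories are flagged and not accepted", {
  flat_on <- hr_trajectory(0:100, rep(60, 101), "on")
  f <- fit_on(flat_on)
  expect_lt(abs(f$amplitude_bpm), 0.5)
  expect_true(f$degenerate)
  expect_false(f$accepted)

  # a recovery that never decays (flat at peak)
  flat_off <- hr_trajectory(0:100, rep(180, 101), "off")
  f2 <- fit_off(flat_off)
  expect_false(f2$accepted)
})

test_that("phase mismatches are rejected", {
  expect_error(fit_on(off_traj(90, 90, 100, 0, 0:60)), "on-phase")
  expect_error(fit_off(on_traj(60, 50, 30, 5, 0:60)), "off-phase")
})

test_that("a uniform time shift is absorbed into the delay", {
  base <- fit_on(on_traj(60, 50, 30, 5, seq(0, 300)))
  shifted_t <- seq(0, 300)
  y <- ifelse(shifted_t <= 15, 60, 60 + 50 * (1 - exp(-(shifted_t - 15) / 30)))
  sh <- fit_on(hr_trajectory(shifted_t, y, "on"))
  expect_equal(sh$delay_s, base$delay_s + 10, tolerance = 1e-4)
  expect_equal(sh$tau_s, base$tau_s, tolerance = 1e-4)
  expect_equal(sh$amplitude_bpm, base$amplitude_bpm, tolerance = 1e-4)
})

test_that("off-fit asymptote stays below the peak for decaying inputs", {
  withr::local_seed(31)
  for (i in 1:5) {
    ylb <- runif(1, 70, 110)
    a <- runif(1, 40, 110)
    tau <- runif(1, 60, 140)
    tr <- off_traj(ylb, a, tau, 0, 0:420)
    tr$hr_bpm <- pmax(tr$hr_bpm + rnorm(length(tr$hr_bpm), 0, 2), 1)
    f <- fit_off(tr, hr_peak_bpm = ylb + a)
    expect_lt(f$baseline_bpm, f$hr_peak_bpm)
  }
})

test_that("mean tau estimates stay near truth under 3-bpm noise", {
  withr::local_seed(37)
  taus <- replicate(10, {
    tr <- on_traj(60, 50, 30, 5, 0:300)
    tr$hr_bpm <- pmax(tr$hr_bpm + rnorm(301, 0, 3), 1)
    fit_on(tr)$tau_s
  })
  expect_lt(abs(mean(taus) - 30) / 30, 0.10)
})

test_that("tau bias shrinks as noise shrinks", {
  withr::local_seed(41)
  bias <- sapply(c(4, 1, 0.25), function(sdn) {
    taus <- replicate(8, {
      tr <- off_traj(90, 90, 100, 0, 0:600)
      tr$hr_bpm <- pmax(tr$hr_bpm + rnorm(601, 0, sdn), 1)
      fit_off(tr)$tau_s
    })
    abs(mean(taus) - 100)
  })
  expect_lt(bias[3], bias[1] + 0.5)
  expect_lt(bias[3], 0.5)
})

test_that("the printed multiplicative off-form is available and self-consistent", {
  t <- 0:400
  y <- 80 * (0.9 * exp(-t / 90)) + 80
  f <- fit_off(hr_trajectory(t, y, "off"), form = "multiplicative")
  expect_equal(f$baseline_bpm, 80, tolerance = 1e-5)
  expect_equal(f$amplitude_bpm, 0.9, tolerance = 1e-5)
  expect_equal(f$tau_s, 90, tolerance = 1e-5)
})

test_that("fit quality reports the r gate, runs test and confidence band", {
  f <- fit_on(on_traj(60, 50, 30, 5, 0:300))
  q <- fit_quality(f)
  expect_equal(q$r, 1, tolerance = 1e-9)
  expect_true(q$accepted)
  expect_true(all(q$band$upper >= q$band$lower, na.rm = TRUE))

  # the gate tracks r > 0.95 exactly for non-degenerate fits
  withr::local_seed(43)
  seen_reject <- FALSE
  for (sdn in c(1, 10, 25, 45)) {
    tr <- on_traj(60, 50, 30, 5, 0:300)
    tr$hr_bpm <- pmax(tr$hr_bpm + rnorm(301, 0, sdn), 1)
    f <- fit_on(tr)
    if (!f$degenerate && !f$at_tau_bound) {
      expect_identical(f$accepted, f$r > 0.95)
    }
    if (!f$accepted) seen_reject <- TRUE
  }
  expect_true(seen_reject)
})

test_that("white-noise residuals rarely trigger the runs test", {
  withr::local_seed(47)
  p_ok <- replicate(50, {
    tr <- off_traj(90, 90, 100, 0, seq(0, 600, by = 2))
    tr$hr_bpm <- pmax(tr$hr_bpm + rnorm(length(tr$hr_bpm), 0, 3), 1)
    q <- fit_quality(fit_off(tr))
    isTRUE(q$runs_test$p_value > 0.05)
  })
  expect_gte(mean(p_ok), 0.9)
})
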