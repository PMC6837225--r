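test_that("generation is deterministic under a fixed seed", {
  tr <- synthetic_truth(schedule = build_protocol("mict"), seed = 99,
                        artifact_rate = 0.01)
  a <- generate_session(tr)
  b <- generate_session(tr)
  expect_identical(a$series$intervals_ms, b$series$intervals_ms)
  expect_identical(a$artifact_positions, b$artifact_positions)
})

test_that("generated intervals account for the session duration within one beat", {
  tr <- synthetic_truth(schedule = one_stage_schedule(600, 0.8), seed = 5,
                        noise_sd_ms = 0, artifact_rate = 0)
  rec <- generate_session(tr, rest_s = 120, recovery_s = 120)
  total <- sum(rec$series$intervals_ms) / 1000
  expect_lte(rec$phase_marks$end_s - total,
             max(rec$series$intervals_ms) / 1000)
})

test_that("with zero modulation and noise the tachogram is the deterministic HR image", {
  tr <- synthetic_truth(schedule = one_stage_schedule(), hr_rest_bpm = 70,
                        hr_reserve_bpm = 0, lf_amp_ms = 0, hf_amp_ms = 0,
                        noise_sd_ms = 0, seed = 1)
  rec <- generate_session(tr, rest_s = 120, recovery_s = 0)
  expect_true(all(abs(rec$series$intervals_ms - 60000 / 70) < 1e-9))
})

test_that("phase marks line up with the schedule", {
  sch <- build_protocol("hiit-4x3")
  rec <- generate_session(synthetic_truth(schedule = sch, seed = 2),
                          rest_s = 300, recovery_s = 240)
  expect_equal(rec$phase_marks$exercise_onset_s, 300)
  expect_equal(rec$phase_marks$cessation_s, 300 + 1560)
  expect_equal(rec$phase_marks$end_s, 300 + 1560 + 240)
})

test_that("a pure respiratory tone at rest dominates the HF band", {
  tr <- synthetic_truth(schedule = one_stage_schedule(),
                        hr_rest_bpm = 60000 / 900, hr_reserve_bpm = 0,
                        hf_amp_ms = 50, lf_amp_ms = 0, noise_sd_ms = 0,
                        seed = 7)
  rec <- generate_session(tr, rest_s = 300, recovery_s = 0)
  expect_gt(frequency_domain(rec$series)$hf_nu, 95)
})

test_that("the off-transient of a noiseless session is recovered by the fitter", {
  sch <- one_stage_schedule(600, 1)
  tr <- synthetic_truth(schedule = sch, hr_rest_bpm = 70, hr_reserve_bpm = 110,
                        tau_on_s = 30, tau_off_s = 100, ta_on_s = 0,
                        ta_off_s = 0, lf_amp_ms = 0, hf_amp_ms = 0,
                        noise_sd_ms = 0, seed = 3)
  rec <- generate_session(tr, rest_s = 60, recovery_s = 600)
  f <- fit_off(hr_from_rr(rec$series, rec$phase_marks$cessation_s, phase = "off"))
  expect_equal(f$tau_s, 100, tolerance = 0.02)
  f_on <- fit_on(hr_from_rr(rec$series, rec$phase_marks$exercise_onset_s,
                            rec$phase_marks$exercise_onset_s + 300, phase = "on"))
  expect_equal(f_on$tau_s, 30, tolerance = 0.02)
})

test_that("injected artifacts carry the short/long signature and are detectable", {
  tr <- synthetic_truth(schedule = one_stage_schedule(), hr_rest_bpm = 70,
                        hr_reserve_bpm = 0, hf_amp_ms = 20, lf_amp_ms = 15,
                        noise_sd_ms = 3, artifact_rate = 0.02, seed = 11)
  rec <- generate_session(tr, rest_s = 900, recovery_s = 0)
  expect_gt(length(rec$artifact_positions), 10)
  flags <- detect_artifacts(rec$series)$flags
  inj <- sort(c(rec$artifact_positions, rec$artifact_positions + 1L))
  expect_gte(mean(flags[inj] != "clean"), 0.9)
})

test_that("vagal withdrawal attenuates modulation during exercise", {
  sch <- one_stage_schedule(600, 1)
  base <- list(schedule = sch, hr_rest_bpm = 62, hr_reserve_bpm = 110,
               hf_amp_ms = 40, lf_amp_ms = 30, noise_sd_ms = 0, seed = 13)
  with_vw <- generate_session(do.call(synthetic_truth,
                                      c(base, vagal_withdrawal = TRUE)),
                              rest_s = 60, recovery_s = 0)
  without <- generate_session(do.call(synthetic_truth,
                                      c(base, vagal_withdrawal = FALSE)),
                              rest_s = 60, recovery_s = 0)
  late <- function(rec) {
    x <- rec$series
    sd(x$intervals_ms[x$beat_times_s > 400])
  }
  expect_lt(late(with_vw), late(without) / 2)
})

test_that("cohorts are reproducible and validate their inputs", {
  rg <- list(tau_off_s = c(80, 120), hr_rest_bpm = c(55, 70))
  a <- generate_cohort(3, schedule = one_stage_schedule(120, 0.5), ranges = rg,
                       seed = 17, rest_s = 60, recovery_s = 60)
  b <- generate_cohort(3, schedule = one_stage_schedule(120, 0.5), ranges = rg,
                       seed = 17, rest_s = 60, recovery_s = 60)
  expect_identical(lapply(a, function(r) r$series$intervals_ms),
                   lapply(b, function(r) r$series$intervals_ms))
  taus <- vapply(a, function(r) r$truth$tau_off_s, numeric(1))
  expect_true(all(taus >= 80 & taus <= 120))
  expect_gt(max(taus) - min(taus), 0)  # truths actually vary

  expect_error(generate_cohort(0), ">= 1")
  expect_error(generate_cohort(2, ranges = list(tau_off_s = c(120, 80))),
               "hi >= lo")

  # degenerate ranges: identical truths, noise still differs across subjects
  fixed <- generate_cohort(2, schedule = one_stage_schedule(60, 0),
                           ranges = list(tau_off_s = c(100, 100)), seed = 19,
                           rest_s = 120, recovery_s = 0)
  expect_equal(fixed[[1]]$truth$tau_off_s, fixed[[2]]$truth$tau_off_s)
  expect_false(identical(fixed[[1]]$series$intervals_ms,
                         fixed[[2]]$series$intervals_ms))
})
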