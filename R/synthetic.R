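#' Ground-truth parameters for a synthetic RR recording
#'
#' Describes one simulated training session: the protocol schedule, resting
#' HR and HR reserve (stage HR targets are \code{hr_rest + intensity *
#' hr_reserve}), on/off kinetics truth (time constants and delays),
#' sinusoidal autonomic modulation of the RR signal — a Mayer-wave (LF) tone
#' at 0.10 Hz and a respiratory (HF) tone at 0.25 Hz, amplitudes in ms —
#' beat-timing noise, and an artifact-injection rate. Defaults are chosen to
#' sit inside the physiological ranges reported for healthy adults in
#' exercise-HRV studies (resting HR near 60 bpm, on time constants of tens
#' of seconds, off time constants near 100 s, modulation depths of tens of
#' ms at rest).
#'
#' @param schedule a \code{\link{build_protocol}} schedule.
#' @param hr_rest_bpm resting HR, bpm.
#' @param hr_reserve_bpm HR reserve, bpm: a stage at intensity f targets
#'   \code{hr_rest + f * hr_reserve}.
#' @param hr_asymptote_per_stage optional explicit per-stage HR targets, bpm
#'   (overrides the reserve mapping); one per schedule stage.
#' @param tau_on_s,ta_on_s time constant and delay of HR rises, s.
#' @param tau_off_s,ta_off_s time constant and delay of HR falls, s.
#' @param lf_amp_ms,lf_freq_hz Mayer-wave modulation amplitude (ms) and
#'   frequency (Hz, inside 0.04--0.15).
#' @param hf_amp_ms,hf_freq_hz respiratory modulation amplitude (ms) and
#'   frequency (Hz, inside 0.15--0.40).
#' @param noise_sd_ms SD of white beat-to-beat timing noise, ms.
#' @param artifact_rate proportion of beats receiving an injected
#'   halve/double artifact pair.
#' @param vagal_withdrawal if \code{TRUE} (default), modulation amplitude is
#'   attenuated in proportion to the fraction of HR reserve in use, emulating
#'   vagal withdrawal during exercise.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return An object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(schedule = build_protocol("mict"),
                            hr_rest_bpm = 62,
                            hr_reserve_bpm = 110,
                            hr_asymptote_per_stage = NULL,
                            tau_on_s = 36, ta_on_s = 2,
                            tau_off_s = 100, ta_off_s = 5,
                            lf_amp_ms = 30, lf_freq_hz = 0.10,
                            hf_amp_ms = 40, hf_freq_hz = 0.25,
                            noise_sd_ms = 3,
                            artifact_rate = 0,
                            vagal_withdrawal = TRUE,
                            seed = 1L) {
  stopifnot(inherits(schedule, "protocol_schedule"),
            hr_rest_bpm > 0, hr_reserve_bpm >= 0,
            tau_on_s > 0, tau_off_s > 0, ta_on_s >= 0, ta_off_s >= 0,
            lf_amp_ms >= 0, hf_amp_ms >= 0,
            lf_freq_hz >= 0.04, lf_freq_hz < 0.15,
            hf_freq_hz >= 0.15, hf_freq_hz <= 0.40,
            noise_sd_ms >= 0, artifact_rate >= 0, artifact_rate < 0.5)
  if (!is.null(hr_asymptote_per_stage) &&
      length(hr_asymptote_per_stage) != nrow(schedule$stages)) {
    stop("hr_asymptote_per_stage must have one target per schedule stage")
  }
  structure(list(
    schedule = schedule,
    hr_rest_bpm = hr_rest_bpm,
    hr_reserve_bpm = hr_reserve_bpm,
    hr_asymptote_per_stage = hr_asymptote_per_stage,
    tau_on_s = tau_on_s, ta_on_s = ta_on_s,
    tau_off_s = tau_off_s, ta_off_s = ta_off_s,
    lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
    hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
    noise_sd_ms = noise_sd_ms,
    artifact_rate = artifact_rate,
    vagal_withdrawal = vagal_withdrawal,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# piecewise-exponential continuous HR trajectory over the whole session:
# at every stage boundary HR relaxes toward the stage target with the on
# (rise) or off (fall) kinetics, after the corresponding delay
session_hr_fun <- function(truth, rest_s, recovery_s) {
  sch <- truth$schedule
  targets <- if (!is.null(truth$hr_asymptote_per_stage)) {
    truth$hr_asymptote_per_stage
  } else {
    truth$hr_rest_bpm + sch$stages$intensity * truth$hr_reserve_bpm
  }
  seg_t0 <- c(0, rest_s + c(0, cumsum(sch$stages$duration_s)))
  seg_target <- c(truth$hr_rest_bpm, targets, truth$hr_rest_bpm)
  n_seg <- length(seg_target)
  seg_h0 <- numeric(n_seg)
  seg_tau <- numeric(n_seg)
  seg_ta <- numeric(n_seg)
  seg_h0[1] <- truth$hr_rest_bpm
  seg_tau[1] <- truth$tau_on_s
  seg_ta[1] <- 0
  seg_end <- c(seg_t0[-1], seg_t0[n_seg] + recovery_s)
  value_at <- function(i, t) {
    dt <- t - seg_t0[i] - seg_ta[i]
    ifelse(dt <= 0, seg_h0[i],
           seg_target[i] + (seg_h0[i] - seg_target[i]) * exp(-dt / seg_tau[i]))
  }
  for (i in seq.int(2, n_seg)) {
    seg_h0[i] <- value_at(i - 1, seg_t0[i])
    rising <- seg_target[i] > seg_h0[i]
    seg_tau[i] <- if (rising) truth$tau_on_s else truth$tau_off_s
    seg_ta[i] <- if (rising) truth$ta_on_s else truth$ta_off_s
  }
  total_s <- seg_end[n_seg]
  fun <- function(t) {
    i <- findInterval(t, seg_t0, rightmost.closed = FALSE)
    i[i < 1] <- 1
    i[i > n_seg] <- n_seg
    dt <- t - seg_t0[i] - seg_ta[i]
    ifelse(dt <= 0, seg_h0[i],
           seg_target[i] + (seg_h0[i] - seg_target[i]) * exp(-dt / seg_tau[i]))
  }
  list(fun = fun, total_s = total_s)
}

#' Generate a synthetic full-session RR recording
#'
#' Builds a continuous instantaneous-HR trajectory (rest plateau, exponential
#' relaxation toward each stage's HR target with the on/off kinetics truth,
#' exponential recovery back to rest), converts it to instantaneous RR
#' (\code{60000 / HR}), adds LF and HF sinusoidal modulation and white noise
#' in the RR (ms) domain, and emits discrete beats by integrate-and-fire:
#' the next beat falls one current-RR after the previous one. Optionally
#' injects artifacts by halving one interval and doubling the next (the
#' short-then-long signature of a noise-split beat), at randomly chosen,
#' non-adjacent positions. Deterministic under the truth's seed.
#'
#' @param truth a \code{\link{synthetic_truth}}.
#' @param rest_s pre-exercise rest duration, s (default 300).
#' @param recovery_s post-exercise recovery duration, s (default 240).
#' @return An object of class \code{"synthetic_recording"}: list with
#'   \code{series} (an \code{\link{rr_series}}), \code{truth},
#'   \code{phase_marks} (list: \code{exercise_onset_s},
#'   \code{cessation_s}, \code{end_s}) and \code{artifact_positions}
#'   (indices of injected short intervals; the paired long interval is the
#'   next index).
#' @export
generate_session <- function(truth, rest_s = 300, recovery_s = 240) {
  stopifnot(inherits(truth, "synthetic_truth"), rest_s >= 0, recovery_s >= 0)
  hrf <- session_hr_fun(truth, rest_s, recovery_s)
  if (any(hrf$fun(seq(0, hrf$total_s, by = 1)) <= 0)) {
    stop("HR targets imply non-positive heart rate")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(truth$seed)
  total_s <- hrf$total_s
  # integrate-and-fire beat emission
  n_guess <- ceiling(total_s * 4) + 16
  intervals <- numeric(n_guess)
  nb <- 0L
  t <- 0
  repeat {
    hr <- hrf$fun(t)
    rr <- 60000 / hr
    if (truth$lf_amp_ms > 0 || truth$hf_amp_ms > 0) {
      atten <- 1
      if (truth$vagal_withdrawal && truth$hr_reserve_bpm > 0) {
        frac <- (hr - truth$hr_rest_bpm) / truth$hr_reserve_bpm
        atten <- min(1, max(0.05, 1 - frac))
      }
      rr <- rr +
        atten * truth$lf_amp_ms * sin(2 * pi * truth$lf_freq_hz * t) +
        atten * truth$hf_amp_ms * sin(2 * pi * truth$hf_freq_hz * t)
    }
    if (truth$noise_sd_ms > 0) rr <- rr + stats::rnorm(1, 0, truth$noise_sd_ms)
    rr <- max(rr, 200)  # physiological floor keeps intervals positive
    if (t + rr / 1000 > total_s) break
    nb <- nb + 1L
    if (nb > length(intervals)) intervals <- c(intervals, numeric(n_guess))
    intervals[nb] <- rr
    t <- t + rr / 1000
  }
  intervals <- intervals[seq_len(nb)]
  artifact_positions <- integer(0)
  if (truth$artifact_rate > 0 && nb >= 4) {
    n_art <- round(truth$artifact_rate * nb)
    if (n_art > 0) {
      cand <- sample(seq.int(2L, nb - 1L))
      for (k in cand) {
        if (length(artifact_positions) >= n_art) break
        # keep injected pairs disjoint and non-adjacent
        if (!any(abs(artifact_positions - k) <= 2L)) {
          artifact_positions <- c(artifact_positions, k)
        }
      }
      artifact_positions <- sort(artifact_positions)
      intervals[artifact_positions] <- intervals[artifact_positions] / 2
      intervals[artifact_positions + 1L] <- intervals[artifact_positions + 1L] * 2
    }
  }
  series <- rr_series(intervals, meta = list(
    source = "synthetic", protocol = truth$schedule$name, seed = truth$seed))
  structure(list(
    series = series,
    truth = truth,
    phase_marks = list(
      exercise_onset_s = rest_s,
      cessation_s = rest_s + truth$schedule$total_time_s,
      end_s = total_s
    ),
    artifact_positions = artifact_positions
  ), class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("Synthetic session (%s, seed %d): %d beats, %.0f s\n",
              x$truth$schedule$name, x$truth$seed, length(x$series),
              x$phase_marks$end_s))
  invisible(x)
}

#' Generate a cohort of synthetic recordings
#'
#' Draws \code{n} subjects' truth parameters from uniform ranges and
#' generates one session per subject. Each subject's generator seed is
#' derived deterministically from \code{seed}, so the whole cohort is
#' reproducible.
#'
#' @param n number of subjects (>= 1).
#' @param schedule a \code{\link{build_protocol}} schedule shared by the
#'   cohort.
#' @param ranges named list of \code{c(lo, hi)} ranges for any of the
#'   numeric \code{\link{synthetic_truth}} parameters (e.g.
#'   \code{list(tau_off_s = c(80, 120), hr_rest_bpm = c(55, 70))});
#'   parameters not listed keep their defaults. A degenerate range
#'   \code{c(v, v)} fixes the parameter.
#' @param seed integer cohort seed.
#' @param rest_s,recovery_s phase durations passed to
#'   \code{\link{generate_session}}.
#' @param ... further fixed arguments for \code{\link{synthetic_truth}}.
#' @return List of \code{\link{generate_session}} recordings, length \code{n}.
#' @export
generate_cohort <- function(n, schedule = build_protocol("mict"),
                            ranges = list(), seed = 1L,
                            rest_s = 300, recovery_s = 240, ...) {
  if (!is.numeric(n) || n < 1) stop("cohort size n must be >= 1")
  n <- as.integer(n)
  if (length(ranges) > 0) {
    ok <- vapply(ranges, function(r) length(r) == 2 && r[2] >= r[1], logical(1))
    if (!all(ok)) stop("each range must be c(lo, hi) with hi >= lo")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  subject_seeds <- sample.int(2^30, n)
  draws <- lapply(seq_len(n), function(i) {
    vals <- lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
    vals
  })
  lapply(seq_len(n), function(i) {
    args <- c(list(schedule = schedule, seed = subject_seeds[i]), draws[[i]],
              list(...))
    truth <- do.call(synthetic_truth, args)
    generate_session(truth, rest_s = rest_s, recovery_s = recovery_s)
  })
}
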