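# time-weighted (trapezoidal) mean of a sampled trajectory over [lo, hi],
# with linearly interpolated values at the window edges
window_mean <- function(time_s, hr_bpm, lo, hi) {
  if (lo < time_s[1] - 1e-9 || hi > time_s[length(time_s)] + 1e-9) {
    return(NA_real_)
  }
  inside <- time_s > lo & time_s < hi
  t <- c(lo, time_s[inside], hi)
  v <- c(stats::approx(time_s, hr_bpm, xout = lo, rule = 2)$y,
         hr_bpm[inside],
         stats::approx(time_s, hr_bpm, xout = hi, rule = 2)$y)
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) / (hi - lo)
}

#' Heart-rate recovery delta profile
#'
#' At each recovery landmark x in \{0, 30, 60, 90, 120, 150, 180\} s after
#' exercise cessation, the delta is the mean HR in a 10-s window centred on
#' the landmark (5 s before and after) minus the peak exercise HR:
#' \deqn{\Delta(x) = \bar{HR}_{[x-5, x+5]} - HR_{peak}.}
#' Negative deltas mean HR has fallen below the peak; the larger
#' \eqn{|\Delta|}, the faster the recovery. Landmark 0 uses the window
#' [0, 5] s only, so no pre-cessation (exercise) beats contaminate it.
#' Window means are time-weighted (trapezoidal over the sampled trajectory
#' with interpolated window edges), so unevenly spaced beat samples do not
#' bias them. Landmarks whose window extends past the available data are
#' reported as missing.
#'
#' @param trajectory an \code{\link{hr_trajectory}} with \code{phase = "off"}
#'   and \code{t = 0} at exercise cessation; should cover at least 185 s for
#'   a complete profile (a partial profile is returned with a warning if it
#'   covers at least 35 s).
#' @param hr_peak_bpm peak exercise HR, conventionally the mean HR over the
#'   final 5 s of exercise (see \code{\link{hr_peak_from_rr}}).
#' @param landmarks_s landmark times, s (default 0 to 180 every 30).
#' @param window_halfwidth_s half-width of the averaging window, s (default 5).
#' @return An object of class \code{"delta_profile"}: list with
#'   \code{hr_peak_bpm}, \code{landmarks_s}, \code{deltas_bpm} (named,
#'   \code{NA} where data ran out), \code{window_means_bpm} and
#'   \code{window_halfwidth_s}.
#' @export
delta_profile <- function(trajectory, hr_peak_bpm,
                          landmarks_s = seq(0, 180, by = 30),
                          window_halfwidth_s = 5) {
  stopifnot(inherits(trajectory, "hr_trajectory"))
  if (trajectory$phase != "off") stop("delta analysis requires an off-phase trajectory")
  stopifnot(is.numeric(hr_peak_bpm), length(hr_peak_bpm) == 1,
            is.finite(hr_peak_bpm), hr_peak_bpm > 0)
  t <- trajectory$time_s
  span <- t[length(t)]
  if (span < 35) {
    stop(sprintf("recovery trajectory covers only %.1f s; at least 35 s needed", span))
  }
  if (span < max(landmarks_s) + window_halfwidth_s) {
    warning(sprintf(
      "recovery covers %.1f s; landmarks beyond it are reported as missing", span))
  }
  w <- window_halfwidth_s
  means <- vapply(landmarks_s, function(x) {
    lo <- if (x == 0) 0 else x - w  # landmark 0: post-cessation data only
    hi <- x + w
    # beat-sampled recoveries cannot start exactly at 0; clamp the window
    # start to the first sample when it lies inside the window
    lo <- max(lo, 0)
    if (t[1] > lo && t[1] < hi - w / 2) lo <- t[1]
    window_mean(t, trajectory$hr_bpm, lo, hi)
  }, numeric(1))
  deltas <- means - hr_peak_bpm
  names(deltas) <- names(means) <- paste0("delta_", landmarks_s)
  structure(list(
    hr_peak_bpm = hr_peak_bpm,
    landmarks_s = landmarks_s,
    deltas_bpm = deltas,
    window_means_bpm = means,
    window_halfwidth_s = w
  ), class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("HR recovery deltas (peak %.1f bpm):\n", x$hr_peak_bpm))
  for (i in seq_along(x$landmarks_s)) {
    cat(sprintf("  t = %3d s: %s bpm\n", x$landmarks_s[i],
                if (is.na(x$deltas_bpm[i])) "missing"
                else sprintf("%+.1f", x$deltas_bpm[i])))
  }
  invisible(x)
}

#' Peak exercise HR from an RR series
#'
#' Mean HR over the final \code{window_s} seconds of exercise (the window
#' ending at \code{cessation_s}), time-weighted over the beats it contains —
#' symmetric with the landmark windows of \code{\link{delta_profile}}.
#'
#' @param series an \code{\link{rr_series}}.
#' @param cessation_s time of exercise cessation, s from recording start.
#' @param window_s averaging window length before cessation, s (default 5).
#' @return Peak HR, bpm.
#' @export
hr_peak_from_rr <- function(series, cessation_s, window_s = 5) {
  stopifnot(inherits(series, "rr_series"))
  t <- series$beat_times_s
  hr <- rri_to_hr(series$intervals_ms)
  keep <- t >= cessation_s - window_s - 30 & t <= cessation_s + 1
  if (sum(keep) < 2) stop("no beats in the peak-HR window before cessation")
  window_mean(t[keep], hr[keep], cessation_s - window_s, cessation_s)
}

#' First-minute heart-rate-recovery summary
#'
#' Reports the magnitude of the 60-s delta and flags whether it reaches the
#' commonly cited healthy first-minute benchmark of a 30-bpm fall
#' (inclusive: \eqn{|\Delta(60)| \ge 30}).
#'
#' @param profile a \code{\link{delta_profile}} with \code{delta_60} present.
#' @return List with \code{delta60_bpm}, \code{abs_delta60_bpm} and
#'   \code{meets_30bpm_benchmark}.
#' @export
hrr_classification <- function(profile) {
  stopifnot(inherits(profile, "delta_profile"))
  d60 <- profile$deltas_bpm[["delta_60"]]
  if (is.na(d60)) stop("delta at 60 s is missing; cannot classify recovery")
  list(
    delta60_bpm = d60,
    abs_delta60_bpm = abs(d60),
    meets_30bpm_benchmark = abs(d60) >= 30
  )
}
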