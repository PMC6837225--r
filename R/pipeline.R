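# extract the sub-series of intervals whose closing beats fall in (lo_s, hi_s]
rr_window <- function(series, lo_s, hi_s) {
  keep <- series$beat_times_s > lo_s & series$beat_times_s <= hi_s
  meta <- series$meta
  meta$window_s <- c(lo_s, hi_s)
  rr_series(series$intervals_ms[keep],
            labels = if (is.null(series$labels)) NULL else series$labels[keep],
            meta = meta)
}

#' Analysis settings for a session run
#'
#' @param artifact_threshold relative jump that flags an artifact (default
#'   0.30; see \code{\link{detect_artifacts}}).
#' @param artifact_policy \code{"interpolate"} or \code{"remove"}.
#' @param segment_beats stable-segment length for HRV, beats (default 256).
#' @param spectral a \code{\link{spectral_settings}} list.
#' @param on_window_s length of the window after exercise onset used for the
#'   on-transient fit, s (default 300: the warm-up stage, several on time
#'   constants long).
#' @return Named list of settings.
#' @export
session_settings <- function(artifact_threshold = 0.30,
                             artifact_policy = "interpolate",
                             segment_beats = 256,
                             spectral = spectral_settings(),
                             on_window_s = 300) {
  list(artifact_threshold = artifact_threshold,
       artifact_policy = artifact_policy,
       segment_beats = as.integer(segment_beats),
       spectral = spectral,
       on_window_s = on_window_s)
}

run_stage <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = conditionMessage(e)))
}

#' Run the full per-recording analysis
#'
#' Orchestrates, for one RR recording with known phase marks:
#' per-phase artifact detection and correction; rest HRV (time and frequency
#' domain) on the most stable 256-beat rest segment; the on-transient
#' kinetics fit from exercise onset; peak HR from the final 5 s of exercise;
#' the off-transient fit, recovery delta profile and post-exercise HRV from
#' cessation. Stages that cannot run on the given data (e.g. a recording cut
#' short) are reported with their error instead of aborting the whole
#' session.
#'
#' @param rr an \code{\link{rr_series}} for the whole recording.
#' @param schedule the session's \code{\link{build_protocol}} schedule
#'   (carried into provenance; phase boundaries come from \code{marks}).
#' @param marks list with \code{exercise_onset_s}, \code{cessation_s} and
#'   optionally \code{end_s} (default: end of recording), seconds from
#'   recording start. Rest is everything before onset and should be at least
#'   3 min; recovery is everything after cessation and should be at least
#'   4 min.
#' @param settings a \code{\link{session_settings}} list.
#' @param subject_id identifier carried into summaries.
#' @return An object of class \code{"session_result"}: list with
#'   \code{subject_id}, \code{protocol}, per-stage results
#'   (\code{rest_time}, \code{rest_spectral}, \code{kinetics_on},
#'   \code{hr_peak_bpm}, \code{kinetics_off}, \code{deltas},
#'   \code{post_time}, \code{post_spectral}), a per-stage \code{status}
#'   table and \code{provenance}.
#' @export
run_session <- function(rr, schedule, marks, settings = session_settings(),
                        subject_id = "S1") {
  stopifnot(inherits(rr, "rr_series"), inherits(schedule, "protocol_schedule"))
  stopifnot(!is.null(marks$exercise_onset_s), !is.null(marks$cessation_s))
  onset <- marks$exercise_onset_s
  cess <- marks$cessation_s
  end_s <- if (!is.null(marks$end_s)) marks$end_s else
    rr$beat_times_s[length(rr$intervals_ms)]
  if (!(0 < onset && onset < cess && cess <= end_s)) {
    stop("phase marks must satisfy 0 < onset < cessation <= end")
  }
  clean_phase <- function(lo, hi) {
    w <- rr_window(rr, lo, hi)
    correct_artifacts(detect_artifacts(w, settings$artifact_threshold),
                      settings$artifact_policy)
  }
  rest <- run_stage(clean_phase(0, onset))
  exercise <- run_stage(clean_phase(onset, cess))
  recovery <- run_stage(clean_phase(cess, end_s))

  stable_hrv <- function(phase) {
    seg <- select_stable_segment(phase, settings$segment_beats)$segment
    list(time = time_domain(seg),
         spectral = frequency_domain(seg, settings$spectral))
  }
  rest_hrv <- run_stage(if (rest$ok) stable_hrv(rest$value) else
    stop(rest$error))
  post_hrv <- run_stage(if (recovery$ok) stable_hrv(recovery$value) else
    stop(recovery$error))

  # kinetics on the artifact-corrected full series rebuilt from phases
  corrected <- run_stage({
    parts <- list(rest, exercise, recovery)
    if (!all(vapply(parts, `[[`, logical(1), "ok"))) {
      stop("a preprocessing stage failed")
    }
    rr_series(c(rest$value$intervals_ms, exercise$value$intervals_ms,
                recovery$value$intervals_ms), meta = rr$meta)
  })
  on_fit <- run_stage({
    if (!corrected$ok) stop(corrected$error)
    fit_on(hr_from_rr(corrected$value, onset,
                      min(onset + settings$on_window_s, cess), phase = "on"))
  })
  hr_peak <- run_stage({
    if (!corrected$ok) stop(corrected$error)
    hr_peak_from_rr(corrected$value, cess)
  })
  off_traj <- run_stage({
    if (!corrected$ok) stop(corrected$error)
    hr_from_rr(corrected$value, cess, end_s, phase = "off")
  })
  off_fit <- run_stage({
    if (!off_traj$ok) stop(off_traj$error)
    fit_off(off_traj$value,
            hr_peak_bpm = if (hr_peak$ok) hr_peak$value else NA_real_)
  })
  deltas <- run_stage({
    if (!off_traj$ok) stop(off_traj$error)
    if (!hr_peak$ok) stop(hr_peak$error)
    delta_profile(off_traj$value, hr_peak$value)
  })

  stages <- list(rest_preprocess = rest, exercise_preprocess = exercise,
                 recovery_preprocess = recovery, rest_hrv = rest_hrv,
                 kinetics_on = on_fit, hr_peak = hr_peak,
                 kinetics_off = off_fit, deltas = deltas,
                 post_hrv = post_hrv)
  status <- data.frame(
    stage = names(stages),
    ok = vapply(stages, `[[`, logical(1), "ok"),
    error = vapply(stages, function(s)
      if (is.null(s$error)) "" else s$error, character(1)),
    row.names = NULL
  )
  structure(list(
    subject_id = subject_id,
    protocol = schedule$name,
    rest_time = if (rest_hrv$ok) rest_hrv$value$time else NULL,
    rest_spectral = if (rest_hrv$ok) rest_hrv$value$spectral else NULL,
    kinetics_on = on_fit$value,
    hr_peak_bpm = if (hr_peak$ok) hr_peak$value else NA_real_,
    kinetics_off = off_fit$value,
    deltas = deltas$value,
    post_time = if (post_hrv$ok) post_hrv$value$time else NULL,
    post_spectral = if (post_hrv$ok) post_hrv$value$spectral else NULL,
    status = status,
    provenance = list(settings = settings, marks = marks,
                      schedule = schedule$name,
                      n_beats = length(rr$intervals_ms),
                      meta = rr$meta,
                      package_version = as.character(
                        utils::packageVersion("hrvkinetics")))
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session result: subject %s, protocol %s\n",
              x$subject_id, x$protocol))
  bad <- x$status[!x$status$ok, ]
  if (nrow(bad) == 0) {
    cat("  all stages complete\n")
  } else {
    for (i in seq_len(nrow(bad))) {
      cat("  stage", bad$stage[i], "failed:", bad$error[i], "\n")
    }
  }
  invisible(x)
}

session_metrics <- function(res) {
  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  out <- c(
    rest_sdnn_ms = num(res$rest_time$sdnn_ms),
    rest_rmssd_ms = num(res$rest_time$rmssd_ms),
    rest_pnn50_pct = num(res$rest_time$pnn50_pct),
    rest_lf_nu = num(res$rest_spectral$lf_nu),
    rest_hf_nu = num(res$rest_spectral$hf_nu),
    rest_lf_hf = num(res$rest_spectral$lf_hf_ratio),
    on_amplitude_bpm = num(res$kinetics_on$amplitude_bpm),
    on_tau_s = num(res$kinetics_on$tau_s),
    hr_peak_bpm = num(res$hr_peak_bpm),
    off_amplitude_bpm = num(res$kinetics_off$amplitude_bpm),
    off_tau_s = num(res$kinetics_off$tau_s),
    post_sdnn_ms = num(res$post_time$sdnn_ms),
    post_rmssd_ms = num(res$post_time$rmssd_ms),
    post_lf_nu = num(res$post_spectral$lf_nu),
    post_hf_nu = num(res$post_spectral$hf_nu)
  )
  if (!is.null(res$deltas)) {
    d <- res$deltas$deltas_bpm
    names(d) <- paste0(names(d), "_bpm")
    out <- c(out, d)
  }
  out
}

metric_units <- function(metric) {
  ifelse(grepl("_ms$", metric), "ms",
    ifelse(grepl("_bpm$", metric), "bpm",
      ifelse(grepl("_pct$", metric), "%",
        ifelse(grepl("_nu$", metric), "nu",
          ifelse(grepl("_s$", metric), "s", "")))))
}

#' Summarize a cohort of session results
#'
#' Long-format tidy table — one row per (subject, protocol, metric) — with
#' per-protocol mean and SD rows appended (pseudo-subjects \code{"mean"} and
#' \code{"sd"}; SD rows are omitted for protocols with a single subject).
#' The table feeds any downstream statistics package directly.
#'
#' @param results list of \code{\link{run_session}} results (length >= 1).
#' @return A data frame with columns \code{subject}, \code{protocol},
#'   \code{metric}, \code{value}, \code{units}.
#' @export
summarize_cohort <- function(results) {
  if (length(results) == 0) stop("summarize_cohort needs at least one result")
  stopifnot(all(vapply(results, inherits, logical(1), "session_result")))
  rows <- do.call(rbind, lapply(results, function(res) {
    m <- session_metrics(res)
    data.frame(subject = res$subject_id, protocol = res$protocol,
               metric = names(m), value = as.numeric(m),
               units = metric_units(names(m)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  agg <- do.call(rbind, lapply(split(rows, rows[c("protocol", "metric")]),
    function(g) {
      if (nrow(g) == 0) return(NULL)
      out <- data.frame(subject = "mean", protocol = g$protocol[1],
                        metric = g$metric[1],
                        value = mean(g$value, na.rm = TRUE),
                        units = g$units[1], stringsAsFactors = FALSE)
      if (nrow(g) > 1) {
        out <- rbind(out, data.frame(subject = "sd", protocol = g$protocol[1],
                                     metric = g$metric[1],
                                     value = stats::sd(g$value, na.rm = TRUE),
                                     units = g$units[1],
                                     stringsAsFactors = FALSE))
      }
      out
    }))
  out <- rbind(rows, agg)
  rownames(out) <- NULL
  out
}
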