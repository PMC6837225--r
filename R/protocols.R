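#' Build a training-protocol schedule
#'
#' A schedule is a piecewise-constant intensity timeline: ordered stages of
#' (duration, intensity as a fraction of the workload at maximal oxygen
#' uptake, kind). Three presets are provided, all sharing a 5-min warm-up at
#' 55\% and a 3-min cool-down at 50\%:
#' \describe{
#'   \item{\code{"hiit-4x3"}}{3 x 4 min at 90\% interleaved with 2 x 3 min
#'     active recovery at 60\% (work, recovery, work, recovery, work);
#'     26 min total.}
#'   \item{\code{"hiit-30-30"}}{29 x (30 s at 100\% + 30 s passive at 0\%);
#'     37 min total.}
#'   \item{\code{"mict"}}{21 min continuous at 70\%; 29 min stage sum.}
#' }
#' Custom schedules pass \code{stages} directly.
#'
#' @param name one of \code{"hiit-4x3"}, \code{"hiit-30-30"}, \code{"mict"},
#'   or \code{"custom"} with \code{stages} supplied.
#' @param stages for \code{"custom"}: data frame with columns
#'   \code{duration_s} (> 0), \code{intensity} (fraction of the reference
#'   workload, >= 0; 0 = passive) and \code{kind} (one of \code{"warmup"},
#'   \code{"work"}, \code{"recovery"}, \code{"cooldown"}).
#' @param wl_vo2max_kmh optional reference treadmill speed (the workload at
#'   maximal oxygen uptake), km/h.
#' @return An object of class \code{"protocol_schedule"}: list with
#'   \code{name}, \code{stages} (data frame), \code{total_time_s} and
#'   \code{wl_vo2max_kmh}.
#' @examples
#' build_protocol("hiit-4x3")$total_time_s / 60  # 26
#' @export
build_protocol <- function(name = c("hiit-4x3", "hiit-30-30", "mict", "custom"),
                           stages = NULL, wl_vo2max_kmh = NULL) {
  name <- match.arg(name)
  st <- function(duration_s, intensity, kind) {
    data.frame(duration_s = duration_s, intensity = intensity, kind = kind,
               stringsAsFactors = FALSE)
  }
  warmup <- st(300, 0.55, "warmup")
  cooldown <- st(180, 0.50, "cooldown")
  stages <- switch(name,
    "hiit-4x3" = rbind(
      warmup,
      st(240, 0.90, "work"), st(180, 0.60, "recovery"),
      st(240, 0.90, "work"), st(180, 0.60, "recovery"),
      st(240, 0.90, "work"),
      cooldown),
    "hiit-30-30" = rbind(
      warmup,
      do.call(rbind, rep(list(rbind(st(30, 1.00, "work"),
                                    st(30, 0.00, "recovery"))), 29)),
      cooldown),
    "mict" = rbind(warmup, st(1260, 0.70, "work"), cooldown),
    "custom" = {
      if (is.null(stages)) stop("custom protocol requires a stages data frame")
      need <- c("duration_s", "intensity", "kind")
      if (!all(need %in% names(stages))) {
        stop("stages must have columns: ", paste(need, collapse = ", "))
      }
      if (any(stages$duration_s <= 0)) stop("stage durations must be > 0")
      if (any(stages$intensity < 0)) stop("stage intensities must be >= 0")
      bad <- setdiff(stages$kind, c("warmup", "work", "recovery", "cooldown"))
      if (length(bad)) stop("unknown stage kind: ", bad[1])
      stages
    })
  rownames(stages) <- NULL
  structure(list(
    name = name,
    stages = stages,
    total_time_s = sum(stages$duration_s),
    wl_vo2max_kmh = wl_vo2max_kmh
  ), class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("Protocol %s: %d stages, %.0f min total\n",
              x$name, nrow(x$stages), x$total_time_s / 60))
  invisible(x)
}

#' Total distance covered over a schedule
#'
#' Distance is the sum over stages of duration x speed, where each stage's
#' speed is its intensity fraction times the reference speed. Passive stages
#' (intensity 0) contribute nothing. Linear in the reference speed and
#' additive over stages.
#'
#' @param schedule a \code{\link{build_protocol}} schedule.
#' @param wl_vo2max_kmh reference treadmill speed, km/h; falls back to the
#'   schedule's own \code{wl_vo2max_kmh}.
#' @return Distance in metres.
#' @examples
#' total_distance(build_protocol("mict"), wl_vo2max_kmh = 10)
#' @export
total_distance <- function(schedule, wl_vo2max_kmh = schedule$wl_vo2max_kmh) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  if (is.null(wl_vo2max_kmh)) stop("a reference speed (km/h) is required")
  stopifnot(wl_vo2max_kmh >= 0)
  sum(schedule$stages$duration_s / 3600 * schedule$stages$intensity) *
    wl_vo2max_kmh * 1000
}

# intensity fraction at a given time into the session (piecewise constant,
# right-open stages); used by the synthetic generator
intensity_at <- function(schedule, t_s) {
  ends <- cumsum(schedule$stages$duration_s)
  i <- findInterval(t_s, c(0, ends), rightmost.closed = FALSE)
  i[i > nrow(schedule$stages)] <- nrow(schedule$stages)
  i[i < 1] <- 1
  schedule$stages$intensity[i]
}
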