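#' Detect RR artifacts by percentage-jump rules
#'
#' Two rules, applied beat by beat from the second interval on:
#' an interval more than \code{threshold} (default 30\%) *longer* than the
#' previous accepted interval is flagged \code{artifact_long} (a missed beat),
#' and one more than \code{threshold} *shorter* is flagged
#' \code{artifact_short} (noise read as an extra beat). Comparisons are strict
#' inequalities. The reference is the previous *accepted* (unflagged)
#' interval, so a single ectopic beat does not cascade flags down the series.
#' The first interval is always accepted.
#'
#' @param series an \code{\link{rr_series}} with at least 2 intervals.
#' @param threshold relative deviation that triggers a flag, as a proportion
#'   (default 0.30).
#' @return An object of class \code{"artifact_report"}: list with
#'   \code{flags} (character per beat), \code{n_flagged},
#'   \code{fraction_flagged}, \code{threshold} and the input \code{series}.
#' @examples
#' rr <- rr_series(c(800, 800, 1200, 800))
#' detect_artifacts(rr)$flags  # beat 3 is artifact_long
#' @export
detect_artifacts <- function(series, threshold = 0.30) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals_ms
  n <- length(x)
  if (n < 2) stop("artifact detection needs at least 2 intervals, got ", n)
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  flags <- rep("clean", n)
  ref <- x[1]
  for (k in 2:n) {
    if (x[k] > (1 + threshold) * ref) {
      flags[k] <- "artifact_long"
    } else if (x[k] < (1 - threshold) * ref) {
      flags[k] <- "artifact_short"
    } else {
      ref <- x[k]
    }
  }
  n_flagged <- sum(flags != "clean")
  structure(list(
    flags = flags,
    n_flagged = n_flagged,
    fraction_flagged = n_flagged / n,
    threshold = threshold,
    series = series
  ), class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("Artifact report: %d/%d beats flagged (%.2f%%) at threshold %.0f%%\n",
              x$n_flagged, length(x$flags), 100 * x$fraction_flagged,
              100 * x$threshold))
  invisible(x)
}

#' Correct flagged RR artifacts
#'
#' Default policy \code{"interpolate"} replaces each flagged interval by
#' linear interpolation between its nearest clean neighbours, preserving beat
#' count and (approximately) recording duration — the property the spectral
#' resampler needs. Policy \code{"remove"} drops flagged intervals and
#' recomputes beat times, shortening the series.
#'
#' @param report an \code{"artifact_report"} from
#'   \code{\link{detect_artifacts}}.
#' @param policy \code{"interpolate"} (default) or \code{"remove"}.
#' @return An \code{\link{rr_series}} with \code{labels} recording which beats
#'   were corrected (\code{"corrected"}) under the interpolate policy.
#' @export
correct_artifacts <- function(report, policy = c("interpolate", "remove")) {
  stopifnot(inherits(report, "artifact_report"))
  policy <- match.arg(policy)
  x <- report$series$intervals_ms
  flagged <- report$flags != "clean"
  meta <- report$series$meta
  meta$artifact_policy <- policy
  meta$n_corrected <- sum(flagged)
  if (!any(flagged)) {
    return(rr_series(x, labels = rep("clean", length(x)), meta = meta))
  }
  if (all(flagged)) stop("all beats flagged; nothing to anchor correction")
  if (policy == "remove") {
    return(rr_series(x[!flagged], labels = rep("clean", sum(!flagged)),
                     meta = meta))
  }
  idx <- seq_along(x)
  clean_idx <- idx[!flagged]
  # linear interpolation over beat index between nearest clean neighbours;
  # flagged beats outside the clean range take the nearest clean value
  fixed <- stats::approx(clean_idx, x[clean_idx], xout = idx[flagged],
                         rule = 2)$y
  x[flagged] <- fixed
  labels <- ifelse(flagged, "corrected", "clean")
  rr_series(x, labels = labels, meta = meta)
}

#' Select the most stable fixed-length segment of an RR series
#'
#' Scans every window of \code{length} consecutive intervals and returns the
#' one with the smallest sample standard deviation (the same statistic family
#' as SDNN, so "stability" is minimal overall variability). Ties are broken
#' by the earliest start. The default window of 256 beats is the conventional
#' segment size for short-term HRV analysis.
#'
#' @param series an artifact-corrected \code{\link{rr_series}} with at least
#'   \code{length} intervals.
#' @param length window size in beats (default 256).
#' @return An object of class \code{"segment_selection"}: list with
#'   \code{start_index} (1-based), \code{length}, \code{stability_score}
#'   (window SD, ms) and \code{segment} (an \code{rr_series}).
#' @export
select_stable_segment <- function(series, length = 256) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals_ms
  n <- base::length(x)
  L <- as.integer(length)
  stopifnot(L >= 2)
  if (n < L) {
    stop("series too short for stable-segment selection: need ", L,
         " intervals, have ", n)
  }
  # rolling sample variance via cumulative sums: var = (S2 - S^2/L) / (L-1)
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  starts <- seq_len(n - L + 1L)
  s <- c1[starts + L] - c1[starts]
  s2 <- c2[starts + L] - c2[starts]
  v <- (s2 - s^2 / L) / (L - 1)
  v[v < 0] <- 0  # guard against cancellation on near-constant windows
  best <- which.min(v)  # which.min takes the earliest tie
  seg_meta <- series$meta
  seg_meta$segment_start <- best
  seg_meta$segment_length <- L
  structure(list(
    start_index = best,
    length = L,
    stability_score = sqrt(v[best]),
    segment = rr_series(x[seq.int(best, length.out = L)], meta = seg_meta)
  ), class = "segment_selection")
}

#' @export
print.segment_selection <- function(x, ...) {
  cat(sprintf("Stable segment: %d beats starting at beat %d, window SD %.3f ms\n",
              x$length, x$start_index, x$stability_score))
  invisible(x)
}
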