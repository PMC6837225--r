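#' Construct an RR-interval series
#'
#' The RR series is the pipeline's universal currency: an ordered record of
#' beat-to-beat intervals in milliseconds, with derived beat times, optional
#' per-beat annotations and free-form provenance metadata.
#'
#' Beat times are assigned at the *end* of each interval (the time of the beat
#' closing the interval), zero-based at recording start, so
#' \code{beat_times_s[k] == sum(intervals_ms[1:k]) / 1000}. This is the common
#' tachogram convention and the one assumed by the spectral resampler.
#'
#' @param intervals_ms numeric vector of RR intervals in milliseconds; all
#'   entries must be finite and strictly positive.
#' @param labels optional character vector, one entry per interval, each one of
#'   \code{"clean"}, \code{"artifact_long"}, \code{"artifact_short"},
#'   \code{"corrected"}.
#' @param meta named list of provenance (source file, subject id, phase, ...).
#' @return An object of class \code{"rr_series"}: a list with elements
#'   \code{intervals_ms}, \code{beat_times_s}, \code{labels}, \code{meta}.
#' @examples
#' rr <- rr_series(c(800, 810, 790))
#' rr$beat_times_s  # 0.80 1.61 2.40
#' @export
rr_series <- function(intervals_ms, labels = NULL, meta = list()) {
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) > 0) {
    bad <- which(!is.finite(intervals_ms) | intervals_ms <= 0)
    if (length(bad) > 0) {
      stop("RR intervals must be finite and strictly positive; offending index ",
           bad[1], " (value ", intervals_ms[bad[1]], ")")
    }
  }
  if (!is.null(labels)) {
    if (length(labels) != length(intervals_ms)) {
      stop("labels must have exactly one entry per interval (",
           length(labels), " labels for ", length(intervals_ms), " intervals)")
    }
    ok <- labels %in% c("clean", "artifact_long", "artifact_short", "corrected")
    if (!all(ok)) stop("unknown label: ", labels[which(!ok)[1]])
  }
  structure(list(
    intervals_ms = intervals_ms,
    beat_times_s = cumsum(intervals_ms) / 1000,
    labels = labels,
    meta = meta
  ), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals_ms)
  cat("RR series:", n, "intervals")
  if (n > 0) {
    cat(sprintf(", %.1f s, mean RR %.1f ms (mean HR %.1f bpm)",
                x$beat_times_s[n], mean(x$intervals_ms),
                rri_to_hr(mean(x$intervals_ms))))
  }
  cat("\n")
  if (!is.null(x$labels)) {
    nart <- sum(x$labels != "clean")
    cat("  annotated:", nart, "non-clean beats\n")
  }
  if (length(x$meta) > 0) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals_ms)

#' Convert heart rate to RR interval
#'
#' \code{rri = 60000 / hr}: a heart rate in beats per minute corresponds to a
#' beat-to-beat interval in milliseconds, and vice versa.
#'
#' @param hr_bpm heart rate(s), bpm; must be strictly positive.
#' @return RR interval(s) in ms.
#' @examples
#' hr_to_rri(60)   # 1000
#' hr_to_rri(120)  # 500
#' @export
hr_to_rri <- function(hr_bpm) {
  if (any(!is.finite(hr_bpm) | hr_bpm <= 0)) {
    stop("heart rate must be finite and > 0 bpm")
  }
  60000 / hr_bpm
}

#' Convert RR interval to heart rate
#'
#' Inverse of \code{\link{hr_to_rri}}: \code{hr = 60000 / rri}.
#'
#' @param rri_ms RR interval(s), ms; must be strictly positive.
#' @return Heart rate(s) in bpm.
#' @export
rri_to_hr <- function(rri_ms) {
  if (any(!is.finite(rri_ms) | rri_ms <= 0)) {
    stop("RR interval must be finite and > 0 ms")
  }
  60000 / rri_ms
}

#' Read an RR-interval recording from a text file
#'
#' Two dialects are supported, covering the common text exports of
#' beat-to-beat HR monitors:
#' \describe{
#'   \item{\code{"one-per-line"}}{one interval per line, in ms. Non-numeric
#'     lines at the head of the file (headers) are skipped and counted.}
#'   \item{\code{"csv"}}{two comma-separated columns \code{time_s, rr_ms} with
#'     a header row; only the \code{rr_ms} column is used to build the series
#'     (beat times are re-derived from the cumulative sum).}
#' }
#'
#' @param path file to read.
#' @param dialect \code{"one-per-line"} (default) or \code{"csv"}.
#' @return An \code{\link{rr_series}}; \code{meta} records the source path,
#'   dialect and number of skipped header lines.
#' @export
read_rr_text <- function(path, dialect = c("one-per-line", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read RR file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path)
    need <- c("time_s", "rr_ms")
    if (!all(need %in% names(df))) {
      stop("CSV dialect requires header columns 'time_s' and 'rr_ms'; found: ",
           paste(names(df), collapse = ", "))
    }
    vals <- as.numeric(df$rr_ms)
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad) > 0) {
      stop("non-positive or non-numeric RR interval at data row ", bad[1],
           " of ", path)
    }
    return(rr_series(vals, meta = list(source = path, dialect = dialect,
                                       skipped_lines = 0L)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  suppressWarnings(vals <- as.numeric(lines))
  # header skip: leading non-numeric / blank lines only
  n_skip <- 0L
  while (n_skip < length(lines) &&
         (is.na(vals[n_skip + 1L]) || lines[n_skip + 1L] == "")) {
    n_skip <- n_skip + 1L
  }
  vals <- vals[seq.int(n_skip + 1L, length.out = length(lines) - n_skip)]
  lines_used <- seq.int(n_skip + 1L, length.out = length(lines) - n_skip)
  if (length(vals) > 0) {
    if (anyNA(vals)) {
      stop("non-numeric content at line ", lines_used[which(is.na(vals))[1]],
           " of ", path)
    }
    bad <- which(vals <= 0)
    if (length(bad) > 0) {
      stop("non-positive RR interval at line ", lines_used[bad[1]],
           " of ", path)
    }
  }
  if (n_skip > 0) {
    message("read_rr_text: skipped ", n_skip, " header line(s) in ", path)
  }
  rr_series(vals, meta = list(source = path, dialect = dialect,
                              skipped_lines = n_skip))
}

#' Write an RR-interval recording to a text file
#'
#' One interval per line, ms, at full double precision (17 significant
#' digits), so \code{read_rr_text(write_rr_text(x))} reproduces the intervals
#' exactly.
#'
#' @param series an \code{\link{rr_series}}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_rr_text <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series$intervals_ms) == 0) {
    warning("writing empty RR series to ", path)
  }
  writeLines(format(series$intervals_ms, digits = 17, scientific = FALSE,
                    trim = TRUE), con = path)
  invisible(path)
}
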