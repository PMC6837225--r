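#' Time-domain HRV metrics
#'
#' Computes, on one analysis segment:
#' \describe{
#'   \item{SDNN}{standard deviation of all RR intervals (divisor N-1);
#'     overall variability.}
#'   \item{RMSSD}{root mean square of successive RR differences, with divisor
#'     N-1 over the N-1 difference terms; a vagal (parasympathetic) index.}
#'   \item{pNN50}{proportion of successive differences strictly exceeding
#'     50 ms, out of the N-1 differences.}
#' }
#'
#' @param segment an \code{\link{rr_series}} with at least 2 intervals
#'   (typically the stable 256-beat window from
#'   \code{\link{select_stable_segment}}).
#' @return An object of class \code{"time_metrics"}: list with
#'   \code{sdnn_ms}, \code{rmssd_ms}, \code{pnn50} (proportion in [0,1]),
#'   \code{pnn50_pct} and \code{n_beats}.
#' @examples
#' time_domain(rr_series(c(700, 800)))  # sdnn 70.71, rmssd 100, pnn50 1
#' @export
time_domain <- function(segment) {
  stopifnot(inherits(segment, "rr_series"))
  x <- segment$intervals_ms
  n <- length(x)
  if (n < 2) stop("time-domain HRV needs at least 2 intervals, got ", n)
  d <- diff(x)
  sdnn <- stats::sd(x)
  rmssd <- sqrt(sum(d^2) / (n - 1))
  pnn50 <- sum(abs(d) > 50) / (n - 1)
  structure(list(
    sdnn_ms = sdnn,
    rmssd_ms = rmssd,
    pnn50 = pnn50,
    pnn50_pct = 100 * pnn50,
    n_beats = n
  ), class = "time_metrics")
}

#' @export
print.time_metrics <- function(x, ...) {
  cat(sprintf("Time-domain HRV (%d beats): SDNN %.2f ms, RMSSD %.2f ms, pNN50 %.1f%%\n",
              x$n_beats, x$sdnn_ms, x$rmssd_ms, x$pnn50_pct))
  invisible(x)
}

#' Spectral settings for frequency-domain HRV
#'
#' Defaults follow standard short-term HRV practice: the unevenly sampled
#' tachogram is resampled to an even 4 Hz grid by cubic-spline interpolation,
#' linearly detrended, and a Welch periodogram is taken with 256-sample
#' Hann-windowed segments at 50\% overlap. All choices are carried in the
#' result's \code{method_meta} for reproducibility.
#'
#' @param resample_hz even resampling rate of the tachogram, Hz.
#' @param window_samples Welch segment length, samples.
#' @param overlap fractional overlap between Welch segments.
#' @param lf_band,hf_band frequency bands, Hz. LF power is integrated over
#'   \code{[lf_band[1], lf_band[2])} and HF over \code{[hf_band[1], hf_band[2]]}.
#' @return A named list of settings.
#' @export
spectral_settings <- function(resample_hz = 4.0, window_samples = 256,
                              overlap = 0.5,
                              lf_band = c(0.04, 0.15),
                              hf_band = c(0.15, 0.40)) {
  stopifnot(resample_hz > 0, window_samples >= 8, overlap >= 0, overlap < 1)
  list(resample_hz = resample_hz, window_samples = as.integer(window_samples),
       overlap = overlap, lf_band = lf_band, hf_band = hf_band)
}

# Welch power spectral density of an evenly sampled series.
# Hann window, mean removed per segment, one-sided density in x-units^2/Hz.
# No installed package provides an averaged-segment periodogram, so it is
# implemented here against the textbook definition.
welch_psd <- function(x, fs, window_samples = 256, overlap = 0.5) {
  n <- length(x)
  L <- min(window_samples, n)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, L - 1L) / (L - 1L))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[seq.int(s, length.out = L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when L even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = seq.int(0L, nf - 1L) * fs / L, psd = acc / length(starts))
}

# trapezoidal band power of a PSD over [lo, hi), with interpolated band edges
band_power <- function(freq, psd, lo, hi) {
  if (hi <= freq[1] || lo >= freq[length(freq)]) return(0)
  f <- freq[freq > lo & freq < hi]
  p <- psd[freq > lo & freq < hi]
  f <- c(lo, f, hi)
  p <- c(stats::approx(freq, psd, xout = lo, rule = 2)$y, p,
         stats::approx(freq, psd, xout = hi, rule = 2)$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Frequency-domain HRV metrics
#'
#' Resamples the tachogram (beat time, RR) to an even grid by cubic-spline
#' interpolation, removes a linear trend, computes a Welch periodogram and
#' integrates band powers over the low-frequency (LF, 0.04--0.15 Hz; mixed
#' sympathetic/parasympathetic) and high-frequency (HF, 0.15--0.40 Hz;
#' respiratory/vagal) bands. Normalized units express each band as a
#' percentage of LF+HF, so \code{lf_nu + hf_nu == 100} whenever either band
#' has power; \code{lf_hf_ratio} indexes sympathovagal balance.
#'
#' @param segment an artifact-corrected \code{\link{rr_series}} spanning at
#'   least 60 s (needed to resolve the 0.04 Hz lower band edge).
#' @param settings a \code{\link{spectral_settings}} list.
#' @return An object of class \code{"spectral_metrics"}: list with
#'   \code{lf_power} and \code{hf_power} (ms^2), \code{lf_nu}, \code{hf_nu},
#'   \code{lf_hf_ratio} (\code{Inf} flagged when HF power is zero),
#'   \code{method_meta} (settings as recorded) and the PSD (\code{freq},
#'   \code{psd}) for plotting.
#' @export
frequency_domain <- function(segment, settings = spectral_settings()) {
  stopifnot(inherits(segment, "rr_series"))
  t <- segment$beat_times_s
  x <- segment$intervals_ms
  if (length(x) < 4) stop("spectral analysis needs at least 4 beats")
  span <- t[length(t)] - t[1]
  if (span < 60) {
    stop(sprintf(
      "segment spans %.1f s; at least 60 s is required to resolve the 0.04 Hz LF band edge",
      span))
  }
  fs <- settings$resample_hz
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  xi <- stats::spline(t, x, xout = grid, method = "fmm")$y
  xi <- stats::resid(stats::lm(xi ~ grid))  # linear detrend
  ps <- welch_psd(xi, fs, settings$window_samples, settings$overlap)
  lf <- band_power(ps$freq, ps$psd, settings$lf_band[1], settings$lf_band[2])
  hf <- band_power(ps$freq, ps$psd, settings$hf_band[1], settings$hf_band[2])
  tot <- lf + hf
  if (tot > 0) {
    lf_nu <- 100 * lf / tot
    hf_nu <- 100 * hf / tot
  } else {
    lf_nu <- hf_nu <- NA_real_
  }
  ratio <- if (hf > 0) lf / hf else Inf
  structure(list(
    lf_power = lf, hf_power = hf,
    lf_nu = lf_nu, hf_nu = hf_nu,
    lf_hf_ratio = ratio,
    resample_hz = fs,
    method_meta = c(settings, list(n_beats = length(x), span_s = span,
                                   detrend = "linear", window = "hann")),
    freq = ps$freq, psd = ps$psd
  ), class = "spectral_metrics")
}

#' @export
print.spectral_metrics <- function(x, ...) {
  cat(sprintf("Frequency-domain HRV: LF %.2f ms^2 (%.1f nu), HF %.2f ms^2 (%.1f nu), LF/HF %s\n",
              x$lf_power, x$lf_nu, x$hf_power, x$hf_nu,
              if (is.finite(x$lf_hf_ratio)) sprintf("%.2f", x$lf_hf_ratio)
              else "Inf (HF power zero)"))
  invisible(x)
}
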