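# Independent oracles used across the suite. These deliberately use naive
# loops / closed forms, not the package's own code paths.

# loop-based time-domain metrics
oracle_time_domain <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (j in 1:n) ss <- ss + (x[j] - m)^2
  sdnn <- sqrt(ss / (n - 1))
  sd2 <- 0
  nn50 <- 0
  for (j in 1:(n - 1)) {
    d <- x[j + 1] - x[j]
    sd2 <- sd2 + d^2
    if (abs(d) > 50) nn50 <- nn50 + 1
  }
  list(sdnn = sdnn, rmssd = sqrt(sd2 / (n - 1)), pnn50 = nn50 / (n - 1))
}

# exhaustive stable-window scan
oracle_stable_window <- function(x, L) {
  best_sd <- Inf
  best_start <- NA_integer_
  for (s in 1:(length(x) - L + 1)) {
    w <- sd(x[s:(s + L - 1)])
    if (w < best_sd - 0) {
      best_sd <- w
      best_start <- s
    }
  }
  list(start = best_start, sd = best_sd)
}

# closed-form time average of ylb + a * exp(-t/tau) over [lo, hi]
exp_window_mean <- function(ylb, a, tau, lo, hi) {
  ylb + a * tau * (exp(-lo / tau) - exp(-hi / tau)) / (hi - lo)
}

# integrate-and-fire tachogram from an instantaneous-RR function (ms),
# independent of the package's generator
fire_beats <- function(rr_fun_ms, duration_s) {
  t <- 0
  out <- numeric(0)
  repeat {
    rr <- rr_fun_ms(t)
    if (t + rr / 1000 > duration_s) break
    out <- c(out, rr)
    t <- t + rr / 1000
  }
  out
}

# single- or two-tone tachogram around a constant RR baseline
tone_series <- function(rr0_ms, amps_ms, freqs_hz, duration_s) {
  rr_series(fire_beats(function(t) {
    rr0_ms + sum(amps_ms * sin(2 * pi * freqs_hz * t))
  }, duration_s))
}

# noiseless monoexponential trajectories
on_traj <- function(ylb, a, tau, ta, t) {
  hr_trajectory(t, ifelse(t <= ta, ylb, ylb + a * (1 - exp(-(t - ta) / tau))),
                phase = "on")
}
off_traj <- function(ylb, a, tau, ta, t) {
  hr_trajectory(t, ifelse(t <= ta, ylb + a, ylb + a * exp(-(t - ta) / tau)),
                phase = "off")
}

# random-walk RR series with successive ratios confined to (1-band, 1+band)
constrained_walk <- function(n, start_ms = 800, band = 0.25) {
  x <- numeric(n)
  x[1] <- start_ms
  for (k in 2:n) {
    x[k] <- x[k - 1] * runif(1, 1 - band, 1 + band)
    x[k] <- min(max(x[k], 300), 2000)
    # clamping may break the ratio constraint; re-draw inside the band
    if (x[k] > 1.29 * x[k - 1]) x[k] <- 1.29 * x[k - 1]
    if (x[k] < 0.71 * x[k - 1]) x[k] <- 0.71 * x[k - 1]
  }
  x
}

one_stage_schedule <- function(duration_s = 1, intensity = 0) {
  build_protocol("custom", stages = data.frame(
    duration_s = duration_s, intensity = intensity, kind = "work"))
}
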