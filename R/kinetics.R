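#' Construct an HR trajectory for kinetics analysis
#'
#' A trajectory is instantaneous heart rate sampled at (typically) beat
#' times, with \code{t = 0} at the transition onset: exercise onset for the
#' on-transient, exercise cessation for the off-transient.
#'
#' @param time_s strictly increasing times, s.
#' @param hr_bpm positive heart rates, bpm; same length as \code{time_s}.
#' @param phase \code{"on"} (rest-to-exercise) or \code{"off"} (recovery).
#' @return An object of class \code{"hr_trajectory"}.
#' @export
hr_trajectory <- function(time_s, hr_bpm, phase = c("on", "off")) {
  phase <- match.arg(phase)
  time_s <- as.numeric(time_s)
  hr_bpm <- as.numeric(hr_bpm)
  if (length(time_s) != length(hr_bpm)) stop("time and HR lengths differ")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(hr_bpm) | hr_bpm <= 0)) stop("HR must be finite and > 0")
  structure(list(time_s = time_s, hr_bpm = hr_bpm, phase = phase),
            class = "hr_trajectory")
}

#' Extract an HR trajectory from an RR series
#'
#' Instantaneous HR (\code{60000 / RR}) at each beat time inside
#' \code{[onset_s, end_s]}, re-zeroed at \code{onset_s}.
#'
#' @param series an \code{\link{rr_series}}.
#' @param onset_s transition onset, seconds from recording start.
#' @param end_s end of the analysis window (default: end of recording).
#' @param phase \code{"on"} or \code{"off"}.
#' @return An \code{\link{hr_trajectory}}.
#' @export
hr_from_rr <- function(series, onset_s, end_s = Inf, phase = c("on", "off")) {
  phase <- match.arg(phase)
  stopifnot(inherits(series, "rr_series"))
  keep <- series$beat_times_s >= onset_s & series$beat_times_s <= end_s
  if (sum(keep) < 2) stop("fewer than 2 beats in [", onset_s, ", ", end_s, "]")
  hr_trajectory(series$beat_times_s[keep] - onset_s,
                rri_to_hr(series$intervals_ms[keep]), phase = phase)
}

# Monoexponential transient models. Before the delay TA the model sits at its
# starting level (baseline for "on", baseline + amplitude for "off").
model_on <- function(t, ylb, a, tau, ta) {
  ifelse(t <= ta, ylb, ylb + a * (1 - exp(-(t - ta) / tau)))
}
model_off <- function(t, ylb, a, tau, ta) {
  ifelse(t <= ta, ylb + a, ylb + a * exp(-(t - ta) / tau))
}
# The off-transient as printed in some sources, baseline-multiplied:
# Y(LB)*A*e^{-(t-TA)/tau} + Y(LB). Dimensionally inconsistent (the baseline
# scales the amplitude term); retained only for auditability.
model_off_multiplicative <- function(t, ylb, a, tau, ta) {
  ifelse(t <= ta, ylb * a + ylb, ylb * (a * exp(-(t - ta) / tau)) + ylb)
}

kin_bounds <- list(lower = c(ylb = -Inf, a = -Inf, tau = 0.1, ta = 0),
                   upper = c(ylb = Inf, a = Inf, tau = 1000, ta = 60))

# Multi-start bounded Levenberg-Marquardt fit of one transient.
fit_transient <- function(traj, model, starts_ta = c(0, 5, 10)) {
  t <- traj$time_s
  y <- traj$hr_bpm
  n <- length(t)
  if (n < 10) stop("kinetics fit needs at least 10 samples, got ", n)
  span <- t[n] - t[1]
  head10 <- y[t <= t[1] + 10]
  tail10 <- y[t >= t[n] - 10]
  y0 <- mean(head10)
  yend <- mean(tail10)
  on_like <- identical(model, model_on)
  ylb0 <- if (on_like) y0 else yend
  a0 <- if (on_like) yend - y0 else y0 - yend
  if (abs(a0) < 1e-8) a0 <- 1e-8  # keep the optimizer off an exact zero
  tau0 <- max(0.5, span / 3)
  resid_fun <- function(p) y - model(t, p[1], p[2], p[3], p[4])
  best <- NULL
  for (ta0 in starts_ta) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(ylb = ylb0, a = a0, tau = tau0, ta = ta0),
        lower = kin_bounds$lower, upper = kin_bounds$upper,
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12 ||
        (abs(fit$deviance - best$deviance) <= 1e-12 &&
         fit$par[["ta"]] < best$par[["ta"]])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("nonlinear least squares failed for all starts")
  best
}

# numerical Jacobian of the model surface at the estimates (for CI bands)
kin_jacobian <- function(model, t, par) {
  J <- matrix(0, length(t), 4)
  h <- pmax(abs(par), 1) * 1e-6
  for (j in 1:4) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h[j]; pm[j] <- pm[j] - h[j]
    J[, j] <- (model(t, pp[1], pp[2], pp[3], pp[4]) -
               model(t, pm[1], pm[2], pm[3], pm[4])) / (2 * h[j])
  }
  J
}

build_kinetics_fit <- function(traj, best, model, form, hr_peak_bpm = NA_real_) {
  t <- traj$time_s
  y <- traj$hr_bpm
  par <- stats::coef(best)
  fitted <- model(t, par[1], par[2], par[3], par[4])
  residuals <- y - fitted
  n <- length(y)
  dof <- n - 4L
  r <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0) {
    stats::cor(y, fitted)
  } else NA_real_
  r2 <- 1 - sum(residuals^2) / sum((y - mean(y))^2)
  sigma2 <- best$deviance / dof
  ci95 <- matrix(NA_real_, 4, 2,
                 dimnames = list(names(par), c("low", "high")))
  vcov_p <- tryCatch({
    J <- kin_jacobian(model, t, par)
    sigma2 * solve(crossprod(J))
  }, error = function(e) NULL)
  if (!is.null(vcov_p)) {
    se <- sqrt(pmax(diag(vcov_p), 0))
    tq <- stats::qt(0.975, dof)
    ci95[, 1] <- par - tq * se
    ci95[, 2] <- par + tq * se
  }
  at_tau_bound <- par[["tau"]] <= kin_bounds$lower[["tau"]] + 1e-9 ||
    par[["tau"]] >= kin_bounds$upper[["tau"]] - 1e-9
  degenerate <- !is.finite(r) || abs(par[["a"]]) < 0.5
  accepted <- is.finite(r) && r > 0.95 && !at_tau_bound && !degenerate
  structure(list(
    phase = traj$phase,
    form = form,
    baseline_bpm = unname(par[["ylb"]]),
    amplitude_bpm = unname(par[["a"]]),
    tau_s = unname(par[["tau"]]),
    delay_s = unname(par[["ta"]]),
    r = r,
    r_squared = r2,
    accepted = accepted,
    at_tau_bound = at_tau_bound,
    degenerate = degenerate,
    residuals = residuals,
    fitted = fitted,
    time_s = t,
    observed = y,
    ci95 = ci95,
    vcov = vcov_p,
    sse = best$deviance,
    sigma = sqrt(sigma2),
    n = n,
    hr_peak_bpm = hr_peak_bpm
  ), class = "kinetics_fit")
}

#' Fit the heart-rate on-transient (rest to exercise)
#'
#' Nonlinear least squares of the monoexponential rise
#' \deqn{Y(t) = Y_{LB} + A (1 - e^{-(t - TA)/\tau})}{Y(t) = YLB + A(1 - exp(-(t-TA)/tau))}
#' with \eqn{Y(t) = Y_{LB}} for \eqn{t \le TA}. \eqn{Y_{LB}} is the baseline
#' HR before the transition, \eqn{A} the response amplitude (asymptote =
#' baseline + amplitude), \eqn{\tau} the time constant (s) and \eqn{TA} a
#' delay allowing HR to lag the load change. Fitting uses bounded
#' Levenberg-Marquardt with multiple delay starts (0, 5, 10 s); the lowest
#' sum of squares wins, ties to the smallest delay. A fit is
#' \code{accepted} only when the Pearson correlation between observed and
#' fitted values exceeds 0.95 and neither the time constant is at its bounds
#' nor the amplitude degenerate.
#'
#' @param trajectory an \code{\link{hr_trajectory}} with \code{phase = "on"},
#'   \code{t = 0} at exercise onset; at least 10 samples, ideally spanning
#'   two or more time constants.
#' @return An object of class \code{"kinetics_fit"} with elements
#'   \code{baseline_bpm}, \code{amplitude_bpm}, \code{tau_s}, \code{delay_s},
#'   \code{r}, \code{r_squared}, \code{accepted}, \code{residuals},
#'   \code{ci95} (per-parameter 95\% bounds) and diagnostics.
#' @seealso \code{\link{fit_off}}, \code{\link{fit_quality}}
#' @export
fit_on <- function(trajectory) {
  stopifnot(inherits(trajectory, "hr_trajectory"))
  if (trajectory$phase != "on") stop("fit_on requires an on-phase trajectory")
  best <- fit_transient(trajectory, model_on)
  build_kinetics_fit(trajectory, best, model_on, form = "on")
}

#' Fit the heart-rate off-transient (exercise to recovery)
#'
#' Nonlinear least squares of the monoexponential decay
#' \deqn{Y(t) = Y_{LB} + A e^{-(t - TA)/\tau}}{Y(t) = YLB + A exp(-(t-TA)/tau)}
#' with \eqn{Y(t) = Y_{LB} + A} for \eqn{t \le TA} (a plateau before the
#' decay begins: HR need not fall immediately after load interruption).
#' \eqn{A} is the amplitude of the HR reduction and \eqn{Y_{LB}} the recovery
#' asymptote. Diagnostics and acceptance as in \code{\link{fit_on}}.
#'
#' An alternative multiplicative parameterization
#' \eqn{Y_{LB}(A e^{-(t-TA)/\tau}) + Y_{LB}}, in which the baseline scales
#' the decay term, is available via \code{form = "multiplicative"} for
#' auditing against software that uses it; it is dimensionally inconsistent
#' (its \eqn{A} is a unitless fraction of baseline) and the additive form is
#' the default.
#'
#' @param trajectory an \code{\link{hr_trajectory}} with \code{phase = "off"},
#'   \code{t = 0} at exercise cessation.
#' @param hr_peak_bpm peak HR at cessation, conventionally the mean HR of the
#'   final 5 s of exercise; carried into the result for delta analysis.
#' @param form \code{"additive"} (default) or \code{"multiplicative"}.
#' @return A \code{"kinetics_fit"}; see \code{\link{fit_on}}.
#' @export
fit_off <- function(trajectory, hr_peak_bpm = NA_real_,
                    form = c("additive", "multiplicative")) {
  stopifnot(inherits(trajectory, "hr_trajectory"))
  form <- match.arg(form)
  if (trajectory$phase != "off") stop("fit_off requires an off-phase trajectory")
  model <- if (form == "additive") model_off else model_off_multiplicative
  best <- fit_transient(trajectory, model)
  build_kinetics_fit(trajectory, best, model,
                     form = paste0("off_", form), hr_peak_bpm = hr_peak_bpm)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("%s-transient monoexponential fit (n = %d)\n",
              sub("_.*", "", x$form), x$n))
  cat(sprintf("  baseline %.2f bpm, amplitude %.2f bpm, tau %.2f s, delay %.2f s\n",
              x$baseline_bpm, x$amplitude_bpm, x$tau_s, x$delay_s))
  cat(sprintf("  r = %.4f, R^2 = %.4f, %s\n", x$r, x$r_squared,
              if (isTRUE(x$accepted)) "accepted (r > 0.95)"
              else "NOT accepted"))
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation).
# A systematic lack of fit shows up as too few runs.
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) {
    return(list(runs = as.integer(n > 0), p_value = NA_real_, z = NA_real_))
  }
  runs <- 1L + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, p_value = 2 * stats::pnorm(-abs(z)), z = z)
}

#' Fit-quality diagnostics for a kinetics fit
#'
#' Bundles the acceptance gate (Pearson r > 0.95), a runs test on residual
#' signs (systematic lack of fit produces too few runs), and a pointwise 95\%
#' confidence band for the fitted curve from the parameter covariance (delta
#' method).
#'
#' @param fit a \code{"kinetics_fit"} from \code{\link{fit_on}} or
#'   \code{\link{fit_off}}.
#' @return An object of class \code{"fit_quality"}: list with \code{r},
#'   \code{r_squared}, \code{accepted}, \code{runs_test} (runs, z, p),
#'   \code{band} (data frame: time_s, fitted, lower, upper) and
#'   \code{residual_summary}.
#' @export
fit_quality <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  rt <- runs_test(fit$residuals)
  band <- data.frame(time_s = fit$time_s, fitted = fit$fitted,
                     lower = NA_real_, upper = NA_real_)
  if (!is.null(fit$vcov)) {
    model <- switch(sub("_.*", "", fit$form),
                    on = model_on,
                    off = if (fit$form == "off_additive") model_off
                          else model_off_multiplicative)
    par <- c(fit$baseline_bpm, fit$amplitude_bpm, fit$tau_s, fit$delay_s)
    J <- kin_jacobian(model, fit$time_s, par)
    se_curve <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
    tq <- stats::qt(0.975, fit$n - 4L)
    band$lower <- fit$fitted - tq * se_curve
    band$upper <- fit$fitted + tq * se_curve
  }
  structure(list(
    r = fit$r,
    r_squared = fit$r_squared,
    accepted = fit$accepted,
    runs_test = rt,
    band = band,
    residual_summary = summary(fit$residuals)
  ), class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("Fit quality: r = %.4f (%s), runs-test p = %s\n",
              x$r, if (isTRUE(x$accepted)) "accepted" else "rejected",
              format(x$runs_test$p_value, digits = 3)))
  invisible(x)
}
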