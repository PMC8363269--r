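#' A uniformly sampled bundle displacement trace
#'
#' The common currency of the analysis functions: displacement in metres on
#' a strictly uniform time grid, with optional stimulus onset/offset marks.
#'
#' @param displacement numeric vector of displacements, metres.
#' @param sampling_rate sampling rate in hertz (give either this or `time`).
#' @param time optional explicit time vector in seconds; must be uniform to
#'   within 1 ppm.
#' @param stimulus_onset,stimulus_offset optional stimulus marks, seconds.
#' @param n_averaged number of repetitions averaged into this trace.
#' @return An object of class `displacement_trace` with fields `time`,
#'   `displacement`, `sampling_rate`, `stimulus_onset`, `stimulus_offset`,
#'   `n_averaged`.
#' @examples
#' displacement_trace(rnorm(100, sd = 1e-9), sampling_rate = 1e4)
#' @export
displacement_trace <- function(displacement, sampling_rate = NULL,
                               time = NULL, stimulus_onset = NULL,
                               stimulus_offset = NULL, n_averaged = 1L) {
  if (!is.numeric(displacement) || length(displacement) < 2)
    stop("`displacement` must be a numeric vector of length >= 2",
         call. = FALSE)
  if (is.null(time)) {
    check_scalar(sampling_rate, "sampling_rate", lower = 0,
                 strict_lower = TRUE)
    time <- (seq_along(displacement) - 1) / sampling_rate
  } else {
    if (length(time) != length(displacement))
      stop("`time` and `displacement` lengths differ", call. = FALSE)
    dt <- diff(time)
    if (any(dt <= 0))
      stop("`time` must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("`time` must be uniformly sampled (constant step within 1 ppm)",
           call. = FALSE)
    sampling_rate <- 1 / mean(dt)
  }
  check_scalar(stimulus_onset, "stimulus_onset", allow_null = TRUE)
  check_scalar(stimulus_offset, "stimulus_offset", allow_null = TRUE)
  structure(list(time = time, displacement = displacement,
                 sampling_rate = sampling_rate,
                 stimulus_onset = stimulus_onset,
                 stimulus_offset = stimulus_offset,
                 n_averaged = as.integer(n_averaged)),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(
    "<displacement_trace> %d samples at %.6g Hz (%.4g s), rms %.4g nm",
    length(x$displacement), x$sampling_rate,
    length(x$displacement) / x$sampling_rate,
    stats::sd(x$displacement) * 1e9))
  if (!is.null(x$stimulus_onset))
    cat(sprintf(", stimulus %g-%g s", x$stimulus_onset,
                if (is.null(x$stimulus_offset)) NA else x$stimulus_offset))
  if (x$n_averaged > 1) cat(sprintf(", average of %d", x$n_averaged))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  data.frame(time_s = x$time, displacement_m = x$displacement)
}

#' Read / write displacement traces as CSV
#'
#' Plain CSV with header `time_s,displacement_m`; stimulus marks travel as
#' leading comment lines `# stimulus_onset_s=...` and
#' `# stimulus_offset_s=...`.
#'
#' @param file path to a CSV file.
#' @return `read_trace()`: a [displacement_trace()].
#' @export
read_trace <- function(file) {
  head_lines <- readLines(file, n = 10L)
  get_mark <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), head_lines, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(sub(sprintf("^#\\s*%s=", key), "", ln[1]))
  }
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("time_s", "displacement_m") %in% names(d)))
    stop("trace CSV needs columns `time_s` and `displacement_m`",
         call. = FALSE)
  displacement_trace(d$displacement_m, time = d$time_s,
                     stimulus_onset = get_mark("stimulus_onset_s"),
                     stimulus_offset = get_mark("stimulus_offset_s"))
}

#' @rdname read_trace
#' @param trace a [displacement_trace()].
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "displacement_trace"))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(trace$stimulus_onset))
    writeLines(sprintf("# stimulus_onset_s=%.15g", trace$stimulus_onset), con)
  if (!is.null(trace$stimulus_offset))
    writeLines(sprintf("# stimulus_offset_s=%.15g", trace$stimulus_offset),
               con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Variance of a trace after detrending
#'
#' Sample variance of the displacement after removing the mean
#' (`detrend = "mean"`) or a least-squares linear drift
#' (`detrend = "linear"`).  Drift inflates the apparent Brownian variance
#' and hence biases equipartition stiffness low.
#'
#' @param trace a [displacement_trace()].
#' @param detrend `"mean"` or `"linear"`.
#' @return Variance in m^2.
#' @seealso [equipartition_stiffness()]
#' @export
trace_variance <- function(trace, detrend = c("mean", "linear")) {
  stopifnot(inherits(trace, "displacement_trace"))
  detrend <- match.arg(detrend)
  x <- trace$displacement
  r <- if (detrend == "mean") x - mean(x)
       else stats::lm.fit(cbind(1, trace$time), x)$residuals
  sum(r^2) / (length(r) - 1L)
}

#' Average repeated stimulus presentations
#'
#' Pointwise mean of traces recorded on identical time grids; averaging `n`
#' repetitions reduces uncorrelated noise by `sqrt(n)`.  No resampling is
#' performed: grids must match exactly.
#'
#' @param traces list of [displacement_trace()] objects on identical grids.
#' @return A [displacement_trace()] whose `n_averaged` records the total
#'   repetition count.
#' @export
average_repetitions <- function(traces) {
  if (!is.list(traces) || !length(traces) ||
      !all(vapply(traces, inherits, logical(1), "displacement_trace")))
    stop("`traces` must be a non-empty list of displacement traces",
         call. = FALSE)
  t0 <- traces[[1]]$time
  for (tr in traces[-1]) {
    if (length(tr$time) != length(t0) || any(tr$time != t0))
      stop("traces are not on identical time grids; resample explicitly ",
           "before averaging", call. = FALSE)
  }
  x <- rowMeans(vapply(traces, `[[`, numeric(length(t0)), "displacement"))
  displacement_trace(
    x, time = t0,
    stimulus_onset = traces[[1]]$stimulus_onset,
    stimulus_offset = traces[[1]]$stimulus_offset,
    n_averaged = sum(vapply(traces, `[[`, integer(1), "n_averaged")))
}

#' Fit an exponential onset to a step response
#'
#' Least-squares fit of
#' `x(t) = baseline + amplitude (1 - exp(-(t - t0) / tau))` to the rising
#' phase of a response, for `t` from `t0 + exclusion_window` to the
#' stimulus offset (or trace end).  The first `exclusion_window` seconds
#' after onset are excluded because the measured rise there is dominated by
#' the recording chain, not the bundle; `R^2` is computed on the fitted
#' window only.
#'
#' @param trace a [displacement_trace()] with `stimulus_onset` set (or pass
#'   `onset`).
#' @param exclusion_window seconds after onset to exclude (default 250e-6).
#' @param onset override for the stimulus onset time, seconds.
#' @return An object of class `onset_fit`: `amplitude` (m),
#'   `time_constant` (s), `baseline` (m), `r_squared`, `exclusion_window`,
#'   plus the underlying `nls` fit.
#' @examples
#' tr <- generate_step_response(
#'   step_stimulus_spec(force = 50e-12, stiffness = 500e-6, drag = 167.5e-9),
#'   onset = 2e-3, offset = 20e-3,
#'   generator_config(seed = 1, sampling_rate = 1e5, duration = 25e-3))
#' fit_onset(tr)$time_constant    # ~335e-6 s
#' @export
fit_onset <- function(trace, exclusion_window = 250e-6, onset = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  t0 <- if (!is.null(onset)) onset else trace$stimulus_onset
  if (is.null(t0))
    stop("stimulus onset is not set on this trace", call. = FALSE)
  check_scalar(exclusion_window, "exclusion_window", lower = 0)
  t_end <- if (!is.null(trace$stimulus_offset)) trace$stimulus_offset
           else max(trace$time)
  sel <- trace$time >= t0 + exclusion_window & trace$time <= t_end
  if (sum(sel) < 10)
    stop("fewer than 10 samples in the fit window", call. = FALSE)
  tt <- trace$time[sel]
  xx <- trace$displacement[sel]
  if (diff(range(xx)) == 0)
    stop("flat trace in the fit window: onset time constant is undefined",
         call. = FALSE)

  ## starting values: plateau from the tail, baseline from pre-onset data
  ## (or extrapolation); tau candidates from a log-linear decay regression,
  ## the 10-90% rise time, and a window fraction (multistart guards the
  ## near-degenerate case where the window is long compared with tau)
  plateau0 <- mean(xx[tt >= tt[1] + 0.8 * (tt[length(tt)] - tt[1])])
  pre <- trace$displacement[trace$time < t0]
  base0 <- if (length(pre) >= 3) mean(pre) else xx[1] - (plateau0 - xx[1])
  amp0 <- plateau0 - base0
  if (amp0 == 0) amp0 <- diff(range(xx))
  ts <- tt - t0
  taus <- (t_end - t0) / 10
  decay <- (plateau0 - xx) / amp0
  valid <- which(decay > 0.02)
  if (length(valid) >= 5) {
    slope <- stats::coef(stats::lm.fit(cbind(1, ts[valid]),
                                       log(decay[valid])))[2]
    if (is.finite(slope) && slope < 0) taus <- c(-1 / slope, taus)
  }
  frac <- (xx - base0) / amp0
  t10 <- tt[which(frac >= 0.1)[1]]
  t90 <- tt[which(frac >= 0.9)[1]]
  if (!is.na(t10) && !is.na(t90) && t90 > t10)
    taus <- c(taus, (t90 - t10) / log(9))
  resid_fn <- function(p)
    p[1] + p[2] * (1 - exp(-ts / p[3])) - xx
  jac_fn <- function(p) {
    e <- exp(-ts / p[3])
    cbind(1, 1 - e, -p[2] * ts * e / p[3]^2)
  }
  fit <- NULL
  for (tau0 in taus) {
    cand <- minpack.lm::nls.lm(
      par = c(baseline = base0, amplitude = amp0, tau = tau0),
      lower = c(-Inf, -Inf, .Machine$double.eps),
      fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, maxfev = 10000, ftol = 1e-15, ptol = 1e-15))
    ok <- cand$info %in% 1:4 && cand$par[3] > 1e-3 / trace$sampling_rate
    if (ok && (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)))
      fit <- cand
  }
  if (is.null(fit))
    stop(sprintf(
      paste0("onset fit did not converge; starting values were ",
             "baseline=%.3g, amplitude=%.3g, tau in {%s}"),
      base0, amp0, paste(signif(taus, 3), collapse = ", ")),
      call. = FALSE)
  cf <- fit$par
  r2 <- 1 - sum(fit$fvec^2) / sum((xx - mean(xx))^2)
  structure(list(amplitude = unname(cf["amplitude"]),
                 time_constant = unname(cf["tau"]),
                 baseline = unname(cf["baseline"]),
                 r_squared = r2,
                 exclusion_window = exclusion_window,
                 onset = t0, fit = fit),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<onset_fit> tau = %.4g us, amplitude = %.4g nm, ",
           "R^2 = %.4f (first %.0f us excluded)\n"),
    x$time_constant * 1e6, x$amplitude * 1e9, x$r_squared,
    x$exclusion_window * 1e6))
  invisible(x)
}

#' Summarise adaptation features of a step response
#'
#' Operational summary of the shapes hair-bundle adaptation produces:
#' the decline of a response from its early peak to a plateau (sag), the
#' undershoot below baseline after stimulus offset, and the twitch — a fast
#' rebound opposite the response direction within the stimulus window,
#' quantified here as the largest dip below the plateau after the peak.
#' All quantities are measured in the response direction (the sign of the
#' plateau relative to the pre-onset baseline).
#'
#' @param trace a [displacement_trace()] with onset and offset set.
#' @param tau onset time constant in seconds used to bound the peak-search
#'   window (`onset` to `onset + 5 tau`); estimated from the 10--90% rise
#'   time when `NULL`.
#' @return An object of class `adaptation_summary` with fields `peak` (m),
#'   `plateau` (m), `sag_fraction`, `undershoot` (m, signed in the response
#'   direction; negative values dip past the baseline),
#'   `twitch_amplitude` (m), `direction` (+1/-1) and `tau_used` (s).
#' @export
summarize_adaptation <- function(trace, tau = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  t0 <- trace$stimulus_onset
  t1 <- trace$stimulus_offset
  if (is.null(t0) || is.null(t1))
    stop("both stimulus onset and offset must be set", call. = FALSE)
  tt <- trace$time
  in_stim <- tt >= t0 & tt <= t1
  post <- tt > t1
  if (sum(in_stim) < 10 || sum(post) < 5)
    stop("stimulus or post-stimulus window too short to summarise",
         call. = FALSE)
  baseline <- if (any(tt < t0)) mean(trace$displacement[tt < t0]) else 0
  x <- trace$displacement - baseline
  plateau_raw <- mean(x[in_stim & tt >= t1 - 0.2 * (t1 - t0)])
  s <- if (plateau_raw < 0) -1 else 1
  y <- s * x

  if (is.null(tau)) {
    ys <- y[in_stim]
    ts <- tt[in_stim]
    ymax <- max(ys)
    t10 <- ts[which(ys >= 0.1 * ymax)[1]]
    t90 <- ts[which(ys >= 0.9 * ymax)[1]]
    tau <- if (!is.na(t10) && !is.na(t90) && t90 > t10)
      (t90 - t10) / log(9) else 0.05 * (t1 - t0)
  }
  peak_win <- in_stim & tt <= max(t0 + 5 * tau, tt[which(in_stim)[10]])
  peak <- max(y[peak_win])
  t_peak <- tt[peak_win][which.max(y[peak_win])]
  plateau <- abs(plateau_raw)
  ## a rise that has not fully saturated by 5 tau would read as a small
  ## negative sag; clamp at zero (facilitation is not modelled)
  sag_fraction <- if (peak > 0) max(0, (peak - plateau) / peak) else 0
  after_peak <- in_stim & tt > t_peak
  twitch_amplitude <- if (any(after_peak))
    max(0, plateau - min(y[after_peak])) else 0
  undershoot <- min(y[post])
  structure(list(peak = peak, plateau = plateau,
                 sag_fraction = sag_fraction,
                 undershoot = undershoot,
                 twitch_amplitude = twitch_amplitude,
                 direction = s, tau_used = tau,
                 baseline = baseline),
            class = "adaptation_summary")
}

#' @export
print.adaptation_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<adaptation_summary> peak %.4g nm, plateau %.4g nm ",
           "(sag %.1f%%), twitch %.4g nm, undershoot %.4g nm\n"),
    x$peak * 1e9, x$plateau * 1e9, 100 * x$sag_fraction,
    x$twitch_amplitude * 1e9, x$undershoot * 1e9))
  invisible(x)
}

#' Averaged-periodogram power spectral density
#'
#' Welch-style estimate: the trace is cut into overlapping segments, each
#' detrended, windowed and Fourier transformed, and the one-sided
#' periodograms are averaged.  Normalisation is Parseval-consistent: the
#' PSD integrates to the (windowed) signal variance.
#'
#' @param trace a [displacement_trace()].
#' @param segment_length samples per segment; default gives ~8 segments at
#'   the chosen overlap.
#' @param overlap fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @param detrend remove each segment's mean before transforming.
#' @return An object of class `power_spectrum`: `frequency` (Hz), `psd`
#'   (m^2/Hz), `df`, `n_segments`, `segment_psd` (per-segment periodograms,
#'   used by bootstrap resampling), `sampling_rate`.
#' @examples
#' cfg <- generator_config(seed = 1, sampling_rate = 200, duration = 60)
#' tr <- generate_oscillation(2, rms_amplitude = 10e-9, quality = 5, cfg)
#' ps <- power_spectrum(tr)
#' ps$frequency[which.max(ps$psd)]   # near 2 Hz
#' @export
power_spectrum <- function(trace, segment_length = NULL, overlap = 0.5,
                           window = c("hann", "rect"), detrend = TRUE) {
  stopifnot(inherits(trace, "displacement_trace"))
  window <- match.arg(window)
  x <- trace$displacement
  n <- length(x)
  fs <- trace$sampling_rate
  if (is.null(segment_length))
    segment_length <- max(16L, floor(2 * n / 9))
  segment_length <- as.integer(segment_length)
  if (segment_length > n)
    stop("trace too short for the requested segment length", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  L <- segment_length
  step <- max(1L, as.integer(floor(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L)) else rep(1, L)
  w2 <- sum(w^2)
  nf <- floor(L / 2) + 1L
  seg_psd <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    xs <- x[starts[j]:(starts[j] + L - 1L)]
    if (detrend) xs <- xs - mean(xs)
    X <- stats::fft(xs * w)
    p <- (Mod(X[1:nf])^2) / (fs * w2)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    if (L %% 2 == 1L) p[nf] <- 2 * p[nf]     # no Nyquist bin for odd L
    seg_psd[, j] <- p
  }
  structure(list(frequency = seq(0, nf - 1L) * fs / L,
                 psd = rowMeans(seg_psd),
                 df = fs / L,
                 n_segments = length(starts),
                 segment_length = L,
                 segment_psd = seg_psd,
                 window = window,
                 sampling_rate = fs),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    paste0("<power_spectrum> %d bins to %.4g Hz (df = %.4g Hz), ",
           "%d segments of %d samples\n"),
    length(x$frequency), max(x$frequency), x$df, x$n_segments,
    x$segment_length))
  invisible(x)
}

## the mirrored-peak double-Lorentzian spectral model
.dlor_model <- function(f, a1, w1, f0, a2, w2, floor_) {
  a1 * w1^2 / ((f - f0)^2 + w1^2) + a1 * w1^2 / ((f + f0)^2 + w1^2) +
    a2 * w2^2 / (f^2 + w2^2) + floor_
}

## analytic Jacobian of log(.dlor_model) wrt (a1, w1, f0, a2, w2, floor_)
.dlor_log_jac <- function(f, p) {
  dm <- (f - p[3])^2 + p[2]^2
  dp <- (f + p[3])^2 + p[2]^2
  dz <- f^2 + p[5]^2
  m <- p[1] * p[2]^2 / dm + p[1] * p[2]^2 / dp + p[4] * p[5]^2 / dz +
    p[6] + 1e-300
  cbind(
    p[2]^2 / dm + p[2]^2 / dp,
    2 * p[1] * p[2] * ((f - p[3])^2 / dm^2 + (f + p[3])^2 / dp^2),
    2 * p[1] * p[2]^2 * ((f - p[3]) / dm^2 - (f + p[3]) / dp^2),
    p[5]^2 / dz,
    2 * p[4] * p[5] * f^2 / dz^2,
    1) / m
}

#' Fit a double-Lorentzian model to an oscillation spectrum
#'
#' Least-squares fit (in log power, so that decades of the spectrum weigh
#' equally) of a spectral peak mirrored at `+/- f0` plus a zero-centred
#' Lorentzian and a flat noise floor:
#' \deqn{S(f) = \frac{A_1 w_1^2}{(f-f_0)^2+w_1^2}
#'            + \frac{A_1 w_1^2}{(f+f_0)^2+w_1^2}
#'            + \frac{A_2 w_2^2}{f^2+w_2^2} + C}
#' `f0` is the spontaneous-oscillation peak frequency.  When the underlying
#' motion has no oscillatory component the fit degenerates towards
#' `f0 < w1`, which callers should treat as "no distinct peak".
#'
#' @param spectrum a [power_spectrum()].
#' @param f0_init optional initial guess for the peak frequency, Hz.
#' @param single fit only the zero-centred Lorentzian plus floor (no peak
#'   pair).
#' @return An object of class `spectrum_fit`: `peak_frequency` (Hz),
#'   `half_widths` (`c(w1, w2)`, Hz), `amplitudes` (`c(A1, A2)`, m^2/Hz),
#'   `noise_floor` (m^2/Hz), `r_squared_log` and the `nls` fit.
#' @export
fit_double_lorentzian <- function(spectrum, f0_init = NULL, single = FALSE) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$frequency > 0 & spectrum$psd > 0
  f <- spectrum$frequency[keep]
  S <- spectrum$psd[keep]
  if (length(f) < 10)
    stop("too few positive-frequency bins to fit", call. = FALSE)
  fmax <- max(f)
  df <- spectrum$df
  f0i <- if (!is.null(f0_init)) f0_init else f[which.max(S)]
  if (!is.null(f0_init)) check_scalar(f0_init, "f0_init", lower = 0)
  a1i <- max(S) / 2
  w1i <- max(2 * df, f0i / 5)
  a2i <- S[1]
  w2i <- max(2 * df, f0i / 2)
  ci <- min(S) / 2
  logS <- log(S)
  if (single) {
    fit <- minpack.lm::nls.lm(
      par = c(a2 = max(S), w2 = w2i, floor_ = ci),
      lower = c(0, df / 4, 0),
      fn = function(p)
        log(p[1] * p[2]^2 / (f^2 + p[2]^2) + p[3] + 1e-300) - logS,
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000))
    if (!fit$info %in% 1:4)
      stop("single-Lorentzian fit did not converge: ", fit$message,
           call. = FALSE)
    cf <- as.list(fit$par)
    cf$a1 <- 0; cf$w1 <- NA_real_; cf$f0 <- 0
  } else {
    run_lm <- function(par) suppressWarnings(minpack.lm::nls.lm(
      par = par,
      lower = c(0, df / 4, 0, 0, df / 4, 0),
      upper = c(Inf, Inf, fmax, Inf, Inf, Inf),
      fn = function(p)
        log(.dlor_model(f, p[1], p[2], p[3], p[4], p[5], p[6]) + 1e-300) -
          logS,
      jac = function(p) .dlor_log_jac(f, p),
      control = minpack.lm::nls.lm.control(maxiter = 1024, maxfev = 50000)))
    fit <- run_lm(c(a1 = a1i, w1 = w1i, f0 = f0i, a2 = a2i, w2 = w2i,
                    floor_ = ci))
    if (!fit$info %in% 1:4) {
      ## the noise-floor direction can be numerically flat: restart from
      ## the terminal point and accept a stationary objective
      refit <- run_lm(fit$par)
      if (refit$info %in% 1:4 ||
          sum(fit$fvec^2) - sum(refit$fvec^2) < 1e-8 * sum(fit$fvec^2)) {
        fit <- refit
      } else {
        stop(sprintf(
          paste0("double-Lorentzian fit did not converge (%s); ",
                 "initial guesses: f0=%.3g, w1=%.3g"),
          fit$message, f0i, w1i), call. = FALSE)
      }
    }
    cf <- as.list(fit$par)
    if (cf$f0 > 0.95 * fmax)
      stop(sprintf(
        "fitted peak frequency (%.3g Hz) pinned to the spectral edge",
        cf$f0), call. = FALSE)
  }
  r2 <- 1 - sum(fit$fvec^2) / sum((logS - mean(logS))^2)
  structure(list(peak_frequency = cf$f0,
                 half_widths = c(peak = cf$w1, central = cf$w2),
                 amplitudes = c(peak = cf$a1, central = cf$a2),
                 noise_floor = cf$floor_,
                 r_squared_log = r2,
                 single = single, fit = fit),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<spectrum_fit> peak %.4g Hz (half-width %.3g Hz), ",
           "central width %.3g Hz, log-R^2 %.3f\n"),
    x$peak_frequency, x$half_widths[1], x$half_widths[2], x$r_squared_log))
  invisible(x)
}

#' Compare spontaneous oscillations before and after irradiation
#'
#' Fits the double-Lorentzian model to both traces' spectra, builds
#' position histograms on common breaks, and reports the change in peak
#' frequency and in oscillation amplitude (root-mean-square displacement)
#' with bootstrap confidence intervals obtained by resampling spectrum
#' segments (for frequency) and trace blocks (for amplitude).
#'
#' @param pre,post [displacement_trace()] objects recorded before and after
#'   the treatment.
#' @param segment_length passed to [power_spectrum()].
#' @param n_boot bootstrap replicates (default 100).
#' @param conf confidence level (default 0.95).
#' @param seed optional seed for the bootstrap resampling.
#' @param f0_init optional initial peak-frequency guess passed to the fits.
#' @return An object of class `pre_post_comparison` with the two
#'   `spectrum_fit`s, `peak_frequency_change_hz`,
#'   `peak_frequency_change_fraction`, `amplitude_change_fraction`,
#'   bootstrap CIs (`ci_frequency_change_hz`,
#'   `ci_amplitude_change_fraction`) and `histograms`.
#' @export
compare_pre_post <- function(pre, post, segment_length = NULL,
                             n_boot = 100, conf = 0.95, seed = NULL,
                             f0_init = NULL) {
  stopifnot(inherits(pre, "displacement_trace"),
            inherits(post, "displacement_trace"))
  sp_pre <- power_spectrum(pre, segment_length = segment_length)
  sp_post <- power_spectrum(post, segment_length = segment_length)
  fit_pre <- fit_double_lorentzian(sp_pre, f0_init = f0_init)
  fit_post <- fit_double_lorentzian(sp_post, f0_init = f0_init)
  f_pre <- fit_pre$peak_frequency
  f_post <- fit_post$peak_frequency
  rms_pre <- stats::sd(pre$displacement)
  rms_post <- stats::sd(post$displacement)

  brk <- pretty(range(c(pre$displacement, post$displacement)), n = 40)
  hists <- list(
    pre = graphics::hist(pre$displacement, breaks = brk, plot = FALSE),
    post = graphics::hist(post$displacement, breaks = brk, plot = FALSE))

  refit_f0 <- function(sp, fit0) {
    idx <- sample.int(ncol(sp$segment_psd), replace = TRUE)
    sp2 <- sp
    sp2$psd <- rowMeans(sp$segment_psd[, idx, drop = FALSE])
    tryCatch(
      fit_double_lorentzian(sp2, f0_init = fit0$peak_frequency)$peak_frequency,
      error = function(e) NA_real_)
  }
  block_rms <- function(tr) {
    x <- tr$displacement
    nb <- 10L
    L <- floor(length(x) / nb)
    blocks <- matrix(x[1:(nb * L)], nrow = L)
    idx <- sample.int(nb, replace = TRUE)
    stats::sd(as.vector(blocks[, idx]))
  }
  boot_fun <- function() {
    c(df0 = refit_f0(sp_post, fit_post) - refit_f0(sp_pre, fit_pre),
      damp = block_rms(post) / block_rms(pre) - 1)
  }
  boot <- if (is.null(seed)) replicate(n_boot, boot_fun())
          else with_seed(seed, replicate(n_boot, boot_fun()))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  structure(list(
    fit_pre = fit_pre, fit_post = fit_post,
    peak_frequency_change_hz = f_post - f_pre,
    peak_frequency_change_fraction = (f_post - f_pre) / f_pre,
    amplitude_change_fraction = rms_post / rms_pre - 1,
    ci_frequency_change_hz =
      stats::quantile(boot["df0", ], probs, na.rm = TRUE),
    ci_amplitude_change_fraction =
      stats::quantile(boot["damp", ], probs, na.rm = TRUE),
    histograms = hists, n_boot = n_boot, conf = conf),
    class = "pre_post_comparison")
}

#' @export
print.pre_post_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<pre_post_comparison> peak frequency change %+.4g Hz ",
           "(%+.1f%%), amplitude change %+.1f%%\n",
           "  %g%% CI frequency change: [%.3g, %.3g] Hz\n"),
    x$peak_frequency_change_hz, 100 * x$peak_frequency_change_fraction,
    100 * x$amplitude_change_fraction, 100 * x$conf,
    x$ci_frequency_change_hz[1], x$ci_frequency_change_hz[2]))
  invisible(x)
}
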