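## Independent oracles used across tests.  These recompute expectations by
## routes separate from the implementation under test.

C0 <- 2.99792458e8
KB <- 1.380649e-23

## Global momentum balance for a traced ray: the force on the cylinder must
## equal the incident momentum flux minus the momentum flux carried off by
## the exiting rays (n/c per watt in each ray's medium; all exits are in
## the outer medium).  Computed purely from the exit-ray table.
momentum_balance_force <- function(path, cyl) {
  ex <- path$exit_rays
  out <- c(sum(ex$power * ex$dir_x), sum(ex$power * ex$dir_y))
  (cyl$index_outside / C0) * (c(path$incident_power, 0) - out)
}

## Lock-in amplitude of a sinusoidal component at frequency f in trace x(t),
## over the window [t_from, t_to]
lockin_amplitude <- function(trace, f, t_from, t_to) {
  sel <- trace$time >= t_from & trace$time <= t_to
  tt <- trace$time[sel]
  x <- trace$displacement[sel]
  x <- x - mean(x)
  2 * Mod(mean(x * exp(-2i * pi * f * tt)))
}

## Analytic one-sided PSD of an Ornstein-Uhlenbeck process with stiffness k,
## drag lam, temperature T: Lorentzian with corner 1/(2 pi tau)
ou_psd <- function(f, k, lam, temp) {
  (4 * KB * temp * lam / k^2) / (1 + (2 * pi * f * lam / k)^2)
}

## Exponential fit of an autocorrelation's decay time by log-linear
## regression over lags where the ACF is still substantial
acf_decay_time <- function(trace, max_lag_s) {
  dt <- 1 / trace$sampling_rate
  nl <- max(2L, round(max_lag_s / dt))
  a <- stats::acf(trace$displacement, lag.max = nl, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  keep <- which(a > 0.2)          # stay on the clean early decay
  lags <- (keep - 1) * dt
  -1 / stats::coef(stats::lm(log(a[keep]) ~ lags))[2]
}

## A clean synthetic exponential-onset trace built directly (not via the
## package generator), for fitting tests
make_onset_trace <- function(tau, amplitude = 100e-9, baseline = 0,
                             onset = 2e-3, fs = 1e5, duration = 30e-3) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- ifelse(t < onset, baseline,
              baseline + amplitude * (1 - exp(-(t - onset) / tau)))
  displacement_trace(x, sampling_rate = fs, stimulus_onset = onset)
}
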