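test_that("repetition averaging preserves the signal and beats down noise", {
  tmpl <- make_onset_trace(tau = 500e-6)
  avg <- average_repetitions(rep(list(tmpl), 25))
  expect_equal(avg$displacement, tmpl$displacement)
  expect_identical(avg$n_averaged, 25L)
  ## 25 white-noise repetitions: residual sd drops by ~sqrt(25)
  set.seed(314)
  n <- 4000
  reps <- lapply(1:25, function(i)
    displacement_trace(rnorm(n, sd = 5e-9), sampling_rate = 1e4))
  avg <- average_repetitions(reps)
  ratio <- 5e-9 / sd(avg$displacement)
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 5.5)
  ## grids must match exactly; no silent resampling
  off <- displacement_trace(rnorm(n, sd = 5e-9), sampling_rate = 9999)
  expect_error(average_repetitions(list(reps[[1]], off)), "grids")
})

test_that("a noisy step average stays inside the Monte-Carlo envelope", {
  ## 25 averaged repetitions of a 100-nm step at SNR 10: the average must
  ## stay within ~4 sd of the clean step (sd of the mean = 2 nm)
  spec <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
                             drag = 229.5e-9)
  cfg0 <- generator_config(seed = 0, sampling_rate = 1e5, duration = 30e-3,
                           noise_sd = 0)
  clean <- generate_step_response(spec, 2e-3, 28e-3, cfg0)
  reps <- lapply(1:25, function(i) generate_step_response(
    spec, 2e-3, 28e-3,
    generator_config(seed = 100 + i, sampling_rate = 1e5,
                     duration = 30e-3, noise_sd = 10e-9)))
  avg <- average_repetitions(reps)
  expect_lt(max(abs(avg$displacement - clean$displacement)), 4 * 10e-9 / 5)
})

test_that("onset fits are exact on noiseless exponentials", {
  for (tau in c(100e-6, 250e-6, 500e-6, 1000e-6, 2000e-6)) {
    fit <- fit_onset(make_onset_trace(tau))
    expect_equal(fit$time_constant, tau, tolerance = 1e-9)
    expect_equal(fit$amplitude, 100e-9, tolerance = 1e-9)
    expect_gt(fit$r_squared, 1 - 1e-12)
  }
  ## the 335-us reference case through the synthetic generator
  spec <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
                             drag = 167.5e-9)
  cfg <- generator_config(seed = 1, sampling_rate = 1e5, duration = 30e-3,
                          noise_sd = 0)
  tr <- generate_step_response(spec, 2e-3, 28e-3, cfg)
  fit <- fit_onset(tr)
  expect_equal(fit$time_constant, 335e-6, tolerance = 1e-3)
  expect_error(fit_onset(make_onset_trace(500e-6), onset = NULL,
                         exclusion_window = 1),
               "samples")
  flat <- displacement_trace(rep(1e-9, 1000), sampling_rate = 1e5,
                             stimulus_onset = 1e-3)
  expect_error(fit_onset(flat), "flat")
})

test_that("onset fits recover tau within 5% at SNR 10 with 25 averages", {
  ## 459-us rise, 100-nm step, 10-nm measurement noise per repetition
  spec <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
                             drag = 229.5e-9)
  reps <- lapply(1:25, function(i) generate_step_response(
    spec, 2e-3, 28e-3,
    generator_config(seed = 200 + i, sampling_rate = 1e5,
                     duration = 30e-3, noise_sd = 10e-9)))
  fit <- fit_onset(average_repetitions(reps))
  expect_lt(abs(fit$time_constant - 459e-6) / 459e-6, 0.05)
})

test_that("adaptation summaries read out programmed sag and twitch", {
  ## pure step: no sag, no undershoot, no twitch
  spec0 <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
                              drag = 150e-9)
  cfg0 <- generator_config(seed = 3, sampling_rate = 2e4, duration = 0.12,
                           noise_sd = 0)
  s0 <- summarize_adaptation(generate_step_response(spec0, 0.02, 0.1, cfg0))
  expect_equal(s0$sag_fraction, 0, tolerance = 1e-6)
  expect_lt(s0$twitch_amplitude, 1e-9)
  expect_gt(s0$undershoot, -1e-12)
  ## 30% programmed sag comes back within +/- 0.02
  spec_sag <- step_stimulus_spec(force = 1e-10, stiffness = 500e-6,
                                 drag = 150e-9, sag_fraction = 0.3,
                                 adaptation_tau = 50e-3)
  cfg <- generator_config(seed = 4, sampling_rate = 2e4, duration = 0.5,
                          noise_sd = 2e-9)
  s <- summarize_adaptation(generate_step_response(spec_sag, 0.02, 0.42, cfg))
  expect_lt(abs(s$sag_fraction - 0.30), 0.02)
  ## adaptation produces an undershoot below baseline after offset
  expect_lt(s$undershoot, -10e-9)
  ## a 10-nm twitch against a 50-nm step
  spec_tw <- step_stimulus_spec(force = 25e-12, stiffness = 500e-6,
                                drag = 150e-9, twitch_amplitude = 10e-9,
                                twitch_tau = 2e-3)
  cfg_tw <- generator_config(seed = 5, sampling_rate = 2e4, duration = 0.12,
                             noise_sd = 1e-9)
  stw <- summarize_adaptation(
    generate_step_response(spec_tw, 0.02, 0.1, cfg_tw))
  ## min-statistic bias over ~1600 noisy samples is up to ~4 noise sd
  expect_lt(abs(stw$twitch_amplitude - 10e-9), 4e-9)
})

test_that("power spectra are Parseval-consistent", {
  ## unit 2-Hz sinusoid: integrated power 0.5 (rect window, whole cycles)
  fs <- 200
  t <- seq(0, 40.96 - 1 / fs, by = 1 / fs)
  sine <- displacement_trace(sin(2 * pi * 2 * t), sampling_rate = fs)
  ps <- power_spectrum(sine, segment_length = 2000, window = "rect")
  expect_equal(sum(ps$psd) * ps$df, 0.5, tolerance = 0.01)
  expect_equal(ps$frequency[which.max(ps$psd)], 2, tolerance = 0.05)
  ## white noise of known variance integrates to that variance
  set.seed(99)
  wn <- displacement_trace(rnorm(16384, sd = 3e-9), sampling_rate = 1000)
  pw <- power_spectrum(wn)
  expect_equal(sum(pw$psd) * pw$df, 9e-18, tolerance = 0.05)
  expect_error(power_spectrum(wn, segment_length = 1e6), "too short")
})

test_that("OU spectra match the analytic Lorentzian around the corner", {
  k <- 500e-6
  lam <- 150e-9
  cfg <- generator_config(seed = 21, sampling_rate = 2e4, duration = 5.12,
                          noise_sd = 0)
  tr <- generate_ou_trace(k, lam, 298, cfg)
  ps <- power_spectrum(tr, segment_length = 512)
  fc <- k / (2 * pi * lam)                 # 530 Hz corner
  band <- ps$frequency >= fc / 3 & ps$frequency <= 3 * fc
  rel <- ps$psd[band] / ou_psd(ps$frequency[band], k, lam, 298) - 1
  expect_lt(sqrt(mean(rel^2)), 0.10)
})

test_that("double-Lorentzian fits recover model and generator peaks", {
  ## exact model input: the fit must return the generating parameters
  f <- seq(0, 20, by = 0.05)
  S <- photonforce:::.dlor_model(f, a1 = 1e-16, w1 = 0.3, f0 = 2,
                                 a2 = 3e-17, w2 = 0.5, floor_ = 1e-19)
  sp <- structure(list(frequency = f, psd = S, df = 0.05, n_segments = 1,
                       segment_length = length(f),
                       segment_psd = matrix(S), window = "hann",
                       sampling_rate = 40),
                  class = "power_spectrum")
  fit <- fit_double_lorentzian(sp)
  expect_equal(fit$peak_frequency, 2, tolerance = 1e-6)
  expect_equal(unname(fit$half_widths["peak"]), 0.3, tolerance = 1e-4)
  ## a peak-free model degenerates to f0 below the peak width
  S0 <- photonforce:::.dlor_model(f, a1 = 1e-16, w1 = 0.5, f0 = 0,
                                  a2 = 0, w2 = 0.5, floor_ = 1e-19)
  sp0 <- sp; sp0$psd <- S0
  fit0 <- fit_double_lorentzian(sp0)
  expect_lt(fit0$peak_frequency, fit0$half_widths["peak"])
  ## noisy synthetic oscillators: ten seeds, 10% recovery
  for (seed in 1:10) {
    cfg <- generator_config(seed = seed, sampling_rate = 200, duration = 60,
                            noise_sd = 1e-9)
    tr <- generate_oscillation(2, rms_amplitude = 10e-9, quality = 5, cfg)
    fit <- fit_double_lorentzian(power_spectrum(tr))
    expect_lt(abs(fit$peak_frequency - 2) / 2, 0.10)
  }
})

test_that("pre/post comparison detects null, frequency and amplitude changes", {
  mk <- function(seed, f0 = 2, rms = 10e-9)
    generate_oscillation(f0, rms, quality = 5,
                         generator_config(seed = seed, sampling_rate = 200,
                                          duration = 60, noise_sd = 1e-9))
  pre <- mk(31)
  ## identical records: no change and a CI that straddles zero
  same <- compare_pre_post(pre, pre, n_boot = 40, seed = 7)
  expect_equal(same$peak_frequency_change_hz, 0)
  expect_equal(same$amplitude_change_fraction, 0)
  expect_lte(same$ci_frequency_change_hz[[1]], 0)
  expect_gte(same$ci_frequency_change_hz[[2]], 0)
  expect_identical(same$histograms$pre$counts, same$histograms$post$counts)
  ## post oscillating 1.5x faster: ~50% frequency change
  fast <- compare_pre_post(pre, mk(32, f0 = 3), n_boot = 10, seed = 7)
  expect_lt(abs(fast$peak_frequency_change_fraction - 0.5), 0.15)
  ## post at half the amplitude: ~-50% amplitude change
  quiet <- compare_pre_post(pre, mk(33, rms = 5e-9), n_boot = 10, seed = 7)
  expect_lt(abs(quiet$amplitude_change_fraction - (-0.5)), 0.07)
})
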