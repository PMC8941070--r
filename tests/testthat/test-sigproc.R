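test_that("acquisition config enforces its invariants", {
  expect_s3_class(acq_config(), "acq_config")
  expect_error(acq_config(sampling_rate = 10000), "Nyquist")
  expect_error(acq_config(bin_width = 0.3, srm_window = 1), "multiple")
  expect_error(acq_config(threshold_mult = 0), "positive")
  expect_error(acq_config(bin_width = 2, srm_window = 1), "bin_width")
})

test_that("band-pass filter removes DC, passes 1 kHz, rejects 50 Hz", {
  cfg <- acq_config()
  fs <- cfg$sampling_rate
  t <- seq(0, 1, by = 1 / fs)
  mid <- seq(round(0.2 * fs), round(0.8 * fs))  # avoid edge transients

  dc <- bandpass_filter(raw_trace(rep(100, length(t))), cfg)
  expect_lt(max(abs(dc$samples[mid])), 1e-6)

  # frequency-response oracle: |H|^2 of the 2nd-order Butterworth design,
  # evaluated directly on the unit circle; squared because filtfilt applies
  # the filter forward and backward
  bf <- signal::butter(2, c(cfg$band_low, cfg$band_high) / (fs / 2), "pass")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * z))^2
  }
  expect_gt(gain2(1000), 0.95)   # oracle: pass-band gain ~ 1 at 1 kHz
  expect_lt(gain2(50), 0.10)     # oracle: > 90% attenuation at 50 Hz
  y1k <- bandpass_filter(raw_trace(sin(2 * pi * 1000 * t)), cfg)
  expect_equal(max(abs(y1k$samples[mid])), gain2(1000), tolerance = 0.05)
  y50 <- bandpass_filter(raw_trace(sin(2 * pi * 50 * t)), cfg)
  expect_lt(max(abs(y50$samples[mid])), 0.10)
  bad <- acq_config()
  bad$band_high <- 15001  # past Nyquist; bypasses the constructor check
  expect_error(bandpass_filter(raw_trace(rnorm(1000)), bad), "Nyquist")
})

test_that("threshold detection matches the naive scan oracle and recovers injected spikes", {
  cfg <- acq_config()
  fs <- cfg$sampling_rate
  set.seed(41)
  n_spk <- 50
  spk_t <- sort(sample(seq(0.05, 1.95, by = 0.002), n_spk))
  ev_true <- spike_events(1, spk_t)
  wf <- waveform_model(amplitude = 150, noise_sd = 10)
  trace <- synthesize_raw_trace(ev_true, wf, cfg, duration = 2, seed = 7)
  filt <- bandpass_filter(trace, cfg)
  det <- detect_threshold_crossings(filt, cfg)

  # exact agreement with a per-sample linear scan at the same threshold
  oracle_idx <- naive_crossing_scan(filt$samples, det$threshold,
                                    cfg$lockout * fs)
  expect_equal(round((det$times - filt$t0) * fs) + 1, as.numeric(oracle_idx))

  # one event per injected spike, each within the waveform of the true peak
  expect_equal(length(det$times), n_spk)
  d <- vapply(det$times, function(tt) min(abs(tt - spk_t)), numeric(1))
  expect_lt(max(d), 0.0012)
})

test_that("detection handles degenerate and sub-threshold traces and honors lockout", {
  cfg <- acq_config()
  expect_error(detect_threshold_crossings(raw_trace(rep(0, 1000)), cfg),
               "flat")
  quiet <- raw_trace(rnorm(30000, sd = 1))
  expect_length(detect_threshold_crossings(quiet, cfg, threshold = 50)$times, 0)

  # two crossings 0.5 ms apart with a 1 ms lockout collapse to one event
  x <- rep(0, 300)
  x[c(100, 115)] <- -100  # 15 samples apart = 0.5 ms at 30 kS/s
  det <- detect_threshold_crossings(raw_trace(x), cfg, threshold = 45)
  expect_length(det$times, 1)
  det2 <- detect_threshold_crossings(raw_trace(x),
                                     acq_config(lockout = 0.0004),
                                     threshold = 45)
  expect_length(det2$times, 2)
})

test_that("binned counts follow the half-open convention and conserve events", {
  cfg <- acq_config(bin_width = 0.05, srm_window = 1)
  ev <- spike_events(1, c(0.010, 0.020, 0.060))
  bc <- bin_spike_counts(ev, cfg, span = c(0, 0.1))
  expect_equal(bc$counts, c(2, 1))
  expect_equal(bin_spike_counts(spike_events(1, numeric(0)), cfg,
                                c(0, 0.5))$counts, rep(0, 10))
  expect_error(bin_spike_counts(ev, cfg, span = c(1, 1)), "span")

  set.seed(11)
  tt <- sort(runif(1000, 0, 7.3))
  bc <- bin_spike_counts(spike_events(2, tt), cfg, span = c(0, 7.35))
  expect_equal(sum(bc$counts), 1000)
})

test_that("the spike rate metric is the trailing-window bin mean, with warm-up flagged", {
  cfg <- acq_config()
  bc <- binned_counts(1, rep(3, 40), 0.05, t0 = 0)
  rs <- spike_rate_metric(bc, t = 2, cfg)
  expect_equal(rs$srm, 3)
  expect_false(rs$warm_up)

  bc2 <- binned_counts(1, c(rep(0, 10), rep(2, 10)), 0.05, t0 = 0)
  expect_equal(spike_rate_metric(bc2, t = 1, cfg)$srm, 1)

  set.seed(5)
  counts <- rpois(100, 2)
  bc3 <- binned_counts(1, counts, 0.05, t0 = 0)
  for (t in c(1.0, 2.37, 5.0)) {
    expect_equal(spike_rate_metric(bc3, t, cfg)$srm,
                 brute_srm(counts, 0, 0.05, t, 20))
  }
  warm <- spike_rate_metric(bc3, t = 0.5, cfg)
  expect_true(warm$warm_up)
  expect_equal(warm$srm, mean(counts[1:10]))
  expect_error(spike_rate_metric(bc3, t = 0.01, cfg), "no complete bins")
})

test_that("the SRM is translation-equivariant in event times", {
  cfg <- acq_config()
  set.seed(9)
  tt <- sort(runif(400, 0, 10))
  bc1 <- bin_spike_counts(spike_events(1, tt), cfg, c(0, 10))
  bc2 <- bin_spike_counts(spike_events(1, tt + 0.15), cfg, c(0.15, 10.15))
  expect_equal(spike_rate_metric(bc1, 4, cfg)$srm,
               spike_rate_metric(bc2, 4.15, cfg)$srm)
  expect_equal(spike_rate_metric(bc1, 9.8, cfg)$srm,
               spike_rate_metric(bc2, 9.95, cfg)$srm)
})

test_that("spike events and counts round-trip through CSV", {
  ev <- spike_events(7, c(0.1, 0.25, 1.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_events(ev, f)
  back <- read_spike_events(f)
  expect_equal(back$times, ev$times)
  expect_equal(back$channel_id, 7L)
  f2 <- withr::local_tempfile(fileext = ".csv")
  bc <- binned_counts(7, c(1, 0, 2), 0.05)
  write_binned_counts(bc, f2)
  df <- read.csv(f2)
  expect_equal(df$count, c(1, 0, 2))
  expect_equal(df$t_bin_start_s, c(0, 0.05, 0.1))
})
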