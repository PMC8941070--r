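test_that("the intent agent pursues the cue after its reaction time", {
  sched <- data.frame(target = c("up", "down"), cue_duration = 1,
                      response_duration = 3)
  tr <- simulate_intent_trace(sched, intent_agent(1, 0, reaction_time = 0.5),
                              seed = 3)
  up <- tr[tr$trial == 1, ]
  expect_true(all(up$intent[up$phase == "cue"] == 0.5))
  expect_true(all(up$intent[up$t >= 0.5] == 1))
  down <- tr[tr$trial == 2, ]
  expect_true(all(down$intent[down$t >= 0.5] == 0))

  flat <- simulate_intent_trace(sched, intent_agent(0), seed = 3)
  expect_true(all(flat$intent == 0.5))

  expect_identical(simulate_intent_trace(sched, intent_agent(1, 0.2), seed = 5),
                   simulate_intent_trace(sched, intent_agent(1, 0.2), seed = 5))
  expect_error(simulate_intent_trace(sched[0, ], intent_agent()), "empty")
})

test_that("simulated counts are Poisson with the intent-interpolated mean", {
  silent <- channel_truth(1, 0, 0)
  bc <- simulate_channel_counts(silent, rep(0.5, 40), 0.25, duration = 10,
                                seed = 1)
  expect_true(all(bc$counts == 0))

  const <- channel_truth(1, 20, modulated = FALSE)
  bc <- simulate_channel_counts(const, rep(0.5, 4), 0.25, duration = 100,
                                seed = 2)
  expect_lt(abs(sum(bc$counts) - 2000), 3 * sqrt(2000))

  # square-wave intent: high windows hit rate_high, low windows rate_low
  mod <- channel_truth(1, 5, 80)
  intent <- rep(rep(c(1, 0), each = 8), 25)  # 2 s on / 2 s off, 100 s total
  bc <- simulate_channel_counts(mod, intent, 0.25, duration = 100, seed = 4)
  hi <- rep(rep(c(TRUE, FALSE), each = 40), 25)
  expect_equal(mean(bc$counts[hi]), 80 * 0.05, tolerance = 0.05)
  expect_equal(mean(bc$counts[!hi]), 5 * 0.05, tolerance = 0.3)

  expect_error(channel_truth(1, -5, 10), "non-negative")
})

test_that("the intent-to-rate latency lags the rate change", {
  mod <- channel_truth(1, 0, 1000, latency = 0.5)
  intent <- c(rep(0, 20), rep(1, 20))  # step at t = 5 s
  bc <- simulate_channel_counts(mod, intent, 0.25, duration = 10, seed = 6)
  # bins centred in (5, 5.5) still see intent 0 through the 0.5 s lag
  expect_true(all(bc$counts[101:109] == 0))
  expect_gt(mean(bc$counts[111:200]), 30)
})

test_that("synthesized traces support near-perfect detection at high SNR", {
  cfg <- acq_config()
  # pure noise: a >= 8 sigma manual threshold yields (almost) no events
  noise <- synthesize_raw_trace(spike_events(1, numeric(0)),
                                waveform_model(noise_sd = 10), cfg,
                                duration = 1, seed = 11)
  det0 <- detect_threshold_crossings(bandpass_filter(noise, cfg), cfg,
                                     threshold = 80)
  expect_lte(length(det0$times), 1)

  # 100 spikes at 10 sigma: at least 95 recovered
  tt <- seq(0.05, 2.95, length.out = 100)
  tr <- synthesize_raw_trace(spike_events(1, tt),
                             waveform_model(amplitude = 100, noise_sd = 10),
                             cfg, duration = 3, seed = 12)
  det <- detect_threshold_crossings(bandpass_filter(tr, cfg), cfg)
  hits <- sum(vapply(tt, function(t0) any(abs(det$times - t0) < 0.0015),
                     logical(1)))
  expect_gte(hits, 95)

  # zero noise: every spike found, at a fixed offset from the true peaks
  tr0 <- synthesize_raw_trace(spike_events(1, tt),
                              waveform_model(amplitude = 100, noise_sd = 0),
                              cfg, duration = 3, seed = 13)
  det0 <- detect_threshold_crossings(bandpass_filter(tr0, cfg), cfg)
  expect_equal(length(det0$times), 100)
  offs <- det0$times - tt
  expect_lt(max(abs(offs)), 0.0012)
  expect_lt(diff(range(offs)), 1e-4 + 1e-9)  # rigid offset: crossing precedes peak

  expect_error(synthesize_raw_trace(spike_events(1, 0.001),
                                    waveform_model(), cfg, duration = 0.0005),
               "template")
})

test_that("closed-loop blocks are reproducible from (config, seed)", {
  truth <- default_truth()
  mix <- default_mixer(truth)
  b1 <- simulate_feedback_block(truth, mix, intent_agent(1, 0.05), seed = 314)
  b2 <- simulate_feedback_block(truth, mix, intent_agent(1, 0.05), seed = 314)
  expect_identical(b1$targets, b2$targets)
  expect_identical(b1$accuracy, b2$accuracy)
  expect_identical(lapply(b1$trials, `[[`, "r_trace"),
                   lapply(b2$trials, `[[`, "r_trace"))
  b3 <- simulate_feedback_block(truth, mix, intent_agent(1, 0.05), seed = 315)
  expect_false(identical(lapply(b1$trials, `[[`, "r_trace"),
                         lapply(b3$trials, `[[`, "r_trace")))
})

test_that("a compliant agent achieves high closed-loop accuracy, a lapsing one less", {
  truth <- default_truth()
  mix <- default_mixer(truth)
  accs <- vapply(1:8, function(s)
    simulate_feedback_block(truth, mix, intent_agent(1, 0), seed = s,
                            keep_srm = FALSE)$accuracy, numeric(1))
  expect_gte(mean(accs), 0.95)
  lapse <- vapply(1:8, function(s)
    simulate_feedback_block(truth, mix, intent_agent(1, 0.6), seed = s,
                            keep_srm = FALSE)$accuracy, numeric(1))
  expect_lt(mean(lapse), mean(accs))
})

test_that("reward events appear when the tone is held at the target", {
  truth <- default_truth()
  mix <- default_mixer(truth)
  b <- simulate_feedback_block(truth, mix, intent_agent(1, 0), n_up = 4,
                               n_down = 4, paradigm = "reward", seed = 21)
  n_rewards <- sum(vapply(b$trials, function(tr) length(tr$reward_events),
                          numeric(1)))
  expect_gt(n_rewards, 0)
})
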