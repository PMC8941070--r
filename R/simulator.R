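#' Ground-truth firing behaviour of one simulated channel
#'
#' A channel fires as an inhomogeneous Poisson process whose rate moves
#' between `rate_low` (intent 0) and `rate_high` (intent 1) by linear
#' interpolation in the agent's intent, with an optional intent-to-rate lag
#' and optional Gaussian jitter on the instantaneous rate. Unmodulated
#' channels fire at the constant `rate_low`. A channel whose rate drops when
#' the agent pushes "up" is expressed as `rate_low > rate_high`.
#'
#' @param channel_id Integer channel identifier.
#' @param rate_low,rate_high Firing rates (spikes/s) at intent 0 and 1.
#' @param modulated Does intent drive this channel's rate? (default TRUE).
#' @param latency Intent-to-rate delay in seconds (default 0).
#' @param rate_noise_sd SD of fast per-bin rate jitter in spikes/s (default 0).
#' @param drift_sd Stationary SD (spikes/s) of a slow AR(1) rate drift
#'   emulating cortical firing-rate nonstationarity (default 0).
#' @param drift_tau Time constant of the drift in seconds (default 3).
#' @return An object of class `channel_truth`.
#' @export
channel_truth <- function(channel_id, rate_low, rate_high = rate_low,
                          modulated = TRUE, latency = 0, rate_noise_sd = 0,
                          drift_sd = 0, drift_tau = 3) {
  if (rate_low < 0 || rate_high < 0) stop("rates must be non-negative")
  if (latency < 0) stop("latency must be non-negative")
  if (rate_noise_sd < 0 || drift_sd < 0) stop("noise SDs must be non-negative")
  if (drift_tau <= 0) stop("drift_tau must be positive")
  structure(list(channel_id = as.integer(channel_id), rate_low = rate_low,
                 rate_high = rate_high, modulated = isTRUE(modulated),
                 latency = latency, rate_noise_sd = rate_noise_sd,
                 drift_sd = drift_sd, drift_tau = drift_tau),
            class = "channel_truth")
}

#' Scriptable intent agent
#'
#' Emulates volitional rate modulation at the granularity of the 250 ms
#' feedback interaction: on each trial the agent pursues the cued target with
#' probability `compliance` (pushing its intent to 1 for "up", 0 for "down"
#' once `reaction_time` has passed), suffers transient lapses back to the
#' 0.5 baseline with per-interaction probability `lapse_rate`, and otherwise
#' rests at baseline.
#'
#' @param compliance Probability of pursuing the cued target on a trial.
#' @param lapse_rate Per-interaction probability of a transient lapse.
#' @param reaction_time Seconds from response onset until intent reaches the
#'   target level (default 0.5).
#' @return An object of class `intent_agent`.
#' @export
intent_agent <- function(compliance = 1, lapse_rate = 0, reaction_time = 0.5) {
  if (compliance < 0 || compliance > 1) stop("compliance must lie in [0, 1]")
  if (lapse_rate < 0 || lapse_rate > 1) stop("lapse_rate must lie in [0, 1]")
  if (reaction_time < 0) stop("reaction_time must be non-negative")
  structure(list(compliance = compliance, lapse_rate = lapse_rate,
                 reaction_time = reaction_time), class = "intent_agent")
}

# Intent levels for one trial, one value per interaction. Baseline 0.5
# during the cue and the reaction time, then the target level (1 up / 0 down)
# on compliant trials, with transient lapses.
trial_intent <- function(target, agent, n_cue, n_resp, update_interval) {
  intent <- rep(0.5, n_cue + n_resp)
  comply <- runif(1) < agent$compliance
  if (comply && n_resp > 0) {
    rt_int <- ceiling(agent$reaction_time / update_interval - 1e-9)
    level <- if (target == "up") 1 else 0
    from <- n_cue + rt_int + 1L
    if (from <= n_cue + n_resp) intent[from:(n_cue + n_resp)] <- level
  }
  if (agent$lapse_rate > 0) {
    lapse <- runif(length(intent)) < agent$lapse_rate
    intent[lapse] <- 0.5
  }
  intent
}

#' Simulate an intent trace over a task schedule
#'
#' @param schedule Data frame with one row per trial: columns `target`
#'   ("up"/"down"), `cue_duration` and `response_duration` in seconds.
#' @param agent An [intent_agent()].
#' @param update_interval Interaction length in seconds (default 0.25).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return Data frame with columns `trial`, `interaction`, `t` (s from trial
#'   start, cue at negative times), `phase` and `intent`.
#' @export
simulate_intent_trace <- function(schedule, agent = intent_agent(),
                                  update_interval = 0.25, seed = NULL) {
  if (is.null(schedule) || !nrow(schedule)) stop("empty schedule")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(schedule)), function(i) {
      n_cue <- round(schedule$cue_duration[i] / update_interval)
      n_resp <- round(schedule$response_duration[i] / update_interval)
      intent <- trial_intent(schedule$target[i], agent, n_cue, n_resp,
                             update_interval)
      data.frame(trial = i, interaction = seq_along(intent),
                 t = (seq_along(intent) - n_cue - 1) * update_interval,
                 phase = rep(c("cue", "response"), c(n_cue, n_resp)),
                 intent = intent)
    })
    do.call(rbind, out)
  })
}

#' Simulate binned spike counts for one channel
#'
#' Counts are Poisson with per-bin mean `rate * bin_width`, where the rate
#' interpolates `rate_low` to `rate_high` by the (lagged) intent for modulated
#' channels and is the constant `rate_low` otherwise.
#'
#' @param truth A [channel_truth()].
#' @param intent Numeric intent trace in `[0, 1]`.
#' @param intent_dt Time step of the intent trace in seconds.
#' @param duration Total duration to simulate in seconds.
#' @param bin_width Count bin width in seconds (default 0.05).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return A [binned_counts()] object.
#' @export
simulate_channel_counts <- function(truth, intent, intent_dt, duration,
                                    bin_width = 0.05, seed = NULL) {
  stopifnot(inherits(truth, "channel_truth"))
  if (duration <= 0) stop("duration must be positive")
  with_seed(seed, {
    n_bins <- round(duration / bin_width)
    t_mid <- (seq_len(n_bins) - 0.5) * bin_width
    if (truth$modulated) {
      idx <- pmin(pmax(floor((t_mid - truth$latency) / intent_dt) + 1L, 1L),
                  length(intent))
      lam <- truth$rate_low + intent[idx] * (truth$rate_high - truth$rate_low)
    } else {
      lam <- rep(truth$rate_low, n_bins)
    }
    if (truth$rate_noise_sd > 0)
      lam <- lam + rnorm(n_bins, 0, truth$rate_noise_sd)
    if (truth$drift_sd > 0) {
      phi <- exp(-bin_width / truth$drift_tau)
      innov <- rnorm(n_bins, 0, truth$drift_sd * sqrt(1 - phi^2))
      innov[1] <- rnorm(1, 0, truth$drift_sd)
      lam <- lam + as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    lam <- pmax(lam, 0)
    binned_counts(truth$channel_id, rpois(n_bins, lam * bin_width),
                  bin_width, t0 = 0)
  })
}

#' Extracellular spike waveform and noise model
#'
#' @param template Waveform samples with peak magnitude normalized to 1
#'   (default: a biphasic template with a sharp negative lobe and a slower
#'   positive rebound, about 1.2 ms at 30 kS/s).
#' @param amplitude Peak amplitude in microvolts (default 100).
#' @param amplitude_sd Relative SD of per-spike amplitude jitter (default 0).
#' @param noise_sd Broadband Gaussian noise SD in microvolts (default 10).
#' @param sampling_rate Samples/s used for the default template.
#' @return An object of class `waveform_model`.
#' @export
waveform_model <- function(template = NULL, amplitude = 100, amplitude_sd = 0,
                           noise_sd = 10, sampling_rate = 30000) {
  if (is.null(template)) template <- biphasic_template(sampling_rate)
  if (max(abs(template)) == 0) stop("template must be non-zero")
  template <- template / max(abs(template))
  if (amplitude_sd < 0 || noise_sd < 0) stop("SDs must be non-negative")
  structure(list(template = template, amplitude = amplitude,
                 amplitude_sd = amplitude_sd, noise_sd = noise_sd,
                 peak_index = which.max(abs(template))),
            class = "waveform_model")
}

#' @rdname waveform_model
#' @param duration Template duration in seconds (default 0.0012).
#' @export
biphasic_template <- function(sampling_rate = 30000, duration = 0.0012) {
  tt <- seq(0, duration, by = 1 / sampling_rate)
  w <- -exp(-((tt - 3e-4) / 1.2e-4)^2) + 0.35 * exp(-((tt - 7e-4) / 2.5e-4)^2)
  w / max(abs(w))
}

#' Synthesize a raw voltage trace from spike events
#'
#' Gaussian broadband noise plus the scaled waveform template added at each
#' event time (template peak aligned to the event), exercising the detection
#' chain end to end.
#'
#' @param events A [spike_events()] object; times must fall inside the trace.
#' @param wf A [waveform_model()].
#' @param cfg An [acq_config()] (for the sampling rate).
#' @param duration Trace duration in seconds (default: past the last event).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return A [raw_trace()].
#' @export
synthesize_raw_trace <- function(events, wf = waveform_model(),
                                 cfg = acq_config(), duration = NULL,
                                 seed = NULL) {
  stopifnot(inherits(events, "spike_events"), inherits(wf, "waveform_model"))
  fs <- cfg$sampling_rate
  if (is.null(duration))
    duration <- (if (length(events$times)) max(events$times) else 0) + 0.01
  n <- round(duration * fs)
  L <- length(wf$template)
  if (L > n) stop("template longer than trace")
  with_seed(seed, {
    x <- rnorm(n, 0, wf$noise_sd)
    for (tt in events$times) {
      s <- round((tt - 0) * fs) + 1L
      start <- s - wf$peak_index + 1L
      idx <- start:(start + L - 1L)
      ok <- idx >= 1L & idx <= n
      if (!any(ok)) stop("event time outside trace span")
      amp <- wf$amplitude * (1 + if (wf$amplitude_sd > 0)
        rnorm(1, 0, wf$amplitude_sd) else 0)
      x[idx[ok]] <- x[idx[ok]] + amp * wf$template[ok]
    }
    raw_trace(x, events$channel_id, t0 = 0)
  })
}

#' A desk-scale simulated electrode array
#'
#' Convenience ground truth: `n_channels` channels of which `modulated_ids`
#' are intent-modulated between `rate_low` and `rate_high` spikes/s (about a
#' 10-sigma separation of the 1 s spike rate metric at the defaults); the
#' remaining channels fire at background rates cycling through
#' `background_rates`. All channels carry a slow AR(1) rate drift
#' (`drift_sd` spikes/s, time constant `drift_tau` s) emulating the
#' within-session firing-rate nonstationarity of chronic recordings.
#'
#' @param n_channels Array size (default 16; 128 supported).
#' @param modulated_ids Channel ids that follow intent (default `c(3, 11)`).
#' @param rate_low,rate_high Modulated-channel rates (defaults 5 and 80).
#' @param background_rates Baseline rates for unmodulated channels.
#' @param latency Intent-to-rate lag of modulated channels (s).
#' @param drift_sd,drift_tau Slow-drift SD (spikes/s) and time constant (s),
#'   defaults 10 and 3.
#' @return A list of [channel_truth()] objects.
#' @export
array_truth <- function(n_channels = 16, modulated_ids = c(3, 11),
                        rate_low = 5, rate_high = 80,
                        background_rates = c(8, 15, 25, 40), latency = 0,
                        drift_sd = 10, drift_tau = 3) {
  stopifnot(all(modulated_ids <= n_channels))
  bg <- rep(background_rates, length.out = n_channels)
  lapply(seq_len(n_channels), function(i) {
    if (i %in% modulated_ids)
      channel_truth(i, rate_low, rate_high, modulated = TRUE,
                    latency = latency, drift_sd = drift_sd,
                    drift_tau = drift_tau)
    else
      channel_truth(i, bg[i], modulated = FALSE, drift_sd = drift_sd,
                    drift_tau = drift_tau)
  })
}

#' Mixer matched to the simulator's ground truth
#'
#' Sets each channel's normalization bounds to its true SRM extremes
#' (`rate * bin_width`) with the sign implied by the rate ordering.
#'
#' @param truth List of [channel_truth()] (e.g. [array_truth()]).
#' @param channel_ids Channels to include in the mixer.
#' @param bin_width Count bin width in seconds (default 0.05).
#' @return A [mixer_config()].
#' @export
mixer_from_truth <- function(truth, channel_ids, bin_width = 0.05) {
  ids <- vapply(truth, `[[`, integer(1), "channel_id")
  mixer_config(lapply(channel_ids, function(id) {
    tr <- truth[[match(id, ids)]]
    lo <- min(tr$rate_low, tr$rate_high) * bin_width
    hi <- max(tr$rate_low, tr$rate_high) * bin_width
    channel_params(id, lo, hi, c = if (tr$rate_high >= tr$rate_low) 1 else -1)
  }))
}

#' Simulate a closed-loop neurofeedback block
#'
#' The full loop at count granularity: for each trial the agent's intent
#' drives every channel's Poisson counts in 50 ms bins, the trailing-window
#' SRM is computed per channel, the mixer's channels are normalized and mixed,
#' and the resulting rate per 250 ms update feeds the hold-threshold decision
#' machine via [run_feedback_trial()]. Trials carry the per-channel SRM
#' traces, so [estimate_channel_params()] can run on the output.
#'
#' @param truth List of [channel_truth()] (e.g. [array_truth()]).
#' @param mixer A [mixer_config()] over a subset of the truth channels.
#' @param agent An [intent_agent()].
#' @param n_up,n_down Trials per target (defaults 10 and 10).
#' @param acq An [acq_config()] (bin width, SRM window).
#' @param fb_cfg,dec_cfg,reward_cfg,cue_duration As in [run_feedback_block()].
#' @param paradigm Paradigm label.
#' @param seed Integer seed; the whole block is reproducible from it.
#' @param keep_srm Attach per-channel SRM matrices to each trial (default
#'   TRUE; needed for calibration).
#' @return A `block_record` whose trials additionally carry `channel_srm`.
#' @export
simulate_feedback_block <- function(truth, mixer, agent = intent_agent(),
                                    n_up = 10, n_down = 10,
                                    acq = acq_config(),
                                    fb_cfg = feedback_config(),
                                    dec_cfg = decision_config(),
                                    reward_cfg = NULL,
                                    paradigm = c("no_reward", "reward",
                                                 "question"),
                                    cue_duration = 1, seed = NULL,
                                    keep_srm = TRUE) {
  paradigm <- match.arg(paradigm)
  if (paradigm != "reward") reward_cfg <- NULL
  if (paradigm == "reward" && is.null(reward_cfg)) reward_cfg <- reward_config()
  ui <- fb_cfg$update_interval
  bins_per_int <- round(ui / acq$bin_width)
  n_cue <- round(cue_duration / ui)
  n_resp <- ceiling(dec_cfg$response_timeout / ui)
  n_int <- n_cue + n_resp
  ids <- vapply(truth, `[[`, integer(1), "channel_id")
  with_seed(seed, {
    targets <- sample(c(rep("up", n_up), rep("down", n_down)))
    trials <- lapply(seq_along(targets), function(i) {
      intent <- trial_intent(targets[i], agent, n_cue, n_resp, ui)
      srm <- vapply(truth, function(tr) {
        bc <- simulate_channel_counts(tr, intent, intent_dt = ui,
                                      duration = n_int * ui,
                                      bin_width = acq$bin_width)
        srm_series(bc, acq)[seq_len(n_int) * bins_per_int]
      }, numeric(n_int))
      colnames(srm) <- as.character(ids)
      r <- normalize_and_mix(srm[(n_cue + 1):n_int, , drop = FALSE], mixer)
      trial <- run_feedback_trial(targets[i], r, fb_cfg = fb_cfg,
                                  dec_cfg = dec_cfg, reward_cfg = reward_cfg,
                                  cue_duration = cue_duration)
      if (keep_srm) trial$channel_srm <- srm[(n_cue + 1):n_int, , drop = FALSE]
      trial
    })
    new_block_record(trials, targets, seed, paradigm)
  })
}
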