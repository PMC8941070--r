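#' Per-channel normalization parameters
#'
#' Each control channel carries a calibration triple: the firing-rate bounds
#' `[a, b]` to which its spike rate metric is clamped before normalization to
#' `[0, 1]`, and a sign `c` that optionally inverts the channel (`c = -1`
#' for channels whose rate falls when the patient intends "yes").
#'
#' @param channel_id Integer channel identifier.
#' @param a,b Lower and upper rate bounds, in SRM units (spikes per bin);
#'   `b > a` required.
#' @param c Inversion flag, `+1` or `-1`.
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(channel_id, a, b, c = 1) {
  if (!is.numeric(a) || !is.numeric(b) || b <= a)
    stop("require rate bounds b > a")
  if (!c %in% c(-1, 1)) stop("inversion flag c must be +1 or -1")
  structure(list(channel_id = as.integer(channel_id), a = a, b = b, c = c),
            class = "channel_params")
}

#' Mixer over one or more control channels
#'
#' @param ... [channel_params()] objects, or a single list of them. Typically
#'   one to four channels are used for control.
#' @return An object of class `mixer_config`.
#' @export
#' @examples
#' mx <- mixer_config(channel_params(21, a = 0.5, b = 3.5, c = 1))
mixer_config <- function(...) {
  chans <- list(...)
  if (length(chans) == 1 && !inherits(chans[[1]], "channel_params"))
    chans <- chans[[1]]
  if (!length(chans)) stop("at least one channel required")
  if (!all(vapply(chans, inherits, logical(1), "channel_params")))
    stop("all arguments must be channel_params objects")
  ids <- vapply(chans, `[[`, integer(1), "channel_id")
  if (anyDuplicated(ids)) stop("channel ids must be unique")
  structure(list(channels = chans), class = "mixer_config")
}

#' @export
print.mixer_config <- function(x, ...) {
  cat(sprintf("<mixer_config> %d channel(s):\n", length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  channel %d: a = %.4g, b = %.4g, c = %+d\n",
                ch$channel_id, ch$a, ch$b, ch$c))
  invisible(x)
}

#' Normalize per-channel rates and mix into one control value
#'
#' Each channel's rate is clamped to `[a, b]`, normalized to `[0, 1]` and
#' optionally inverted, and the channel values are averaged:
#' the per-channel term is `(1 - c)/2 + c * (clamp(r, a, b) - a)/(b - a)`,
#' and the mixed rate is the mean of the terms, guaranteed to lie in `[0, 1]`.
#'
#' @param rates One rate per configured channel: a numeric vector in mixer
#'   channel order (optionally named by channel id), or a matrix with one
#'   column per channel and one row per time step.
#' @param mixer A [mixer_config()].
#' @return The mixed normalized rate(s) in `[0, 1]`; a scalar for a vector
#'   input, a vector for a matrix input.
#' @export
#' @examples
#' mx <- mixer_config(channel_params(1, a = 2, b = 10, c = 1),
#'                    channel_params(2, a = 0, b = 20, c = -1))
#' normalize_and_mix(c(6, 5), mx)  # 0.625
normalize_and_mix <- function(rates, mixer) {
  stopifnot(inherits(mixer, "mixer_config"))
  chans <- mixer$channels
  n <- length(chans)
  if (is.null(dim(rates))) {
    if (length(rates) != n)
      stop("need exactly one rate per configured channel")
    rates <- matrix(rates, nrow = 1,
                    dimnames = list(NULL, names(rates)))
    scalar <- TRUE
  } else {
    scalar <- FALSE
  }
  ids <- as.character(vapply(chans, `[[`, integer(1), "channel_id"))
  if (!is.null(colnames(rates)) && all(ids %in% colnames(rates)))
    rates <- rates[, ids, drop = FALSE]
  if (ncol(rates) != n)
    stop("need exactly one rate column per configured channel")
  if (anyNA(rates)) stop("missing channel rate")
  terms <- vapply(seq_len(n), function(j) {
    p <- chans[[j]]
    (1 - p$c) / 2 + p$c * (pmin(pmax(rates[, j], p$a), p$b) - p$a) / (p$b - p$a)
  }, numeric(nrow(rates)))
  terms <- matrix(terms, nrow = nrow(rates))
  r <- rowMeans(terms)
  if (scalar) r[[1]] else r
}

#' Auditory feedback configuration
#'
#' @param f_min,f_max Feedback tone range in Hz (defaults 120 and 480).
#' @param update_interval Feedback update period in seconds (default 0.250).
#' @param tone_duration Tone length in seconds (default 0.250, pure sine).
#' @return An object of class `feedback_config`.
#' @export
feedback_config <- function(f_min = 120, f_max = 480, update_interval = 0.25,
                            tone_duration = 0.25) {
  if (!(f_max > f_min && f_min > 0)) stop("require f_max > f_min > 0")
  if (update_interval <= 0) stop("update_interval must be positive")
  structure(list(f_min = f_min, f_max = f_max,
                 update_interval = update_interval,
                 tone_duration = tone_duration), class = "feedback_config")
}

#' Map a normalized rate to a feedback tone frequency
#'
#' Linear (affine, bijective) map from `[0, 1]` to `[f_min, f_max]`:
#' `f = f_min + r * (f_max - f_min)`.
#'
#' @param r Normalized rate(s) in `[0, 1]`; values outside error (clamping is
#'   the mixer's job).
#' @param cfg A [feedback_config()].
#' @return Frequency in Hz, same length as `r`.
#' @export
#' @examples
#' map_rate_to_tone(0.5)  # 300 Hz
map_rate_to_tone <- function(r, cfg = feedback_config()) {
  stopifnot(inherits(cfg, "feedback_config"))
  if (any(r < -1e-12 | r > 1 + 1e-12))
    stop("normalized rate must lie in [0, 1]")
  cfg$f_min + pmin(pmax(r, 0), 1) * (cfg$f_max - cfg$f_min)
}

#' Hold-threshold decision configuration
#'
#' A "yes" is committed when the normalized rate is held above `upper` for
#' `hold_interactions` feedback updates (500 ms at the defaults), a "no" when
#' held below `lower`; otherwise the trial times out. Comparisons are strict:
#' values at a threshold count as the dead zone.
#'
#' @param lower,upper Normalized thresholds (defaults 0.3 and 0.7).
#' @param hold_interactions Updates required beyond a threshold (default 2).
#' @param response_timeout Response period length in seconds (default 10).
#' @param consecutive If `TRUE` (default) the hold must be unbroken: the run
#'   counter resets on re-entering the dead zone or the opposite side.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(lower = 0.3, upper = 0.7, hold_interactions = 2,
                            response_timeout = 10, consecutive = TRUE) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("require 0 <= lower < upper <= 1")
  if (hold_interactions < 1) stop("hold_interactions must be >= 1")
  if (response_timeout <= 0) stop("response_timeout must be positive")
  structure(list(lower = lower, upper = upper,
                 hold_interactions = as.integer(hold_interactions),
                 response_timeout = response_timeout,
                 consecutive = isTRUE(consecutive)),
            class = "decision_config")
}

#' Reward configuration for the feedback-with-reward paradigm
#'
#' When the feedback tone is held within `tolerance` Hz of the target tone for
#' `hold_interactions` updates, a reward sound event is emitted.
#'
#' @param tolerance Half-width of the frequency band around the target (Hz).
#' @param hold_interactions Updates the tone must stay in band (default 2).
#' @param reward_duration Reward sound duration in seconds (default 0.250).
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(tolerance = 60, hold_interactions = 2,
                          reward_duration = 0.25) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (hold_interactions < 1) stop("hold_interactions must be >= 1")
  structure(list(tolerance = tolerance,
                 hold_interactions = as.integer(hold_interactions),
                 reward_duration = reward_duration), class = "reward_config")
}

#' Fresh decision state
#'
#' @return An object of class `decision_state` with run counters at zero,
#'   `elapsed = 0`, and outcome `"pending"`.
#' @export
decision_state <- function() {
  structure(list(run_high = 0L, run_low = 0L, elapsed = 0, n_steps = 0L,
                 outcome = "pending"), class = "decision_state")
}

#' Advance the yes/no decision state machine by one feedback update
#'
#' `r > upper` extends the high run (and, in consecutive mode, resets the low
#' run); `r < lower` symmetrically; values in the dead zone reset both runs in
#' consecutive mode. The outcome becomes `"yes"` (`"no"`) when the high (low)
#' run reaches `hold_interactions`, or `"timeout"` once `elapsed` reaches
#' `response_timeout` with no decision.
#'
#' @param state A pending [decision_state()].
#' @param r Normalized rate for this update.
#' @param cfg A [decision_config()].
#' @param dt Duration of one update in seconds (default 0.25).
#' @return The updated `decision_state`.
#' @export
step_decision <- function(state, r, cfg = decision_config(), dt = 0.25) {
  stopifnot(inherits(state, "decision_state"))
  if (state$outcome != "pending")
    stop("cannot step a decided state (outcome already ", state$outcome, ")")
  state$n_steps <- state$n_steps + 1L
  state$elapsed <- state$elapsed + dt
  if (r > cfg$upper) {
    state$run_high <- state$run_high + 1L
    if (cfg$consecutive) state$run_low <- 0L
  } else if (r < cfg$lower) {
    state$run_low <- state$run_low + 1L
    if (cfg$consecutive) state$run_high <- 0L
  } else if (cfg$consecutive) {
    state$run_high <- 0L
    state$run_low <- 0L
  }
  if (state$run_high >= cfg$hold_interactions) {
    state$outcome <- "yes"
  } else if (state$run_low >= cfg$hold_interactions) {
    state$outcome <- "no"
  } else if (state$elapsed >= cfg$response_timeout - 1e-9) {
    state$outcome <- "timeout"
  }
  state
}

# Standardize a rate source into a zero-argument closure yielding the next
# mixed normalized rate, or NULL on exhaustion.
as_rate_source <- function(rate_source) {
  if (is.function(rate_source)) return(rate_source)
  if (is.numeric(rate_source)) {
    i <- 0L
    v <- rate_source
    return(function() {
      i <<- i + 1L
      if (i > length(v)) NULL else v[[i]]
    })
  }
  stop("rate_source must be a numeric vector or a function")
}

#' Run one neurofeedback trial
#'
#' A target tone (480 Hz for "up", 120 Hz for "down") is presented during a
#' cue period, then the decision loop consumes one mixed normalized rate per
#' feedback update until the hold-threshold state machine commits yes, no, or
#' timeout. In the reward paradigm, holding the feedback tone within
#' `reward_cfg$tolerance` of the target for the reward hold count emits a
#' reward event.
#'
#' @param target `"up"` or `"down"`.
#' @param rate_source Numeric vector of mixed rates (one per update) or a
#'   zero-argument function yielding the next rate (`NULL` when exhausted).
#' @param fb_cfg A [feedback_config()].
#' @param dec_cfg A [decision_config()].
#' @param reward_cfg A [reward_config()], or `NULL` for no reward.
#' @param cue_duration Cue period in seconds (default 1).
#' @param log_tones Log one `feedback_tone` event per update (default FALSE;
#'   cue, reward and decision events are always logged).
#' @return An object of class `trial_record` with fields `target`, `outcome`,
#'   `correct`, `latency` (s), `r_trace`, `reward_events` and `events`.
#' @export
run_feedback_trial <- function(target = c("up", "down"), rate_source,
                               fb_cfg = feedback_config(),
                               dec_cfg = decision_config(),
                               reward_cfg = NULL, cue_duration = 1,
                               log_tones = FALSE) {
  target <- match.arg(target)
  src <- as_rate_source(rate_source)
  dt <- fb_cfg$update_interval
  f_target <- if (target == "up") fb_cfg$f_max else fb_cfg$f_min
  events <- list(session_event(-cue_duration, "cue",
                               target = target, f_target = f_target,
                               duration = cue_duration))
  state <- decision_state()
  r_trace <- numeric(0)
  reward_events <- numeric(0)
  reward_run <- 0L
  while (state$outcome == "pending") {
    r <- src()
    if (is.null(r))
      stop("rate source exhausted before a decision was reached (aborted trial)")
    t_now <- state$n_steps * dt
    r_trace <- c(r_trace, r)
    f <- map_rate_to_tone(r, fb_cfg)
    if (log_tones)
      events <- c(events, list(session_event(t_now, "feedback_tone",
                                             r = r, frequency = f)))
    if (!is.null(reward_cfg)) {
      if (abs(f - f_target) <= reward_cfg$tolerance) {
        reward_run <- reward_run + 1L
        if (reward_run >= reward_cfg$hold_interactions) {
          reward_events <- c(reward_events, t_now + dt)
          events <- c(events, list(session_event(t_now + dt, "reward",
                                                 duration = reward_cfg$reward_duration)))
          reward_run <- 0L
        }
      } else {
        reward_run <- 0L
      }
    }
    state <- step_decision(state, r, dec_cfg, dt = dt)
  }
  latency <- state$elapsed
  correct <- (target == "up" && state$outcome == "yes") ||
    (target == "down" && state$outcome == "no")
  events <- c(events, list(session_event(latency, "decision",
                                         target = target,
                                         outcome = state$outcome,
                                         latency = latency)))
  structure(list(target = target, outcome = state$outcome, correct = correct,
                 latency = latency, r_trace = r_trace,
                 reward_events = reward_events, events = events),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> target %s -> %s (%s) in %.2f s, %d updates\n",
              x$target, x$outcome, if (x$correct) "correct" else "incorrect",
              x$latency, length(x$r_trace)))
  invisible(x)
}

#' Run a block of neurofeedback trials
#'
#' Targets are a seeded balanced shuffle of `n_up` "up" and `n_down` "down"
#' cues (typically 10 + 10) presented in pseudo-random order. Block accuracy
#' is `correct / (n_up + n_down)`, timeouts counting as incorrect.
#'
#' @param rate_source_factory Function `(target, trial_index)` returning a
#'   rate source for [run_feedback_trial()].
#' @param n_up,n_down Number of high/low target trials (defaults 10 and 10).
#' @param paradigm `"no_reward"`, `"reward"`, or `"question"` (labelled
#'   yes/no questions; identical mechanics, distinct label).
#' @param seed Integer seed for the target shuffle and any randomness in the
#'   rate sources; recorded in the block. `NULL` uses the current RNG stream.
#' @param fb_cfg,dec_cfg,reward_cfg,cue_duration,log_tones Passed to
#'   [run_feedback_trial()]; `reward_cfg` is only used when
#'   `paradigm = "reward"`.
#' @return An object of class `block_record`.
#' @export
run_feedback_block <- function(rate_source_factory, n_up = 10, n_down = 10,
                               paradigm = c("no_reward", "reward", "question"),
                               seed = NULL, fb_cfg = feedback_config(),
                               dec_cfg = decision_config(),
                               reward_cfg = NULL, cue_duration = 1,
                               log_tones = FALSE) {
  paradigm <- match.arg(paradigm)
  if (n_up < 0 || n_down < 0) stop("trial counts must be non-negative")
  if (paradigm != "reward") reward_cfg <- NULL
  if (paradigm == "reward" && is.null(reward_cfg)) reward_cfg <- reward_config()
  with_seed(seed, {
    targets <- sample(c(rep("up", n_up), rep("down", n_down)))
    trials <- lapply(seq_along(targets), function(i) {
      run_feedback_trial(targets[i], rate_source_factory(targets[i], i),
                         fb_cfg = fb_cfg, dec_cfg = dec_cfg,
                         reward_cfg = reward_cfg, cue_duration = cue_duration,
                         log_tones = log_tones)
    })
    new_block_record(trials, targets, seed, paradigm)
  })
}

new_block_record <- function(trials, targets, seed, paradigm) {
  correct <- vapply(trials, `[[`, logical(1), "correct")
  outcomes <- vapply(trials, `[[`, character(1), "outcome")
  structure(list(trials = trials, targets = targets, seed = seed,
                 paradigm = paradigm,
                 n_trials = length(trials),
                 n_correct = sum(correct),
                 n_timeout = sum(outcomes == "timeout"),
                 accuracy = if (length(trials)) mean(correct) else NA_real_),
            class = "block_record")
}

#' @export
print.block_record <- function(x, ...) {
  cat(sprintf("<block_record> %s paradigm, %d trials (seed %s)\n",
              x$paradigm, x$n_trials,
              if (is.null(x$seed)) "none" else format(x$seed)))
  cat(sprintf("  %d correct, %d timeouts: accuracy %.1f%%\n",
              x$n_correct, x$n_timeout, 100 * x$accuracy))
  invisible(x)
}

#' @export
summary.block_record <- function(object, ...) {
  acc <- block_accuracy(object)
  print(object)
  print(acc$table)
  invisible(acc)
}

#' Plot the normalized rate traces of a feedback block
#'
#' Up-target trials in red, down-target trials in blue, with the decision
#' thresholds as horizontal lines.
#'
#' @param x A [run_feedback_block()] result.
#' @param dec_cfg Decision thresholds to draw (default [decision_config()]).
#' @param dt Feedback update interval in seconds.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.block_record <- function(x, dec_cfg = decision_config(), dt = 0.25, ...) {
  traces <- lapply(x$trials, `[[`, "r_trace")
  n <- max(lengths(traces))
  m <- vapply(traces, function(v) c(v, rep(NA, n - length(v))), numeric(n))
  cols <- ifelse(x$targets == "up", "#c23b22", "#2b6cb0")
  graphics::matplot((seq_len(n) - 1) * dt, m, type = "l", lty = 1, col = cols,
                    xlab = "time in response period (s)",
                    ylab = "normalized mixed rate", ylim = c(0, 1), ...)
  graphics::abline(h = c(dec_cfg$lower, dec_cfg$upper), lty = 2, col = "grey40")
  invisible(x)
}

#' Decide whether a training block passes the speller gate
#'
#' The session advances from neurofeedback training to free spelling only if
#' the patient matched the feedback to the target in at least `criterion`
#' (default 80%) of the trials; timeouts count against.
#'
#' @param block A [run_feedback_block()] result (or any object accepted by
#'   [block_accuracy()]).
#' @param criterion Fraction of correct trials required (default 0.8).
#' @return `TRUE` if the block's accuracy is at least `criterion`.
#' @export
gate_speller <- function(block, criterion = 0.8) {
  acc <- block_accuracy(block)$accuracy
  acc >= criterion
}

#' Rank channels by target separation and suggest calibration parameters
#'
#' From feedback blocks whose trials carry per-channel SRM traces, computes
#' for every channel a rank-based separation score between up-trial and
#' down-trial SRM distributions (the area under the discrimination curve,
#' folded so 0.5 is chance and 1 is perfect), and suggests normalization
#' bounds `a`/`b` as low/high percentiles of the pooled SRM and the sign
#' `c = +1` if up-trials carry the higher rates, else `-1`.
#'
#' @param blocks A `block_record` or list of them; each trial must have a
#'   `channel_srm` matrix (updates x channels, columns named by channel id),
#'   as produced by [simulate_feedback_block()].
#' @param percentiles Pooled-SRM percentiles used for `a` and `b`
#'   (default `c(0.05, 0.95)`).
#' @return A data frame of class `channel_calibration`, one row per channel,
#'   sorted by decreasing separation score, with columns `channel_id`, `auc`,
#'   `score`, `a`, `b`, `c`, and an attribute `n_trials`.
#' @export
estimate_channel_params <- function(blocks, percentiles = c(0.05, 0.95)) {
  if (inherits(blocks, "block_record")) blocks <- list(blocks)
  trials <- do.call(c, lapply(blocks, `[[`, "trials"))
  if (!length(trials) || is.null(trials[[1]]$channel_srm))
    stop("trials must carry per-channel SRM traces (channel_srm)")
  targets <- vapply(trials, `[[`, character(1), "target")
  if (sum(targets == "up") < 2 || sum(targets == "down") < 2)
    stop("insufficient data: need at least 2 trials per target class")
  ids <- colnames(trials[[1]]$channel_srm)
  # per-trial mean SRM in the response period, per channel
  mean_srm <- t(vapply(trials, function(tr) colMeans(tr$channel_srm),
                       numeric(length(ids))))
  pooled <- do.call(rbind, lapply(trials, `[[`, "channel_srm"))
  up <- targets == "up"
  n1 <- sum(up); n2 <- sum(!up)
  res <- do.call(rbind, lapply(seq_along(ids), function(j) {
    x <- mean_srm[up, j]; y <- mean_srm[!up, j]
    rk <- rank(c(x, y))
    auc <- (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    qs <- quantile(pooled[, j], percentiles, names = FALSE)
    if (qs[2] <= qs[1]) qs[2] <- qs[1] + 1e-6
    data.frame(channel_id = as.integer(ids[j]), auc = auc,
               score = max(auc, 1 - auc), a = qs[1], b = qs[2],
               c = if (auc >= 0.5) 1 else -1)
  }))
  res <- res[order(-res$score, res$channel_id), ]
  rownames(res) <- NULL
  attr(res, "n_trials") <- length(trials)
  class(res) <- c("channel_calibration", "data.frame")
  res
}

#' @export
print.channel_calibration <- function(x, ...) {
  cat(sprintf("<channel_calibration> %d channels ranked by target separation (%d trials)\n",
              nrow(x), attr(x, "n_trials")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Build a mixer from the top-ranked calibrated channels
#'
#' @param calib An [estimate_channel_params()] result.
#' @param n_channels Number of top-ranked channels to use (default 1).
#' @return A [mixer_config()].
#' @export
calibration_to_mixer <- function(calib, n_channels = 1) {
  stopifnot(inherits(calib, "channel_calibration"))
  n_channels <- min(n_channels, nrow(calib))
  mixer_config(lapply(seq_len(n_channels), function(i)
    channel_params(calib$channel_id[i], calib$a[i], calib$b[i], calib$c[i])))
}
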