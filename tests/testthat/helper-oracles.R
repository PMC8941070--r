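# Independent oracles used across the suite. These deliberately re-derive
# results by the most naive possible route (per-sample scans, step-by-step
# trace walks, closed forms) so they stay independent of the implementation.

# Naive per-sample threshold-crossing scan with lockout, on a filtered trace.
naive_crossing_scan <- function(x, threshold, lockout_samples,
                                polarity = "negative") {
  idx <- integer(0)
  last <- -Inf
  for (i in seq_along(x)) {
    below <- x[i] < -threshold && (i == 1 || x[i - 1] >= -threshold)
    above <- x[i] > threshold && (i == 1 || x[i - 1] <= threshold)
    hit <- switch(polarity,
                  negative = below, positive = above, both = below || above)
    if (hit && i - last >= lockout_samples) {
      idx <- c(idx, i)
      last <- i
    }
  }
  idx
}

# Step-by-step trace of the hold-threshold rule: returns list(outcome, step).
decision_trace_oracle <- function(rs, lower = 0.3, upper = 0.7, hold = 2,
                                  timeout_steps = length(rs),
                                  consecutive = TRUE) {
  run_hi <- 0L; run_lo <- 0L
  for (i in seq_along(rs)) {
    r <- rs[i]
    if (r > upper) {
      run_hi <- run_hi + 1L
      if (consecutive) run_lo <- 0L
    } else if (r < lower) {
      run_lo <- run_lo + 1L
      if (consecutive) run_hi <- 0L
    } else if (consecutive) {
      run_hi <- 0L; run_lo <- 0L
    }
    if (run_hi >= hold) return(list(outcome = "yes", step = i))
    if (run_lo >= hold) return(list(outcome = "no", step = i))
    if (i >= timeout_steps) return(list(outcome = "timeout", step = i))
  }
  list(outcome = "timeout", step = length(rs))
}

# Run the package state machine over a whole rate sequence.
run_decision_machine <- function(rs, cfg, dt = 0.25) {
  st <- decision_state()
  for (r in rs) {
    st <- step_decision(st, r, cfg, dt = dt)
    if (st$outcome != "pending") break
  }
  st
}

# Mean of the last n bins ending at or before t, computed by brute force.
brute_srm <- function(counts, t0, bin_width, t, n_win) {
  k <- floor((t - t0) / bin_width + 1e-9)
  k <- min(k, length(counts))
  mean(counts[max(1, k - n_win + 1):k])
}

# Decided-trial outcomes of a block: logical correctness over non-timeouts.
decided_correct <- function(block) {
  outcomes <- vapply(block$trials, `[[`, character(1), "outcome")
  correct <- vapply(block$trials, `[[`, logical(1), "correct")
  correct[outcomes != "timeout"]
}

default_truth <- function() array_truth()
default_mixer <- function(truth = default_truth()) mixer_from_truth(truth, c(3, 11))
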