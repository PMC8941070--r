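test_that("normalization clamps, inverts and averages as specified", {
  one <- function(a, b, c, r)
    normalize_and_mix(r, mixer_config(channel_params(1, a, b, c)))
  expect_equal(one(2, 10, 1, 2), 0)    # lower bound maps to 0
  expect_equal(one(2, 10, 1, 10), 1)   # upper bound maps to 1
  expect_equal(one(2, 10, -1, 2), 1)   # inversion
  expect_equal(one(2, 10, 1, 0), 0)    # clamped below
  expect_equal(one(2, 10, 1, 99), 1)   # clamped above

  mx <- mixer_config(channel_params(1, 2, 10, 1), channel_params(2, 0, 20, -1))
  expect_equal(normalize_and_mix(c(6, 5), mx), 0.625)  # hand-evaluated
  expect_error(normalize_and_mix(c(6, NA), mx), "missing")
  expect_error(channel_params(1, 5, 5), "b > a")
  expect_error(channel_params(1, 0, 1, c = 2), "\\+1 or -1")
})

test_that("mixed rate stays in [0,1] and is monotone with sign c", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(1:4, 1)
    chans <- lapply(seq_len(n), function(j) {
      a <- runif(1, -5, 5)
      channel_params(j, a, a + runif(1, 0.1, 10), sample(c(-1, 1), 1))
    })
    mx <- mixer_config(chans)
    r <- normalize_and_mix(runif(n, -10, 20), mx)
    expect_true(r >= 0 && r <= 1)
  }
  # monotonicity in one channel's rate, each sign
  for (cc in c(-1, 1)) {
    mx <- mixer_config(channel_params(1, 1, 4, cc), channel_params(2, 0, 1, 1))
    rates <- seq(-2, 8, by = 0.25)
    vals <- vapply(rates, function(x) normalize_and_mix(c(x, 0.5), mx),
                   numeric(1))
    expect_true(all(cc * diff(vals) >= 0))
  }
})

test_that("rate-to-tone mapping is the affine bijection onto 120-480 Hz", {
  expect_equal(map_rate_to_tone(0), 120)
  expect_equal(map_rate_to_tone(1), 480)
  expect_equal(map_rate_to_tone(0.5), 300)
  rs <- seq(0, 1, by = 0.01)
  f <- map_rate_to_tone(rs)
  expect_equal(f, 120 + rs * 360)             # affine
  expect_equal((f - 120) / 360, rs)           # invertible
  expect_error(map_rate_to_tone(1.2), "\\[0, 1\\]")
  expect_error(map_rate_to_tone(-0.1), "\\[0, 1\\]")
})

test_that("hold-threshold state machine follows the rule definition", {
  cfg <- decision_config()  # 0.3/0.7, hold 2, 10 s timeout
  st <- run_decision_machine(c(0.8, 0.8), cfg)
  expect_equal(st$outcome, "yes")
  expect_equal(st$n_steps, 2L)

  st <- run_decision_machine(rep(0.5, 100), cfg)
  expect_equal(st$outcome, "timeout")
  expect_equal(st$elapsed, 10)  # decided exactly at the timeout

  # dead zone resets a consecutive run
  st <- run_decision_machine(c(0.8, 0.5, 0.8, 0.8), cfg)
  expect_equal(st$outcome, "yes")
  expect_equal(st$n_steps, 4L)

  # opposite side resets too; cumulative mode does not reset
  st <- run_decision_machine(c(0.8, 0.1, 0.8, 0.1, 0.1), cfg)
  expect_equal(st$outcome, "no")
  cum <- decision_config(consecutive = FALSE)
  st <- run_decision_machine(c(0.8, 0.5, 0.8), cum)
  expect_equal(st$outcome, "yes")

  # boundary values are the dead zone (strict comparisons)
  st <- run_decision_machine(c(0.7, 0.7, 0.3, 0.3, rep(0.5, 40)), cfg)
  expect_equal(st$outcome, "timeout")

  done <- run_decision_machine(c(0.9, 0.9), cfg)
  expect_error(step_decision(done, 0.9, cfg), "decided")
})

test_that("state machine agrees with the step-by-step trace oracle on random sequences", {
  set.seed(33)
  for (i in 1:600) {
    hold <- sample(c(1, 2, 4), 1)
    len <- sample(3:20, 1)
    rs <- runif(len)
    cfg <- decision_config(hold_interactions = hold,
                           response_timeout = len * 0.25)
    got <- run_decision_machine(rs, cfg)
    want <- decision_trace_oracle(rs, hold = hold, timeout_steps = len)
    expect_identical(got$outcome, want$outcome)
    expect_identical(got$n_steps, as.integer(want$step))
  }
})

test_that("feedback trials score targets, honor rewards, and abort on exhaustion", {
  tr <- run_feedback_trial("up", rep(0.9, 10))
  expect_equal(tr$outcome, "yes")
  expect_true(tr$correct)
  expect_equal(tr$latency, 2 * 0.25)  # hold_interactions x update_interval

  tr <- run_feedback_trial("down", rep(0.1, 10))
  expect_equal(tr$outcome, "no")
  expect_true(tr$correct)

  tr <- run_feedback_trial("down", rep(0.9, 10))
  expect_false(tr$correct)

  # reward: tone within 60 Hz of the 480 Hz target for two updates
  rw <- reward_config(tolerance = 60, hold_interactions = 2)
  rs <- c(0.9, 0.95, 0.5, 0.5, 0.9, 0.9)
  tr <- run_feedback_trial("up", c(rs, rep(0.5, 40)),
                           dec_cfg = decision_config(hold_interactions = 8),
                           reward_cfg = rw)
  expect_gte(length(tr$reward_events), 2)

  expect_error(run_feedback_trial("up", rep(0.5, 3)), "exhausted")
})

test_that("feedback blocks shuffle balanced targets reproducibly and score accuracy", {
  perfect <- function(target, i) rep(if (target == "up") 0.9 else 0.1, 50)
  inverted <- function(target, i) rep(if (target == "up") 0.1 else 0.9, 50)
  b1 <- run_feedback_block(perfect, seed = 42)
  expect_equal(b1$accuracy, 1)
  expect_equal(sum(b1$targets == "up"), 10)
  b2 <- run_feedback_block(inverted, seed = 42)
  expect_equal(b2$accuracy, 0)
  expect_identical(b1$targets, b2$targets)  # same seed, same sequence
  b3 <- run_feedback_block(perfect, seed = 43)
  expect_false(identical(b1$targets, b3$targets))
})

test_that("the speller gate requires 80% matched trials", {
  mk <- function(n_correct, n = 20) {
    function(target, i) {
      ok <- i <= n_correct
      r <- if ((target == "up") == ok) 0.9 else 0.1
      rep(r, 50)
    }
  }
  b16 <- run_feedback_block(mk(16), seed = 1)
  expect_true(gate_speller(b16))
  b15 <- run_feedback_block(mk(15), seed = 1)
  expect_false(gate_speller(b15))
  b18 <- run_feedback_block(mk(18), seed = 1)
  expect_equal(block_accuracy(b18)$accuracy, 0.9)
  expect_true(gate_speller(b18))
})

test_that("calibration ranks truly modulated channels first and signs inversions", {
  truth <- array_truth(n_channels = 8, modulated_ids = c(2, 5))
  mix <- mixer_from_truth(truth, c(2, 5))
  blocks <- lapply(1:2, function(s)
    simulate_feedback_block(truth, mix, intent_agent(1, 0), seed = 70 + s))
  cal <- estimate_channel_params(blocks)
  expect_setequal(cal$channel_id[1:2], c(2, 5))
  expect_true(all(cal$c[1:2] == 1))
  expect_true(all(cal$b > cal$a))

  # a channel firing more on down-trials gets c = -1
  inv <- truth
  inv[[7]] <- channel_truth(7, rate_low = 80, rate_high = 5, modulated = TRUE,
                            drift_sd = 10)
  b <- simulate_feedback_block(inv, mix, intent_agent(1, 0), seed = 99)
  cal <- estimate_channel_params(b)
  expect_equal(cal$c[cal$channel_id == 7], -1)
  expect_setequal(cal$channel_id[1:3], c(2, 5, 7))
})

test_that("without modulation, separation scores sit in the null band of the rank statistic", {
  truth <- array_truth(n_channels = 12, modulated_ids = integer(0))
  mix <- mixer_config(channel_params(1, 0.1, 2))
  blocks <- lapply(1:3, function(s)
    simulate_feedback_block(truth, mix, intent_agent(0, 0), seed = 500 + s,
                            dec_cfg = decision_config(response_timeout = 2.5)))
  cal <- estimate_channel_params(blocks)
  n1 <- sum(vapply(do.call(c, lapply(blocks, `[[`, "trials")),
                   `[[`, character(1), "target") == "up")
  n <- attr(cal, "n_trials")
  sigma <- sqrt((n + 1) / (12 * n1 * (n - n1)))  # null SD of the AUC
  expect_true(all(abs(cal$auc - 0.5) <= 3 * sigma))
  expect_error(estimate_channel_params(
    simulate_feedback_block(truth, mix, intent_agent(0), n_up = 1, n_down = 1,
                            seed = 1,
                            dec_cfg = decision_config(response_timeout = 2.5))),
    "insufficient")
})
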