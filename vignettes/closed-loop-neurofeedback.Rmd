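---
title: "Methods: a closed-loop auditory neurofeedback speller from spike rates"
author: "neurospeller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop auditory neurofeedback speller from spike rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurospeller)
```

## The problem this package models

A person in the completely locked-in state (CLIS) has no reliable muscle-based
channel left — not even eye movements — so vision-dependent communication aids
fail. One demonstrated alternative is an intracortical brain–computer
interface in which the user *volitionally modulates* the firing rate of a few
motor-cortex channels and hears that rate as a tone: rate up means "yes", rate
down means "no". Chained yes/no answers drive a group-scanning auditory
speller. This package implements that whole loop — spike detection, rate
normalization, tone mapping, the yes/no decision rule, the speller, and the
session metrics — together with a seeded simulator that stands in for the
recording hardware and the user, so the complete system can be exercised and
tested at a desk.

## Signal chain

Raw 30 kS/s voltage traces are band-pass filtered at 250–7500 Hz. We use a
4th-order zero-phase Butterworth realization (a 2nd-order design applied
forward and backward with `signal::filtfilt`): offline reproducibility and
zero group delay matter more here than causal realism, and the pass-band gain
stays within a few percent of unity.

Spikes are *unsorted threshold crossings*: an event is recorded whenever the
filtered trace crosses 4.5 × RMS of the segment. Three details are
configurable because the field convention leaves them open:

* **Polarity** — negative-going by default (extracellular spikes are
  dominantly negative at the electrode).
* **Lockout** — 1 ms by default, so a single biphasic waveform is not counted
  twice.
* **RMS window** — the RMS is computed over the whole supplied segment, and a
  manual threshold override is available, mirroring how experimenters adjust
  thresholds per channel after visual inspection.

Counts are accumulated in 50 ms bins anchored at the segment start, half-open
`[t, t + 50 ms)`, which makes re-binning deterministic. The **spike rate
metric (SRM)** is the mean of the 20 most recent complete bins — a trailing
one-second boxcar, in units of spikes per bin. With fewer than 20 bins
available the mean over the available bins is returned and flagged as
warm-up, which avoids an undefined start-up.

## Normalization and mixing

Each control channel $i$ has calibration parameters $a_i < b_i$ (rate bounds)
and $c_i \in \{+1, -1\}$ (inversion). The mixed control value is

$$
r(t) = \frac{1}{n}\sum_{i=1}^{n}\left[\frac{1-c_i}{2}
  + c_i\,\frac{\mathrm{clamp}(r_i(t), a_i, b_i) - a_i}{b_i - a_i}\right].
$$

We subtract $a_i$ in the numerator. A variant without that subtraction is
sometimes written, but it maps the clamped range to $[a/(b-a),\, b/(b-a)]$
rather than $[0,1]$ and so breaks the stated contract that each channel is
"normalized to the interval [0, 1]"; the two forms coincide exactly when
$a_i = 0$. With the subtractive form, $r(t) \in [0,1]$ for *any* parameters
and rates, monotone in each channel's rate with the sign of $c_i$ — both are
enforced by property tests.

$r$ is mapped affinely to a feedback tone frequency,
$f = 120 + 360\,r$ Hz, updated every 250 ms (pure 250 ms sine tones in the
real system; we model the frequency value, not audio rendering).

## The yes/no decision rule

During a response period the user must *hold* the rate past a threshold:
strictly above 0.7 for "yes", strictly below 0.3 for "no", for a configurable
number of consecutive 250 ms interactions (default 2, i.e. 500 ms). Values
exactly at a threshold count as the dead zone — strict comparisons give a
deterministic tie-break. The hold is consecutive by default (re-entering the
dead zone resets the run, as an unbroken hold implies); a cumulative mode is
available. If no decision is reached within the response timeout the trial is
scored "timeout". The timeout is not a published constant; we default to 10 s
and make it configurable. Timeouts are a first-class outcome: they count
against accuracy and occupy their own cell in the contingency table.

Each training block presents a seeded balanced shuffle of (typically) 10
high-frequency and 10 low-frequency target tones, preceded by a 1 s cue. In
the reward paradigm, holding the feedback tone within a configurable band of
the target frequency for a hold count additionally emits a 250 ms reward
event. A block *gates* the speller when at least 80% of its trials are
correct.

## Channel calibration

Given blocks whose trials carry per-channel SRM traces, channels are ranked
by a rank-based separation score between up-trial and down-trial mean SRMs:
the two-sample rank statistic normalized to an AUC, folded about 0.5 so that
1 is perfect discrimination in either direction. Suggested bounds $a, b$ are
the 5th and 95th percentiles of the pooled SRM samples (robust to outliers;
the experimenter's actual choice is not published), and $c = +1$ when
up-trials carry the higher rates, $-1$ otherwise.

## The speller

Thirty options: 26 letters plus space, delete, question mark, and
end-program. Letters are ordered by descending frequency in written German
and partitioned into groups (default 6/6/6/6/2, with the four actions as a
trailing group). The exact partition used clinically is not published; the
default preserves the frequency-ordering principle and is fully
config-overridable. Umlauts are transcribed as digraphs (ae/oe/ue), so 26
letters suffice.

Scanning is two-level: groups are offered in order ("yes" descends, "no"
advances, wrapping), then the group's options ("yes" selects). A timeout
during scanning advances like "no" after being logged — this prevents
deadlock while remaining distinguishable in the log. Unbounded wrapping is
cut off after 3 scan cycles per selection, which abandons the selection and
restarts scanning (a forced timeout). Selecting an option costs
(group index − 1) + (position − 1) + 2 decisions, which the tests verify
against explicit path enumeration for every menu entry.

## Session metrics

Block accuracy is (TP + TN) / total with timeouts in the denominator.
Spelling rate is characters per minute. The information transfer rate per
selection follows Wolpaw:

$$
B = \log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1},
$$

with $N = 30$ and the convention $0\log_2 0 = 0$ at $P = 1$; multiplied by
selections per minute it yields bits/min. $B$ is zero at chance ($P = 1/N$)
and increases strictly to $\log_2 N$ at $P = 1$. $P$ must be supplied by the
caller (e.g. from scripted ground truth in simulation); per-session empirical
$P$ values from the clinical corpus are not available and are not estimated
here.

## The simulator

The simulator replaces the two parts of the loop we cannot have: the
recording and the user.

* **Intent agent** — modeled at the 250 ms interaction granularity (the
  resolution at which the decision loop observes the world). Intent rests at
  0.5, moves to 1 ("up") or 0 ("down") after a 0.5 s reaction time on trials
  the agent pursues (probability = compliance), and lapses transiently back
  to baseline with a per-interaction probability.
* **Spiking channels** — inhomogeneous Poisson counts in 50 ms bins whose
  mean interpolates linearly between `rate_low` (intent 0) and `rate_high`
  (intent 1), with an optional intent-to-rate lag. The default control
  channels use 5 and 80 spikes/s, which puts roughly ten SDs of the 1 s SRM
  between the two states — a deliberately clean, well-modulated channel.
* **Rate nonstationarity** — every channel carries a slow AR(1) rate drift
  (default SD 10 spikes/s, time constant 3 s). Chronic recordings are not
  stationary: session-to-session and within-session rate drift is why the
  clinical system needed repeated recalibration, and why poor sessions sat at
  chance rather than producing pure timeouts. Without the drift term a
  non-modulating agent almost never crosses a decision threshold, which is
  not what degraded real sessions look like.
* **Waveform synthesis** — for the detection chain, a normalized biphasic
  template (sharp negative lobe, slower positive rebound, ~1.2 ms) is added
  to Gaussian broadband noise at each event time. At 10σ amplitude the full
  filter→threshold→lockout chain recovers ≥95% of injected events, and it
  agrees sample-for-sample with a naive linear-scan oracle.

What the simulator does **not** emulate: spike waveform diversity and
overlap, electrode impedance changes and array degradation, learning or
fatigue within the agent, auditory rendering, and any correlation structure
across channels beyond shared intent. Passing tests therefore demonstrate
the correctness of the decision and spelling machinery and the plausibility
of the closed loop under Poisson-plus-drift statistics — not clinical
performance.

## Problem sizes and reproducibility

Every stochastic path is reproducible from `(config, seed)`; block records
store their seed. The test suite runs the closed loop at desk scale: a
16-channel array with 2 modulated channels, 20-trial blocks, 100-block
batteries for the compliant/null/calibration properties, and $10^4$ random
sequences for the decision-machine equivalence check. The chance-level check
conditions on decided (non-timeout) trials: at compliance 0 the firing is
independent of the cue by construction, so each decided trial is a fair coin
and the observed rate is compared against a 99% binomial band at the realized
number of decided trials.

## Known limitations

* The SRM boxcar makes consecutive 250 ms control values strongly
  autocorrelated (15 of 20 bins shared); decisions are therefore not
  independent Bernoulli trials at the interaction level, and latencies
  cluster just above the hold duration.
* Calibration assumes per-trial mean SRMs are exchangeable within a target
  class; slow drift violates this mildly, which the rank-based score absorbs
  better than a t-statistic would.
* The event log stores decisions and selections, not raw counts, so replay
  reconstructs outcomes and transcripts exactly but cannot re-derive rates.
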