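---
title: "From clickstream logs to behavioral segments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clickstream logs to behavioral segments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickseg)
```

## The problem

Point-of-care clinical reference tools (evidence-based clinical resources,
EBCRs) log every click a clinician makes: an anonymized user id, a
millisecond timestamp, and a vendor-assigned event type such as `Search` or
`TopicView`. Donation programs that give clinicians in low-resource settings
a one-year subscription want to know *how* the tool is actually used over
that year — who never starts, who uses it briefly and stops, who settles into
daily lookups — so that support can be targeted. `clickseg` implements a
complete, reproducible path from the raw click log to five interpretable
behavioral segments, together with a synthetic cohort generator that makes
every stage testable without access to any proprietary log.

## Pipeline model, stage by stage

### Click filtering

Two click-level filters are applied before any aggregation:

* **Double clicks.** A click falling less than 500 ms after the most recent
  *retained* click of the same user is removed. "Within 500 ms of each
  other" is ambiguous for chains (0, 400, 800 ms...): we resolve it with a
  keep-first forward scan anchored on the last retained click, which is
  deterministic, order-independent given sorted input, and matches common
  dedup practice. After filtering, every same-user gap is at least the
  threshold, and applying the filter twice changes nothing. The rule ignores
  event type.
* **Single-click users.** A user left with exactly one click carries no
  measurable interaction (no gap, no session length). These users are
  removed from the clickstream and reported; segmentation labels them
  never-users. The pipeline reports the excluded count separately from the
  zero-click count, so either convention (counting them as never-users or
  not) is recoverable.

Timestamp ties are broken by event type, then input order (stable sort), so
runs are reproducible.

### Activities

Event types are classified into three activities — NAVIGATING (searches and
movement toward content), READING (exposure to medical content, including
printing/sharing and offline topic views), ACCOUNT (settings, bookmarks) —
plus TERMINAL for events such as `ExternalLinkClick` that end interaction.
Production vocabularies run to dozens of event types and vary by vendor, so
the mapping is data (`activity_map()`, a CSV, or the built-in default) rather
than code. The default unknown-event policy is `error`: silent
misclassification is impossible unless you opt into `drop` or
`navigating`.

### Sessions and spans

Clicks are grouped with a 5-minute inactivity timeout: a gap of 300 s or
more starts a new session. The sources of the rule state "less than 5
minutes" stays together and "more than 5 minutes" splits, leaving the exact
boundary undefined; we take gap `>= 300 s` as a split (strict "less than"
keeps a session together), and the timeout is configurable. The boundary is
unit-tested on both sides (299.999 s vs 300.000 s).

Between two consecutive clicks the user is assumed engaged in the activity
of the *first* click, so every non-terminal click opens a span ending at the
next click. The final non-terminal click of a session opens a span whose
duration cannot be observed — the censored span. A terminal click closes the
preceding span at its own timestamp and never opens one; whether terminal
events inside a session should also close spans is not settled anywhere, and
we follow the reading that they signal the end of an activity (close, don't
open). A session consisting only of terminal clicks is a zero-duration
artifact and is discarded with a count. Consecutive same-activity clicks
open separate spans; downstream statistics only ever use per-activity sums,
for which this is equivalent and simpler.

### Censored-duration model

Known span durations are heavily right-skewed. We model them with a Box-Cox
power transformation,

$$y = \frac{d^{\lambda} - 1}{\lambda},$$

and a linear mixed model on the transformed scale:

$$y_{ij} = \beta_0 + \beta_{a(ij)} + u_i + \varepsilon_{ij}, \qquad
u_i \sim N(0, \sigma^2_u),\; \varepsilon_{ij} \sim N(0, \sigma^2_e),$$

with activity as a (up to) three-level fixed effect and a per-user random
intercept, fitted by REML (`lme4::lmer`). The exponent $\lambda$ is chosen
by profile likelihood over a grid ($[-2, 2]$, step 0.01) of a linear model
with the activity fixed effect; profiling with the activity means included
keeps between-activity location shifts from distorting the exponent, and the
grid search is deterministic. Whether $\lambda$ should be estimated jointly
with the random effect or marginally is a genuinely open design point; we
estimate it marginally (simple, deterministic) and allow pinning it (e.g.
`lambda = -0.25`, the value typical of this kind of dwell data) through
`pipeline_config()`. A degenerate constant-duration input warns and falls
back to $-0.25$.

Each censored span is imputed by the model's point prediction
$\beta_0 + \beta_a + \hat u_i$, back-transformed with the naive inverse.
No smearing/bias correction is applied — a deliberate, documented choice
that introduces a known downward bias on the natural scale but matches the
transparent "back-transform the prediction" convention. Users with no known
spans receive $\hat u_i = 0$ (full shrinkage to the population mean).
Imputed durations are capped so a session can never reach the user's next
session start (cap: next start − last click − 1 ms); the user's last
session is uncapped. Single imputation only: the downstream statistics are
sums and medians over hundreds of spans per user, for which a point
prediction is adequate and reproducible.

### Usage statistics

Eight per-user statistics are computed from finalized sessions: session
count, total minutes, percent of time per activity, lag (activation to
first click), period of use (first to last click), percent of active days,
rate of use (minutes per active day), and lapse (last click to the end of
the 365-day horizon). All day arithmetic is in whole UTC calendar days so
that lag + period + lapse = 365 holds *exactly* for every user who ever
used the tool; fractional-day definitions would break that identity. Two
conventions are deliberately configurable because the originals are
ambiguous: the active-day denominator is `period_days + 1` by default
(inclusive of both endpoints, so a single-day user is 100% active), and a
session's active day is the UTC date of its *start* (a session straddling
midnight counts once). A user lapsing 42 days (6 weeks) or more is flagged
a dropout.

### Segments

Two inclusive cut points define the segments: *heavy* use at a rate of at
least 5 minutes per active day (a round, interpretable number near the
observed median of such cohorts) and *long-term* use at a period of at
least 48 weeks = 336 days exactly (no calendar-week alignment). Crossing
them gives segments A (short-term light), B (short-term heavy), C
(long-term heavy), D (long-term light); users with no retained clicks are
segment E (never-users). The cut points are plain parameters
(`segment_thresholds()`) — the approach is deliberately rule-based, not a
clustering method, because interpretability and portability to future
cohorts are the point.

### Survey linkage and adjustment

Baseline survey covariates (demographics, device access,
professional-climate items) are joined by user id. Raw segment-by-covariate
tables are complete-case with missing counts reported. Adjusted
distributions fit a multinomial logistic regression of segment on the
exposure plus adjusters (`nnet::multinom`, largest segment as reference —
predictions are invariant to that) and report marginally standardized
percentages: for each exposure level, every user's predicted segment
probabilities are computed with the exposure set to that level and averaged
over the observed adjuster distribution. How the original adjusted
distributions were computed from the multinomial fit is not documented
anywhere; marginal standardization is the transparent choice. With an empty
adjuster set the standardization reduces algebraically to the raw row
percentages, so that case returns them directly (exact, no optimizer
noise). No hypothesis tests are produced anywhere in the report — only
counts, percentages, and adjusted percentages.

## The synthetic cohort generator

`generate_cohort()` exists so that each stage has a recovery target with
known truth. It emulates:

* latent segment membership (default mix 25/15/24/21/15% for A–E — the D
  share is 21 rather than 22 so the five shares form an exact probability
  distribution);
* activation dates over a 9-week enrollment window, geometric lags (most
  users start within days), periods of use drawn 14–280 days for short-term
  segments and 343–365 for long-term ones (both a week away from the
  336-day cut point, so "well-separated" is meaningful);
* active days as endpoint-forced Bernoulli days within the period; sessions
  placed in non-overlapping within-day slots; click sequences from a Markov
  chain over activities starting at a `Search` click, with event types
  drawn within the activity;
* dwell times drawn exactly from the Box-Cox-normal mixed model above
  (defaults: $\lambda=-0.25$, $\beta_0=-0.75$, $\beta_{READ}=0.95$,
  $\beta_{ACCT}=-0.1$, $\sigma_u=0.25$, $\sigma_e=0.4$; medians ≈ 0.5, 1.2
  and 0.45 minutes), truncated to [0.66 s, 4.5 min] so every within-session
  gap respects both the 500 ms dedup threshold and the 300 s timeout. The
  truncation mass is under 1% by design: heavier tails would make the
  exponent unrecoverable from pipeline data, and the parameters were fixed,
  once, from that feasibility analysis;
* heavier session counts per active day for segments B/C than A/D, with
  similar session lengths across segments, so that session count and total
  time are strongly correlated (>0.9) as in real cohorts of this kind;
* double-click artifacts (duplicates 50–450 ms after a real click),
  single-click users, occasional terminal-ended sessions, and survey
  covariates drawn *conditionally on segment* with configurable log-odds
  tilts — association without disturbing the marginal segment mix;
* `simulate_spans()` draws spans straight from the dwell model (no session
  structure, no truncation) for clean parameter-recovery tests, and
  `simulate_confounded_survey()` builds an exposure–confounder–segment
  triangle with a switchable direct effect for validating the adjustment.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: real event-type vocabularies (42+ types),
diurnal/weekly rhythms, midnight-straddling sessions, devices going offline
mid-session, model misspecification of dwell times (available as the
`lognormal_heavy` family switch, but not the default), and survey
missingness patterns. Results on synthetic data validate the *machinery*,
not any real cohort's numbers.

## Numerical and degenerate-input choices

* Timestamps are numeric epoch milliseconds (exact integers well inside
  double precision); durations are minutes; day arithmetic uses UTC dates.
* The λ grid search uses one QR decomposition and `qr.resid` per candidate;
  `lambda = 0` uses the log limit.
* Sessions whose only clicks are terminal are discarded (counted); a single
  known span cannot support the model (error below 2 spans; warning below
  100); a single-user input degrades to a plain linear model with
  $\sigma^2_u = 0$; a single-activity input drops the fixed effect.
* A singular mixed fit ($\sigma^2_u \to 0$) succeeds with a warning and
  near-zero BLUPs.
* `inv_boxcox` checks its domain ($1 + \lambda y > 0$) and fails loudly;
  with $\lambda = -0.25$ and the capped predictions used here the check
  cannot trigger, but it guards future parameterizations.
* All randomness flows from one integer seed; generation and the pipeline
  are byte-reproducible given it.

## Problem sizes

The shipped tests run the pipeline end to end on cohorts of 200–2000 users
(roughly 10⁵–10⁶ clicks), sizes chosen to exercise every code path and give
stable recovery statistics on a single CPU in a few minutes. The
parameter-recovery checks use 300 users × 40 spans; the sessionizer is
checked against a brute-force splitter on 1000 random instances of up to
500 clicks.

## Known limitations

* The naive back-transformation biases imputed natural-scale durations
  downward; a smearing correction would remove it at the cost of matching
  the documented convention.
* Time between an intra-session terminal click and the next click is
  attributed to no activity; per-activity percentages are normalized over
  attributed time, so they still sum to 100, but session duration can
  exceed the activity sum in that (rare) case.
* Marginal λ estimation ignores the random intercept; simulations show the
  residual bias is small relative to the ±0.1 band that matters here, but
  joint estimation would be more efficient.
* The segmentation is intentionally not data-driven; if your cohort's rate
  distribution sits far from 5 min/day, move the thresholds rather than
  expecting the defaults to split it evenly.
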