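# clickseg

Behavioral segmentation of clickstream usage logs from point-of-care
clinical reference tools.

## What problem this solves

Programs that donate one-year subscriptions to an evidence-based clinical
resource (an EBCR, e.g. a point-of-care reference app) receive raw
clickstream exports — one row per click, with an anonymized clinician id, a
millisecond timestamp, and a vendor event type — and want to know how each
clinician actually used the tool over the subscription year. `clickseg`
turns that log into five interpretable behavioral segments and
covariate-linked segment reports:

1. **Filtering** — remove double clicks (< 500 ms after the last retained
   click of the same user, keep-first rule) and users with exactly one
   click.
2. **Activities** — classify event types into navigating / reading /
   account management (terminal events end activity), via a configurable
   mapping.
3. **Sessionization** — group clicks with a 5-minute inactivity timeout;
   every non-terminal click opens an activity span ending at the next
   click; the final span of a session is duration-censored.
4. **Censored-duration imputation** — fit, on the Box-Cox transformed scale
   `y = (d^λ − 1)/λ`, the linear mixed model
   `y = β₀ + β_activity + u_user + ε` with `u_user ~ N(0, σ²_u)` (REML via
   lme4), estimate λ by profile likelihood, and impute each censored span
   with the back-transformed point prediction, capped so sessions never
   overlap.
5. **Usage statistics** — eight per-user measures (sessions, total minutes,
   % per activity, lag, period of use, % active days, rate per active day,
   lapse), with lag + period + lapse = 365 exactly, and a 6-week dropout
   flag.
6. **Segmentation** — two inclusive cut points (rate ≥ 5 min/active day =
   heavy; period ≥ 48 weeks = long-term) give segments A (short-term
   light), B (short-term heavy), C (long-term heavy), D (long-term light),
   plus E (never-users).
7. **Survey reporting** — raw and multinomial-regression-adjusted
   (marginally standardized) segment distributions by demographic and
   device-access covariates; counts and percentages only, no hypothesis
   tests.

A synthetic cohort generator with full ground truth (latent segments, true
span durations, true random intercepts, covariate–segment associations)
makes every stage testable without any proprietary data.

## Worked example

```r
library(clickseg)

cohort <- generate_cohort(generator_config(n_users = 300, seed = 42))
result <- run_pipeline(cohort$clicks, cohort$activations, cohort$survey)
result
#> clickstream segmentation pipeline
#>   clicks in 206153 | retained 200133 | double-clicks removed 6019 | single-click users 1
#>   sessions 46945 | users 300 (ever 262 / never 38) | lambda -0.18
#>   segments:  A=82 B=46 C=76 D=58 E=38
```

206,153 generated clicks (including injected 50–450 ms double-click
artifacts, which the filter removes) collapse to 46,945 sessions; 38 of the
300 users never produce a click and land in segment E. The fitted dwell
model recovers the generator's structure:

```r
result$fit
#> Box-Cox dwell-time mixed model
#>   lambda      : -0.180
#>   intercept   : -0.752 (transformed scale, ref = NAVIGATING)
#>   READING     : +0.925
#>   ACCOUNT     : -0.100
#>   sigma_u^2   : 0.0635   sigma_e^2 : 0.1482
#>   fitted on 153188 spans from 262 users
```

(The generator's truth is λ = −0.25, β₀ = −0.75, β_READ = 0.95,
β_ACCT = −0.1 — the slight λ attenuation comes from the timeout truncation
of dwell draws, and stays within the ±0.1 band the recovery tests assert.)

```r
result$cohort_table
#> # A tibble: 5 × 4
#>   segment segment_name         n   pct
#> 1 A       short-term light    82  27.3
#> 2 B       short-term heavy    46  15.3
#> 3 C       long-term heavy     76  25.3
#> 4 D       long-term light     58  19.3
#> 5 E       never-user          38  12.7

ct <- join_and_tabulate(result$segments, cohort$survey, "device_access")
dplyr::filter(ct, segment == "E")
#> # A tibble: 2 × 4
#>   level segment     n   pct
#> 1 high  E          34  11.9
#> 2 low   E           4  28.6
```

The crosstab shows the generator's built-in association: users with low
device access are far more likely to be never-users (28.6% vs 11.9%).
`adjusted_distribution()` removes confounding from such contrasts by
marginal standardization over a multinomial fit.

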