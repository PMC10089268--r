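---
title: "Methods: flags, trends and missions in habitcoach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flags, trends and missions in habitcoach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitcoach)
library(tibble)
```

habitcoach is a desk-scale decision-support engine for behavioural
coaching of school-age children (9-12 years). It turns three input
streams — daily wearable series, weekly questionnaire self-reports and
anthropometric measurements — into a weekly traffic-light assessment
per monitored behaviour, a trend-based risk verdict per wearable
variable, and a three-mission personalised coaching plan. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the bundled simulator does and
does not emulate.

## Anthropometric classification

Body-mass index is standardised against an age- and sex-specific
growth reference with the LMS method. Given reference parameters
$L$ (Box-Cox skewness), $M$ (median) and $S$ (coefficient of
variation) at the child's age and sex,

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad z = \frac{\ln(x/M)}{S} \;\text{ when } L = 0.$$

The implementation evaluates $(x/M)^L - 1$ as `expm1(L * log(x/M))`,
which avoids catastrophic cancellation and makes the general form
numerically continuous with the log form as $L \to 0$ (the two exact
forms themselves differ by $\approx z \ln(x/M) L / 2$ at small $L$, a
first-order bound the unit tests assert).

Five nutritional statuses follow from school-age z-score cut-offs at
$-3$, $-2$, $+1$ and $+2$: severe thinness, thinness, normal,
overweight, obesity. Every boundary value takes the **less severe**
status, so $z = -2$ and $z = +1$ are both "normal". Reference tables
are user-supplied CSV (`sex, age_months, L, M, S`); parameters at
fractional ages are linearly interpolated within sex. The bundled
`lms_bmi_synthetic.csv` is a synthetic table with smooth, plausible
curves — adequate for tests (whose oracles are closed-form in the table
itself) and demonstrations, not a published growth standard. Records
with $|z| > 5$ are flagged `suspect` and kept, on the view that an
entry error should be audited rather than silently dropped.

Fat-mass and waist-based categories use the generic
`categorize_by_cutoffs()` classifier: user-supplied strictly increasing
thresholds, half-open `[low, high)` intervals. Whether a deployment
categorises waist circumference or waist-to-hip ratio is a
configuration question; both are plain cut-off classifications.

## Questionnaires

PAQ-C items are scored 1-5 and summarised as the unweighted mean
(instrument length configurable, default 9 items). Food-frequency
categories map to weekly consumption counts through an editable table;
ranged categories ("2-3/week") use the midpoint of their range. Both
choices are configuration, not science fixed in code, because published
deployments calibrate them against their own baseline evaluation.

## Three-level risk stratification

Every monitored variable carries a rule: a direction
(`higher_is_worse` or `lower_is_worse`) and two cut-offs, defining
exactly three bands — green (optimal, maintain), yellow (not optimal,
change), red (needs immediate change, prioritised). Values exactly at
a cut-off take the less severe flag, mirroring the nutritional-status
convention. The shipped defaults (e.g. steps green at >= 9000/day, red
below 6000/day; sweets red above 5 portions/week) are order-of-magnitude
placeholders: real cut-offs come from a cohort's baseline evaluation
and belong in configuration. Physical-activity coaching targets grow
from the child's individual baseline by a weekly fraction,
$\min(b(1+\delta)^w, T)$, until the population target $T$ is reached.

## Trend risk detection

For each wearable series the detector runs six steps: ingest the
daily series; decompose and extract the trend; fit piecewise linear
segments; classify each slope; choose a reference point; forecast and
confirm.

**Gaps.** Missing days are linearly interpolated when a gap spans at
most 2 days; longer gaps split the series and only the most recent run
of at least two seasonal periods is analysed.

**Decomposition.** The weekly component is the per-weekday mean of the
linearly detrended series, centred to zero; the trend is the seasonally
adjusted series, optionally passed through a short centred running mean
(`smooth_window`, default 1 = none). The default deliberately avoids
smoothing: a single-day device dropout (a step count of 0 between
normal days) must survive into the trend as an implausibly steep
segment so the classifier can reject it. Any smoother wider than the
artifact turns the dropout into a small level shift that a
discontinuous segment fit absorbs with innocent-looking slopes.

**Piecewise regression.** Segments are fitted by exact dynamic
programming: for every candidate segment count $k \le$ `max_segments`
(default 3) the breakpoint placement minimising the total squared error
is found (each segment's slope and intercept are its own OLS fit;
minimum segment length 2 days), and $k$ is selected by minimising
$\mathrm{SSE}(k) + \lambda k$. The default penalty is
$\lambda = 5 \log(n)\,\hat\sigma^2$ with $\hat\sigma^2$ the residual
variance of the finest fit — a BIC-flavoured choice. A much weaker
penalty (a small multiple of $\hat\sigma^2$) lets the programme carve
pure noise into short segments whose slopes exceed `min_slope`,
producing spurious "unhealthy" detections at realistic step-count noise
levels; the stronger default removes essentially all such false alarms
while leaving genuine declines detected.

**Classification.** A slope is `no_risk` when $|s| <$ `min_slope`
(too flat to be behaviour change), `ignored_too_steep` when
$|s| >$ `max_slope` (implausible for human behaviour, treated as a
device artifact), and otherwise ascending/descending unhealthy when its
sign matches the variable's harmful direction. Defaults for steps are
100 and 2000 steps/day per day. Reading "too steep" as
artifact-rejection is a deliberate interpretation: a plausible steep
decline in, say, step counts is precisely what the detector must
report, so only implausible steepness can be a reason to ignore a
segment.

**Reference point and onset refinement.** The reference point is the
start of the latest unhealthy segment. Because a free
(discontinuous-at-breakpoints) least-squares segmentation localises a
slope *kink* only coarsely — the breakpoint can slide several days at
little cost in squared error — `detect_risk()` refines the reference
point with a constrained two-phase fit in the window spanning the
latest unhealthy run and the flat run before it: a constant baseline up
to day $k$, a straight drift after it, $k$ chosen by least squares.
This models the clinical question directly ("when did the child leave
their stable baseline?"). The property suite measures recovery as the
fraction of simulated declines whose reference point lands within two
days of the injected changepoint; at the default noise level the
achievable precision is of the order of a few days, set by the
slope-change-to-noise ratio, and the refinement step is what keeps the
detector near that statistical limit rather than several days off.

**Forecast and verdict.** The forecast linearly extrapolates the final
fitted segment over `horizon` days (default 7). When an unhealthy
segment exists, the verdict is `unhealthy_trend_confirmed_by_forecast`
if the forecast line itself still classifies as unhealthy (the decline
is ongoing at the series end), and `unhealthy_trend_not_confirmed`
otherwise (the behaviour turned before the end). Both unhealthy
verdicts are exported to the coaching engine; they feed motivation
messages and the plan rationale but do not override the flag scheme.

## The coaching engine

Weekly assessment resolves each behaviour's source variable from the
week's summaries and applies its rule; behaviours with missing data are
flagged yellow by default (configurable to green, red or a hard error)
with a warning, so a silent sensor failure can never masquerade as an
optimal week.

Mission selection works per health dimension (physical activity &
sleep; diet; education & empowerment). The behaviour with the most
severe current flag wins; among ties, the behaviour whose red flags
persist through the longest run of consecutive weeks ending at the
current week wins ("the history of most recent red flags"); remaining
ties fall back to the configured behaviour order, making selection
total and deterministic. An all-green dimension still receives a
maintenance mission (first behaviour in configured order). The weekly
plan is exactly one mission per dimension and applies to the following
ISO week.

Carer feedback validates missions: family or educator reports set
`completed`/`not_completed`; unreported missions stay `pending` until
the end of the following week and then default to `not_completed`;
when family and educator disagree the educator's report wins and the
conflict is logged. Completed missions award points; ability
percentages (dexterity / discipline / intelligence) are each ability's
share of total points. The default mission-to-ability mapping (physical
activity -> dexterity, diet -> discipline, education -> intelligence)
is configuration — deployments define their own catalogue. The weekly
six-question agent self-report is likewise a configurable instrument
with a strict length check.

## The simulator

`simulate_cohort()` generates a cohort whose defaults emulate a
school-based baseline: ages uniform on 9-12 years, 58.7% girls,
nutritional-status prevalences of 11.7% obesity, 17.1% overweight, 3%
thinness, 0.7% severe thinness, and mean daily steps of 5170.
Anthropometry is generated in z-space and inverted through the LMS
table, so classification ground truth is exact by construction.
Wearable series are baseline + weekly sinusoid + piecewise-linear trend
(slope change of -250 steps/day from a day uniform on 20-40, in 30% of
children) + Gaussian noise (sd 800 for steps), clipped at zero, with a
1%/day single-day dropout artifact. Weekly behaviour values are drawn
by inverting the stratification rules — sample a band, then a value
inside it — so flag ground truth is known. The adherence model shifts a
planned mission's target variable toward its green band by a per-variable
effect size with probability `adherence` (default 0.74).

The tests run the closed loop at deliberately desk-scale sizes — 60-day
series, cohorts of 10-30 children (5000 for the prevalence check, which
generates anthropometry only), 8-week loops, 200-replicate recovery
studies — chosen so every property is measured on the same generative
conditions the detector is configured for.

What the simulator does **not** emulate: intraday accelerometry,
device wear-time bias, correlated multi-variable behaviour, seasonal
school-calendar effects, behaviour-change psychology beyond a constant
adherence probability, and measurement drift. Passing tests therefore
demonstrate internal correctness of the engine under its own generative
assumptions, not field performance on real wearable data.

## Degenerate inputs and edge conventions

Non-positive weights/heights, non-finite z-scores, unordered cut-offs,
unknown FFQ categories and out-of-range PAQ-C items abort with
explicit messages. Series shorter than two seasonal periods are
rejected. Breakpoint ties in the dynamic programme resolve to fewer
segments (an extra breakpoint that gains nothing is not spent); ties in
mission selection resolve by configured order; all file writes go
through a write-then-rename so failed validation never leaves partial
outputs. All randomness flows from explicit integer seeds; nothing
reads the clock for logic.

## Known limitations

Cut-offs shipped as defaults are placeholders pending a real baseline
calibration. The detector's changepoint localisation is limited by the
slope-to-noise ratio of daily step counts; day-level precision claims
should be read against that limit. The LMS fixture is synthetic;
deployments must supply a published growth reference. Education &
empowerment is carried as a single score variable, a simplification of
what a deployment would measure.
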