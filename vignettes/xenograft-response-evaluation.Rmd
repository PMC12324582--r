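---
title: "Evaluating xenograft efficacy studies: events, EFS, and objective response"
author: "xenotrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating xenograft efficacy studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenotrial)
```

## The problem

Preclinical efficacy panels treat small cohorts of tumor-bearing mice —
typically three evaluable animals per arm across a dozen or more
cell-line- and patient-derived xenograft models — and must turn noisy,
twice-weekly caliper measurements into defensible statements: did the drug
delay tumor growth, shrink tumors, or eradicate them, and in what fraction
of models? `xenotrial` implements the response-evaluation framework used by
the Pediatric Preclinical Testing Consortium (PPTC) tradition for exactly
this setting, together with a simulator that generates whole synthetic
studies with the statistical structure the analysis assumes, so the entire
pipeline is testable without animal data.

## The model and procedures

**Volumes and events.** Tumor volume is computed from calipers as
$V = 0.52\,L\,W^2$ (prolate ellipsoid, mm³). Day 0 is randomization at an
enrollment volume of about 200 ± 50 mm³; the *event* is quadrupling of the
baseline volume $V_0$. Because growth between measurements is modeled as
log-linear (piecewise exponential), the exact event time is interpolated
between the bracketing measurements $(t_1, V_1)$ and $(t_2, V_2)$:

$$t = t_1 + (t_2 - t_1)\,\frac{\ln(4V_0) - \ln V_1}{\ln V_2 - \ln V_1}.$$

If the bracketing volume is 0 the log is undefined and the package falls
back to linear interpolation, with a warning and a note in the report. Mice
that never quadruple are censored at last follow-up; mice removed for
toxicity are censored at removal (the framework does not define this case,
so the choice is logged prominently in the report notes).

**Event-free survival.** Per-arm medians come from the Kaplan–Meier
product-limit estimator: the median is the smallest event time at which
$\hat S(t) \le 0.5$. With three mice per arm treated medians are often not
reached; the last follow-up time then substitutes as a conservative bound in
both `EFS T−C` (difference of medians) and `EFS T/C` (ratio), flagged as a
bound rather than an estimate. This convention is forced by how published
panel tables pair entries like ">84" with a finite T/C.

**The Peto–Peto modified Gehan–Wilcoxon test.** Arms are compared with a
weighted log-rank statistic in which each distinct event time is weighted by
the *left-continuous pooled-sample Kaplan–Meier estimate*, emphasizing early
events:

$$U = \sum_j \hat S(t_j^-)\,(O_j - E_j), \qquad
  z = U \Big/ \sqrt{\textstyle\sum_j \hat S(t_j^-)^2 V_j},$$

with the usual hypergeometric $E_j$, $V_j$ and ties grouped at distinct
event times. Both the asymptotic normal p-value and an exact permutation
p-value (all $\binom{n}{n_A}$ group assignments) are available. The
asymptotic method is the default: published panels report p-values (e.g.
0.0339 at $n=3$ per arm) finer than the $1/20$ granularity an exact 3-vs-3
permutation allows, so the authors' computation must have been asymptotic.

*A calibration worth recording:* for the configuration that recurs across a
well-separated panel — all three control events strictly preceding all three
treated times — this statistic is $z = 1.5/\sqrt{0.5} = 2.1213$ regardless
of the treated arm's exact times, giving a two-sided $p = 0.0339$. The
recurring published value is therefore reproduced exactly by the
left-continuous weight convention, with no tuning; the exact-permutation
variant gives $p = 2/20 = 0.1$ for the same data, which is why it is kept
for validation rather than reporting.

**Relative tumor volume and response categories.** RTV$(t) = V(t)/V_0$;
minRTV is the minimum over post-baseline measurements inside the response
window (six weeks, the end of continuous dosing, by default — configurable
because follow-up in published panels clearly extended past day 70). The
per-mouse objective response measure is evaluated in priority order:

| category | rule |
|---|---|
| MCR | no measurable tumor for ≥ 3 consecutive readings after treatment ends |
| CR  | tumor not measurable at ≥ 1 reading, without meeting MCR |
| PR  | minRTV ≤ 0.5, tumor measurable at every reading |
| SD  | minRTV > 0.5 and final RTV ≤ 1.25 |
| PD  | minRTV > 0.5 and final RTV > 1.25 |

"Measurable" means recorded volume above the detection limit (default 0:
published minRTV entries of "0 ± 0" imply exact zeros were recorded).
Treated PD mice split into PD1/PD2 by whether their time-to-event exceeds
200% of the control median; control mice keep the unsplit PD label. Two
interpretive choices were genuinely open and are resolved as follows. The CR
clause "up to two times consecutively or intermittently any number of times"
is read as: any run of not-measurable readings qualifies for CR, and a run
of ≥ 3 *after treatment end* upgrades to MCR (a ≥ 3 run wholly before
treatment end remains CR, since MCR explicitly requires the tumor to stay
gone after treatment). A treated PD mouse that never quadruples is split on
its censoring time, with a warning when that time does not exceed 200% of
the control median — the censoring time is then only a lower bound on the
true event time, so PD1 is the conservative call.

**Scores, groups, panels.** Mice score PD1 = 0, PD2 = 2, SD = 4, PR = 6,
CR = 8, MCR = 10; the group median determines the overall response, with
half-way medians assigned to the lower category (a median of 9 is CR).
Studies with > 25% toxic deaths, or a control group better than SD, are
unevaluable (flagged, not dropped). Group categories map to activity tiers —
PR/CR/MCR high ("objective response"), SD/PD2 intermediate, PD1 low — and
panels summarize to the objective response rate and the anti-tumor-activity
rate (high + intermediate).

**Other metrics.** %TGI = $((\Delta TV_{vehicle} - \Delta TV_{treated}) /
\Delta TV_{vehicle}) \times 100$ on arm means (undefined when the vehicle
arm did not grow; which day is "last" with staggered removals is not
standardized, so the package uses the latest day with full vehicle data and
reports it). %BW change uses each animal's own baseline. Small-sample
two-group comparisons (V0, minRTV) use the Wilcoxon rank-sum test with a
full-enumeration exact method (midranks for ties, two-sided by distance from
the null mean) and a tie-corrected normal approximation.

## The simulator

`simulate_study()` generates whole studies from a `simulation_config()`:

- **Growth.** Piecewise-exponential latent volume — deliberately the same
  log-linear assumption the interpolation makes, so simulated event times
  have a closed form to test against (`quadrupling time = ln 4 / k`).
  Gompertz-style deceleration is out of scope. The control default
  `growth_rate = 0.105/day` puts quadrupling near 13 days, the middle of
  the control-median range seen in neuroblastoma panels (4.5–27 days).
- **Effects.** `effect_class` presets set the on-drug net rate: none,
  growth_delay, stasis, regression, cure (eradication once below the
  measurable floor), regress_regrow (regrowth after `regrow_day`).
- **Noise.** Measurement error is multiplicative lognormal with unit mean
  (`noise_cv = 0.1` default): volumes are positive and caliper error scales
  with size. Unit-mean noise keeps the log-slope unbiased, which the
  parameter-recovery tests verify (mean recovered rate within 5% of truth
  across ≥ 100 noisy mice).
- **Schedule and toxicity.** Measurements on a twice-weekly grid
  (0, 3, 7, 10, …). Weight (baseline 20 ± 1.5 g, a typical adult mouse)
  drifts down per dosed day and recovers toward baseline off drug; dosing
  pauses at a measured loss of ≥ 15% of baseline and resumes only above
  90%. Holiday decisions are made at measurement days — the same grid on
  which a real study would weigh the animals — so the pause/resume
  invariants hold at that resolution. Toxic deaths remove the mouse at a
  uniformly chosen dosed day with `fate = "toxic_death"`.
- **Endpoints.** The mouse exits at the day its latent volume crosses the
  volume cap (log-linear inversion between grid days), with a final
  measurement at the cap, or at `max_day`. Two published descriptions of
  the intermittent dosing phase disagree (two 2-week-on/off cycles vs
  7-on/7-off to day 70), so no intermittent default is asserted:
  `dosing_windows` are fully configurable and default to continuous
  [0, 42).

What the simulator does *not* emulate: pharmacokinetic exposure–response
linkage, immune effects or spontaneous (GEMM) tumor onset, inter-mouse
growth-rate heterogeneity beyond the baseline-volume draw, and measurement-
day jitter. Passing tests therefore demonstrate the pipeline's correctness
under its own model assumptions, not agreement with any particular real
study's raw data — the raw per-mouse trajectories behind published panel
tables are not public, which is precisely why group-level arithmetic
(contrasts, response rates) is validated against the published summaries
while per-mouse machinery is validated against independent oracles and
closed forms.

## Numerical choices and degenerate inputs

- Event crossing exactly at an observation uses that day; a first
  post-baseline measurement already above threshold brackets with
  $(0, V_0)$.
- KM medians use $\hat S(t) \le 0.5$ with a $10^{-12}$ slack against float
  rounding at exact 0.5 steps.
- Exact tests refuse group sizes with more than $2\times10^5$ assignments.
- A pooled sample with no events returns $p = 1$ with a warning rather than
  NaN; a weighted log-rank with zero variance returns $z = 0$.
- Report rendering rounds days and ratios to 2 decimals (matching published
  tables); all internal computation is full precision.

## Problem sizes used in the packaged checks

The packaged validation uses 3 mice/arm studies for end-to-end runs, 120–500
simulated mice for calibration checks (rate recovery, median quadrupling
time), 10,000 random trajectories for the classifier/oracle agreement, and
exact enumeration up to 6 animals per arm — sizes chosen to give tight Monte
Carlo error on a desktop while matching the arm sizes the framework is
designed for.

## Known limitations

- With $n = 3$ per arm the exact permutation test cannot reach $p < 0.1$;
  asymptotic p-values at such sizes rely on a normal approximation whose
  finite-sample accuracy is poor in the tails. Both are reported honestly;
  neither is adjusted.
- The censored-median bound makes T−C and T/C conservative lower bounds,
  not estimates, and they are flagged as such.
- minRTV group comparisons at $n = 3$ with many exact zeros are dominated
  by ties; published p-values for these columns depend on unstated tie
  conventions and are not reproduction targets.
- TGI on arm means is sensitive to which day is "last" when removals
  stagger; the package logs the day it used.
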