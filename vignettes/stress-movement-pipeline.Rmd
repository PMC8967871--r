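---
title: "Methods: simulating and analysing stress effects on rule- vs plan-based movement selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing stress effects on rule- vs plan-based movement selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmcstress)
```

## The scientific setting

In the rule-plan-motor-cognition (RPMC) paradigm a participant selects
one of two grips (pronated or supinated) for a grasp-and-rotate
movement, either by retrieving a learned if-then rule or by
prospectively planning for end-state comfort. Both routes produce the
same overt movement, so differences in response time and accuracy
isolate the selection process. The design studied here wraps two RPMC
sessions (pre and post) around a Trier Social Stress Test (TSST)
manipulation, with one group receiving the active psychosocial
stressor and a control group a matched non-evaluative protocol, and
tracks three stress channels throughout: heart rate (HR), heart-rate
variability (the time-domain vagal index RMSSD), and salivary
cortisol.

The package implements the full analysis chain as a tested pipeline —
synthetic cohort generation, marker extraction, behavioural scoring,
inference — so that every estimator can be exercised against planted
ground truth.

## Behavioural model and scoring

**Balanced Integration Score (BIS).** Speed and accuracy are combined
with equal weight: for each participant x session x approach cell,
the proportion of correct responses (PC) and the mean response time of
correct trials (RT) are z-standardized over the pooled set of all
cells of all analysed participants (sample SD), and
`BIS = z(PC) - z(RT)`. Higher is better; a cell that is faster but
proportionally less accurate by matched z-amounts scores the same,
which is the point of the measure. The standardization scope (pooled
across participants, sessions and approaches) follows the
recommendation of the BIS literature; a per-session scope would make
change scores incomparable across sessions.

**Derived summaries.** The rule-based efficiency advantage per session
is `BIS(rule) - BIS(plan)`; the behavioural change per approach is
`BIS(post) - BIS(pre)`. The headline behavioural test is the
2(group) x 2(session) x 2(approach) mixed-design repeated-measures
ANOVA of BIS and of movement time, with one observation per cell.
With 2-level within factors, sphericity holds by construction; with a
single between factor and complete cells the split-plot partitioning
is Type-III-equivalent even for unbalanced groups, and every reported
effect carries df (1, n - 2).

**Trial filtering.** Technically failed trials are removed first.
Outlying response and movement times are then flagged per cell with
the generalized extreme studentized deviate (ESD) test (Rosner), with
`alpha = 0.05` and up to 20% of the cell tested — the test is valid
only for a prespecified maximum number of outliers, and 20% is a
deliberately generous cap for reaction-time data. Participants whose
overall error rate is *strictly above* 20% are excluded entirely (the
task-comprehension rule); a participant at exactly 20% is retained.

## Physiological markers

**RR cleaning.** Artifact handling replaces visual inspection with an
automated criterion: a beat whose RR interval deviates from the
5-beat running median by more than 25% (configurable) is flagged and
linearly interpolated over beat time. The 25% threshold catches the
two canonical artifact classes — missed beats (doubled intervals) and
spurious/ectopic beats (split intervals) — while leaving physiological
variability (typically under 10% beat-to-beat) untouched. A warning is
raised when 3% or more of beats needed interpolation, the conventional
quality bound for continuous HRV recordings. Cleaning is idempotent:
a cleaned series flags nothing on a second pass.

**Marker timelines.** Heart rate is computed from the instantaneous-HR
series (60000/RR, linearly interpolated at 4 Hz) averaged over each
10-minute interval. RMSSD is computed from the cleaned RR intervals in
60-s segments shifted by 30 s (19 segments per interval) and averaged
per interval. Two choices deserve flagging:

* RMSSD is computed on RR intervals, not on the 4 Hz resampled HR
  series. The processing description this mirrors is ambiguous on
  that point, but RMSSD on a resampled series is not standard
  practice and distorts successive differences.
* Per-interval aggregation of segment RMSSD is the arithmetic mean;
  segments with fewer than 3 beats are skipped and counted.

Both HR and RMSSD are ln-transformed for analysis (as is cortisol);
a segment-mean RMSSD below 0.1 ms is treated as degenerate and
reported missing rather than `ln(0)`.

**Timeline layout.** The recording comprises a 20-min baseline and
three 30-min sessions (pre, TSST, post), each holding three contiguous
10-min intervals, indexed t1..t9 with times attached at interval
midpoints relative to stressor onset (the start of the TSST session).
The exact clock positions of the nine intervals are a package choice:
only the session structure is fixed by the design, so the three
intervals per session are laid out contiguously.

**AUC markers.** Stress reactivity is summarized by the area under
the curve with respect to increase:
`AUC_I = AUC_G - value(first) * span`, with `AUC_G` the trapezoid over
the window and the *first measurement inside the analysed window* as
baseline — that is the form of the standard repeated-measures AUC
formulas, and the analysis windows start at late-pre/onset. Windows
default to t3-t7 for HR and lnRMSSD (manipulation-centred, matching
the fast autonomic response) and t2-t5 for cortisol (onset to final
sample, accommodating the slower endocrine response). Whether t3 and
t7 belong to the flanking sessions or the TSST block is not fully
determined by the source design; the defaults follow the window labels
literally.

## Moderated regression

Two ordinary-least-squares models relate behavioural change to the
stress markers, one per approach:

```
change = b0 + b1*group + b2*AUC_I(lnCortisol) + b3*AUC_I(lnHR)
       + b4*AUC_I(lnRMSSD) + b5*group:cortisol + b6*group:HR
       + b7*group:RMSSD + b8*BMI + b9*age
```

with group dummy-coded 0 = control, 1 = stress and interactions formed
as explicit product columns. The fit reports the model F against the
intercept-only model, R², the Durbin-Watson statistic (independent
residuals expected in 1-3), and VIF per predictor. Collinearity —
which is substantial by construction, since product terms correlate
with their mains — is *reported, never auto-remediated*; that mirrors
how such exploratory models should be read. The fit requires at least
12 complete rows so the diagnostics retain at least 2 residual df.

The variance-homogeneity choice for the between-group marker
comparisons is exposed as configuration (`welch_markers`): by default
the RMSSD comparison uses the Welch form (fractional
Welch-Satterthwaite df) and HR/cortisol the pooled form. Bonferroni
correction is applied to the two per-group advantage-change tests as a
family of 2. Normality checks use the Lilliefors-corrected
Kolmogorov-Smirnov test because the normal parameters are estimated
from the data; the plain KS variant (anti-conservative in that
situation) is available as an option.

## What the synthetic generator emulates

`generate_cohort()` draws, per participant, a latent profile (speed
factor, mean RR, baseline RMSSD, cortisol baseline, TSST reactivities,
age, BMI) and emits three data channels:

* **Trials.** Response and movement times are log-normal — positive
  support and right skew typical of RT data; no distributional form is
  fixed by the source design, so this is a package choice — with
  effects acting on the cell mean: a rule-based advantage (default
  120 ms), a general session gain (80 ms), and an additional
  plan-based gain (60 ms, the session x approach interaction).
  Correctness is Bernoulli per approach (3% rule, 7% plan); technical
  failures occur at 1.89%. The 64 trials per session are split 32/32
  between approaches — an assumption, not a documented fact of the
  original design.
* **Beats.** RR intervals are Gaussian around the planted per-interval
  target with successive-difference SD set by the planted RMSSD
  (`s = RMSSD/sqrt(2)` for i.i.d. deviations); the stress group's TSST
  intervals apply +15 bpm and -15 ms RMSSD deltas. A configurable
  fraction of beats (default 1.5%, hard-capped below 10%) is corrupted
  as missed beats (doubled RR) or spurious beats (split RR), which is
  exactly the artifact phenomenology the cleaner targets.
* **Cortisol.** A flat afternoon baseline plus, for the stress group,
  a log-normal secretory pulse peaking 20 min post onset. No
  pharmacokinetics — the analysis only consumes the five samples.

**The planted moderation.** Each participant's post-minus-pre
plan-based improvement depends linearly on that participant's planted
AUC_I of ln RMSSD, with group-specific slope (control -0.125, stress
-0.125 + 0.125 = 0, in BI-units per AUC-unit converted to ms through
an explicit `bi_ms_per_unit = 120` scale). This is precisely the
quantity the group x RMSSD regression coefficient estimates, so
recovery tests close the loop from generator to inference. The
BI-unit conversion is approximate (the true pooled SD of cell means is
cohort-dependent), which matters for none of the sign/recovery
properties.

Default magnitudes were chosen once to emulate the reported scale of
the reference pattern — group differences of roughly 5-6 SE on
cortisol and HR AUC_I, ~3 on RMSSD, a moderation t around 3, a
marginal session x approach interaction (F in the 5-7 range at
n = 36), and change-score means near 1.1 (plan) and 0.4 (rule) BI
units — and then frozen.

**What it does not emulate.** Committee behaviour and protocol detail
of the TSST, circadian or menstrual-cycle endocrine structure, RT
sequential effects (fatigue, post-error slowing), correlated HR/RMSSD
dynamics within a phase (targets are piecewise-constant per interval),
or non-stationary artifacts. Passing tests therefore certify the
estimators and their calibration under a plausible generative model,
not the behaviour of any specific empirical dataset.

## Numerical and testing choices

* Trapezoids are exact for the piecewise-linear curves the AUC is
  defined on; the test suite checks agreement with a fine Riemann sum
  to 1e-9 and with hand-computed fixtures exactly.
* The mixed ANOVA is validated against a hand-written
  sums-of-squares oracle on balanced n = 6 cohorts (1e-8) and returns
  an all-zero F table for a constant response instead of 0/0.
* The ESD implementation is validated index-by-index against a naive
  transliteration of Rosner's procedure on contaminated samples; a
  zero-variance sample yields no outliers.
* Seed handling: every stochastic element derives from a single
  integer seed (`withr::with_seed`), so identical configurations give
  byte-identical cohorts, reports and JSON bundles.
* Simulation problem sizes: calibration checks use 1500 null cohorts
  of 8+8 participants with 16 trials per session (the behavioural
  type-I rate) and 500-1500 participant-level marker cohorts of 19+17
  (moderation recovery and its null). The participant-level marker
  simulator (`simulate_marker_summaries()`) shares the latent profile
  draws of the full generator but skips beat-level resampling, which
  keeps large sweeps cheap while preserving the planted moderation
  structure; one full beat-level cohort per run backs the end-to-end
  checks. Note that with very few trials per cell the discreteness of
  proportion-correct makes the BIS ANOVA only approximately calibrated
  — at 8 trials per cell the group-effect type-I rate is within the
  binomial band of 0.05 over 1500 replicates, but users analysing
  designs that small should not over-read borderline p-values.

## Known limitations

* BIS standardization pools across sessions; a per-session scope is a
  documented alternative that would change change-score magnitudes
  (not signs). Sensitivity analysis is left to the user.
* The automated artifact criterion is a stand-in for expert visual
  inspection; extreme slow drifts inside the 5-beat median window
  would evade it.
* The regressions inherit the exploratory character of the design:
  with product terms on uncentered markers, VIFs above 10 are
  expected, and coefficients should be read as descriptive.
* Group sizes below ~6 per group make the 9-predictor regression
  undefined (insufficient residual df) and the KS checks unreliable;
  the pipeline errors rather than guessing.
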