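---
title: "Methods: pose-based movement assessment and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-based movement assessment and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabpose)
library(dplyr)
```

`rehabpose` models a tele-rehabilitation workflow in which a 3D pose
estimator watches a participant exercising at home and software judges
their form against an instructor's reference performance, alongside the
screening, randomization and statistical analysis of the trial that
evaluates such a programme. This vignette records the models, the
tunable parameters, the numerical choices, and what the synthetic-data
experiments do and do not establish.

## The pose pipeline

**Landmark schema.** Streams carry 33 named landmarks per frame, indexed
0–32 (nose first, then face, upper limbs, hands, pelvis, legs, feet) —
the layout emitted by full-body trackers of the BlazePose family. The
package consumes these streams; it never runs a vision model. Axis
conventions and units are declared in stream metadata (x lateral with
the subject's left positive, y up, z toward the camera, metres by
default), not inferred: upstream estimators disagree on conventions, so
a declared contract is the only robust interface. Timestamps are
authoritative; the declared fps is advisory metadata and streams whose
spacing contradicts it by more than 10% are rejected rather than
repaired.

**Smoothing.** Tracker output jitters. `smooth_stream()` applies a
centred moving average per landmark per coordinate, default window 5
frames, shrinking the window symmetrically at the stream edges. A
centred window was chosen over causal or spline filters because its
behaviour is analytically checkable: it preserves constant and (away
from edges) linear trajectories exactly and divides white-noise variance
by the window length, both of which the tests assert. Heavier filtering
belongs upstream if an application needs it.

**Keypoint reduction.** Analysis uses 17 of the 33 points: the 10
non-nose face landmarks (indices 1–10) and the 6 hand landmarks
(17–22) are dropped as irrelevant to whole-body exercise form, while
the nose is retained as the head/torso reference. The centre of gravity
is proxied by the midpoint of the two hip landmarks — crude relative to
a true segmental-mass model, but sufficient to track weight shift and
exactly computable from any frame.

**Joint angles.** The angle at a joint is the interior angle at the
vertex landmark between the two adjacent segment vectors,
`arccos` of their normalized dot product (equivalently the triangle
cosine rule), in degrees in [0, 180]. The cosine is clamped to [−1, 1]
before `arccos` so floating-point drift near collinearity cannot produce
`NaN`. Segments shorter than 10⁻⁹ m raise a degenerate-geometry error in
scalar use; inside `extract_angle_series()` such frames yield a flagged
`NA` sample instead, because one bad frame should not abort a session.
Default joint definitions measure the elbow (shoulder–elbow–wrist),
shoulder (elbow–shoulder–hip), hip (shoulder–hip–knee), knee
(hip–knee–ankle) and ankle (knee–ankle–foot tip) on both sides; a YAML
config can redefine or extend them, since different movements emphasise
different joints.

## Templates and feedback

Movements are delimited by a fixed, instructor-supplied timeline (the
24-form routine is 24 named segments); automatic segmentation is out of
scope. Within each segment, each joint's instructor trajectory is
linearly resampled onto G = 100 equally spaced points of normalized time
— duration-invariant comparison without dynamic time warping, which is
deliberately omitted (a limitation: a learner who performs the right
shape at a locally wrong tempo is penalised).

A learner is compared by resampling their angles onto the same grid and
scanning the signed deviation curve. One finding is emitted per maximal
run of grid points whose absolute deviation exceeds the joint's
tolerance band, provided the run covers at least 10% of the grid (the
minimum-run fraction suppresses single-point flickers). The default
tolerance is 10° per joint, overridable per joint: with the synthetic
generator's 1° angle jitter this gives essentially perfect detection of
20° form errors with a false-finding rate near zero, which the
acceptance suite quantifies (≥95% / ≤5% over 100 replicates). The
direction label comes from the sign of the mean run deviation, and
messages follow the fixed grammar
`"the {side} {joint} joint is bent at too {large|small} of an angle"`.

The accuracy score is the percentage of (joint, grid-point) cells within
tolerance, per segment, with the overall score a duration-weighted mean.
No accuracy metric was prescribed by the workflow this emulates; the
cell-counting definition was chosen because it is unit-free, monotone in
deviation, and exactly checkable by counting (a fully deviated joint in
a J-joint comparison scores 100·(J−1)/J).

For live prompting, `stream_feedback()` keeps an exponentially weighted
signed deviation per joint (half-life 0.5 s) and emits when it crosses
tolerance, with a 3 s per-joint refractory period. The half-life trades
responsiveness against noise: 0.5 s detects a sustained 20° step within
about 0.4 s at 20 fps yet averages out frame-level jitter. Batch and
streaming modes agree on the deviating joint and direction for
zero-noise input, which is tested.

## Clinical assessment rules

AWGS 2019 screening: low muscle mass is ASMI < 7.0 kg/m² (men) /
< 5.7 kg/m² (women); low strength is grip < 28 / < 18 kg; low
performance is gait speed < 1.0 m/s. All comparisons are strict — the
consensus phrasing is "less than", so boundary values are not low, and
the tests pin this at the exact cut-offs. Sarcopenia is low mass plus
low strength and/or low performance; all three flags give severe
sarcopenia. Strength- or performance-only deficits are labelled
`possible_low_function` and never satisfy eligibility, which requires
age 60–75 and a sarcopenia category, with configurable boolean exclusion
flags supplied alongside the record rather than inferred.

Outcome scoring: grip is the best of the repeated dynamometer trials;
walking pace is the mean of per-trial speeds, reported to two decimal
places (rounding half-up, as measurement protocols expect, rather than
banker's rounding); at least two walk trials are required and averaged
— where a protocol is ambiguous between best-of and mean-of walk
trials, averaging was chosen as the stated reading.

Randomization is stratified by sex: within each stratum every subject
receives a seeded uniform random number, the stratum is sorted by these
numbers, and subjects are dealt round-robin to the k groups. This makes
the allocation a permutation (everyone appears once), balanced within
±1 per stratum, and exactly reproducible from the seed.

The session schedule is weeks × per-week rows (default 12 × 3 = 36
sessions of 40 min with 10 min warm-up and 5 min cool-down), stage 1
covering weeks 1–4 and stage 2 weeks 5–12.

## Statistical analysis

**Normality.** The K-S distance is computed against a normal CDF with
estimated mean and SD — the Lilliefors statistic — and its p-value by
seeded Monte-Carlo under the estimated-parameter null (default 10⁴
replicates) rather than the asymptotic table, trading a few hundred
milliseconds for correctness at small n. Rejection at α = 0.05 yields a
log-transform recommendation; the transform refuses non-positive values.

**Mixed RM-ANOVA.** For a groups × timepoints design the package fits,
from scratch, the classical decomposition: the between-group effect is
tested on subject means (the repeated-measures factor cancels), and
within-subject inference is built on orthonormalized contrast scores
Z = YC fitted against group with sum-to-zero coding. From the
general-linear-hypothesis SSCP matrices H and E it reports, per effect,
either the sphericity-assumed univariate F
(tr(H)·df_e / (tr(E)·df_h) with df multiplied by m−1) or the
Pillai-trace F approximation. Mauchly's W =
det(S)/(tr(S)/p)ᵖ on the pooled contrast covariance (error df N−k)
decides the path: when its chi-square p-value falls below 0.05, the
within and interaction effects switch to Pillai's trace; the between
effect is always univariate. Greenhouse–Geisser/Huynh–Feldt corrections
are deliberately not offered — the analysis plan this implements falls
back to the multivariate test, not to ε-correction. Both paths are
verified in the tests against independent base-R machinery
(`aov()` error strata, `mauchly.test()`, `anova.mlm(test = "Pillai")`)
to 10⁻⁹. Partial η² is always F·df₁/(F·df₁+df₂), and an invariant test
recomputes it from each reported effect's own F and dfs. Incomplete
subjects are dropped listwise with a warning, mirroring a
completed-cases analysis.

**Pairwise differences.** Within-group time contrasts (paired) and
between-group contrasts at each timepoint use the pooled within-group
covariance S of the repeated measures (df N−k): a paired contrast has
variance c′Sc/n_g, a between contrast S_tt(1/n₁+1/n₂). On a two-group or
one-group subcase this reduces exactly to the pooled or paired t
interval, which the tests assert against `t.test()`. The default is
unadjusted (LSD) comparisons, matching the common reporting style for
this design; Bonferroni is available by flag. A 500-replicate simulation
checks ~95% nominal coverage of a known post-timepoint shift.

**Power and sample size.** The between-group test in the
repeated-measures design has df₁ = k−1, df₂ = N−k and noncentrality
λ = f²·N·m/(1+(m−1)ρ): averaging m measurements with common correlation
ρ shrinks the subject-level error by m/(1+(m−1)ρ), and this λ is exactly
the noncentrality of the subject-means F test under the package's own
generative model — so analytic power and simulated power must agree,
and the acceptance suite checks they do within 0.02 over 2000
replicates. Effect size f is measured against total
(between-subject + residual) SD. The solver steps total N by k and
returns the smallest equal-group size reaching the target power;
`inflate_dropout()` applies ceiling(n·(1+rate)). Under the planning
convention f = 0.4, α = 0.05, power 0.90, k = m = 3, ρ = 0.5 the solver
returns 19 per group (power 0.868 at 17, 0.906 at 19). Published
plans for this configuration sometimes quote 17 per group; that figure
is only consistent with a smaller ρ (≈0.45) or some other unstated
calculator setting, so the package reports the convention in its output
metadata and treats 17 as a floor rather than a reproduction target.
The 20% dropout inflation of 17 is 21 and the three-group total 63,
which the chain reproduces exactly.

## The synthetic generators

`generate_motion()` places all 33 landmarks by forward kinematics from a
scripted routine: a vertical trunk, each limb chain rotated in its own
sagittal plane (shoulders and hips share the same lateral half-width so
every default joint triple lies in one plane), face and hand filler
landmarks rigidly attached so streams are schema-complete before
reduction. By construction every scripted interior angle is reproduced
exactly and bone lengths are frame-constant, so the generator is a
geometric oracle for the kinematics layer: the script → stream → angles
round trip recovers trajectories to 10⁻⁶ degrees at zero noise (the
0.5° acceptance band absorbs clamping and resampling effects). Angle
jitter (degrees) and coordinate jitter (metres) are seeded and optional.
Scripted trajectories are mean-plus-sinusoid per segment and may jump at
segment joins; tests that reason about smoothed output therefore use
continuous (single-segment) scripts, and deviation-detection tolerances
absorb boundary smear because template and learner pass through the
same smoothing.

The default property-suite routine is 2–3 segments of 3–4 s at 20 fps —
enough frames to exercise every operator while keeping 100-replicate
experiments in tens of seconds; the 24-segment routine is generated
where the count itself is the claim.

`generate_cohort()` draws value = baseline + αg + βt + (αβ)gt + bᵢ + εᵢₜ
with bᵢ ~ N(0, σ_b²), ε ~ N(0, σ_e²), i.e. compound symmetry with
ρ = σ_b²/(σ_b²+σ_e²) — exactly the power formula's assumption, which is
why the analytic/Monte-Carlo cross-check is a meaningful test. Defaults
are σ_b² = σ_e² = 0.5 (ρ = 0.5, total variance 1) and group sizes
23/24/23, the completed-cases shape of a 75-enrolled, 70-analysed
three-arm trial; the type-I-error simulation uses 23 per group and 500
replicates, inside which the interaction test's rejection rate must stay
in [0.03, 0.07]. An AR(1)-structured covariance is used in tests to
force the sphericity violation and exercise the Pillai path.

**What passing does not show.** The generators emulate geometry and
covariance structure, not reality: no soft-tissue artefact, occlusion,
estimator-specific bias, missing frames, or non-Gaussian outcome
distributions; sagittal-dominant motion only; compound symmetry rather
than the longitudinal covariance drift real cohorts show. Green tests
certify the algorithms against their stated models, not clinical
performance.

## Degenerate inputs and numerical conventions

Zero-length joint segments flag rather than crash inside series
extraction; a grid of G = 1 collapses a template to a mean pose and
warns; zero within-subject error makes the interaction F exactly 0 (and
a zero hypothesis SSCP short-circuits before any matrix inversion);
Mauchly is skipped (W = 1, p = NA) at m = 2 where sphericity is trivial;
pace rounding is half-up; all tolerances used by the tests are stated in
the tests themselves. Every stochastic routine takes a mandatory or
defaulted integer seed and is bit-reproducible under it.
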