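---
title: "Phenotyping feed intake patterns from trough-weight recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping feed intake patterns from trough-weight recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprifeed)
```

## The measurement and the question

Dairy goats housed in individual pens eat from a trough mounted on a
weighing scale. The scale records the mass of feed every 2 minutes with a
5-g resolution, from the afternoon feed delivery until refusals are
removed 22 h later. Subtracting the current weight from the weight at
delivery, converting to dry matter (DM) and scaling by body weight turns
each goat-day into a cumulative intake curve in g DM/kg BW. The question
this package addresses is whether the *shape* of that curve — how fast and
how early an animal eats — is a stable, repeatable characteristic of the
individual across days and across physiological stages (gestation,
lactation), and therefore a usable phenotype for precision livestock
farming.

`caprifeed` implements the full chain: profile construction, two
complementary curve summaries (an exponential model and a
segmentation-clustering analysis), eleven aggregate traits per goat-day,
and the statistical layer that quantifies repeatability. Because no raw
recordings ship with the package, a seeded generator produces synthetic
herds with known latent traits against which every stage is validated.

## From trough weights to intake profiles

For one goat-day with trough weights $w(t)$, body weight $BW$ and dry
matter fraction $f_{DM}$, the raw cumulative curve is

$$y(t) = \frac{(w(0) - w(t))\, f_{DM}}{BW}.$$

Load cells drift and occasionally register transient positive bumps (an
animal leaning on the trough, feed pushed back in), which would make the
cumulative curve decrease. Cleaning is a running maximum: simple,
idempotent, exact on already-monotone data, and it never changes the
final cumulative value. Isotonic least squares was considered and
rejected as over-engineered for 5-g noise.

All windows are half-open $[0, d)$ with $t = 0$ at the afternoon
delivery: the recording grid is $0, 2, \dots, 1318$ min (660 samples over
22 h) and the 15-h analysis window holds exactly 450 samples. Window
reads (e.g. intake at 90 min) take the value at the last sample before
the boundary; with this convention clipping to the full span is the
identity and nested clips compose. Gaps of up to 3 missing samples are
linearly interpolated at read time; longer gaps invalidate the goat-day,
mirroring the practice of discarding days with recording problems.

## The exponential intake model

The cumulative curve over the 15-h window is summarized by

$$y(t) = a\,(1 - e^{-bt}),$$

with $a$ the asymptote (g DM/kg BW), $b$ the fractional rate of intake
(min$^{-1}$), and $a \cdot b$ the initial rate of intake. The fit is
nonlinear least squares including the origin sample, unweighted. Rather
than iterating a two-parameter solver from heuristic starts, the package
profiles $a$ out in closed form — for fixed $b$, $\hat a(b) = \sum f y /
\sum f^2$ with $f = 1 - e^{-bt}$ — and minimizes the profiled sum of
squares over $b$ with a coarse log-spaced grid followed by
golden-section refinement. The same minimum is reached as with a
Gauss-Newton fit, but deterministically and without convergence
failures; the `converged` flag is lowered only for degenerate profiles
(no intake, or an optimum pinned to the search boundary).

`rmse_ab` is $\sqrt{SSE/n}$ without a degrees-of-freedom correction; at
$n = 450$ the difference from an $n-2$ denominator is below 0.3%. The
RMSE behaves as a meal-pattern indicator: a goat that takes most of its
feed in one early meal is fitted closely, while one spreading intake over
several bouts leaves structured residuals and a larger RMSE.

## Segmentation and the first meal

The second summary cuts the cumulative curve into linear segments at
slope change-points. Each segment is an independent least-squares line;
the segmentation minimizes total squared error plus a penalty per
change-point, solved *exactly* by dynamic programming (minimum segment
length 2 samples). By default the penalty is chosen per profile from a
small grid by a BIC-type score $n\log(RSS/n) + (3k - 1)\log n$, counting
slope, intercept and boundary per segment; ties go to fewer segments. On
a noiseless two-piece curve any reasonable penalty recovers the
breakpoint, and the test suite checks the dynamic program against
exhaustive enumeration on small grids.

Segment slopes, pooled over all goat-days of a dataset so that labels
are comparable across animals, are classified into 8 ordered clusters by
one-dimensional k-means (seeded, 25 starts), relabeled by increasing
centroid: cluster 8 holds the fastest eating rates and clusters 1–2
slopes near zero (no intake). A slope exactly on a boundary is assigned
downward — the conservative choice for meal continuation.

The first meal accumulates eating segments (cluster ≥ 3) in time order
until the first near-zero segment (cluster ≤ 2) lasting at least 30 min;
shorter interruptions do not end a meal. Because an optimal change-point
can tie one sample to either side of a true bout boundary, the meal
intake is read off the cumulative curve just outside each contiguous run
of eating segments (the sample before the run and the first sample
after); both neighbours being flat, this read is exact under ±1-sample
boundary ties. The per-segment `intake` column itself uses the
boundary convention $y(t_{end}) - y(t_{start})$, so segment intakes
telescope exactly to the 15-h intake.

## The eleven traits

Per goat-day: `ddmi` (22-h intake), `dmi90`, `dmi180`, `dmi900`
(cumulative intake at 90, 180, 900 min), the early-intake fractions
`p90 = dmi90/dmi900` and `p180 = dmi180/dmi900`, the model parameters
`a` and `ab` with `rmse_ab`, `first_meal_dmi`, and the NDF sorting
index — the NDF (cell-wall fibre) content of the intake, reconstructed by
mass balance from offered feed and refusals, divided by the NDF content
of the offered diet. An index below 1 means the goat sorted against
fibre. Days with zero 15-h intake have undefined ratios and are flagged
out of downstream statistics. Goat × period means average the available
days per trait (refusal composition may exist only on some days); cells
with fewer than two days are flagged.

## Statistical layer

The day-level model is a nested fixed-effect ANOVA: breed, goat within
breed, day within breed and goat, period, and breed × period, fitted by
sequential (type-I) sums of squares in that order; unbalanced data
(missing goat-days) are handled by least squares. Error terms follow the
nested design: breed is tested against the goat-within-breed mean
square, everything else against the residual. *Within-period
repeatability* is read off the day-within-goat test: a day-effect
p-value above 0.95 (threshold configurable) is taken as strong evidence
that days differ only by noise for a given goat. The threshold
deliberately implements the unusual "large p-value" criterion literally.

On the goat × period means, a simplified model drops the day term;
per-breed and per-period means carry pairwise grouping letters at
α = 0.05 tested against their effect's error stratum. Between-period
correlations are Pearson correlations over paired goat means with
pairwise-complete handling. The *between-period repeatability ratio* is
a one-way method-of-moments decomposition by goat:
$\sigma^2_b / (\sigma^2_b + \sigma^2_w)$, the proportion of variance
between animals — the square of the correlation expected between
repeated measures of one animal. Negative between-variance estimates
are truncated at zero. All effects are fixed with explicit error-term
mapping rather than a REML random-effects fit, which reproduces the
F-test construction this analysis tradition uses; a mixed-model refit is
an easy diagnostic but is not the primary output.

PCA of the eleven traits uses the correlation matrix — the traits mix
g/kg BW, ratios and rates, so unit-variance scaling is the only
defensible choice — with a deterministic sign convention (the dominant
loading of each component is positive). Scores feed the simplified
ANOVA per component, the same repeatability ratio, and per-goat
barycentres (the animal's mean position across periods).

## The synthetic herd generator

`simulate_herd()` emulates the study conditions: 35 goats (13 Alpine,
22 Saanen), 4 periods × 4 days, 2-min sampling over 22 h, 5-g scale,
with an optional missing-cell list whose default pattern drops 19 cells
over 13 goats (4 × 2 + 1 × 3 + 8 × 1). Only the post-afternoon window is
generated; morning feeding is out of scope.

Each goat carries latent traits: a daily intake level (breed mean plus
N(0, `sd_goat`)), an initial intake rate (log-normal, truncated to
0.4–1.2 g/kg BW/min), an eagerness (logit-normal share of the 15-h
intake taken in the first meal), a fibre-sorting intensity (gamma), and
a body weight with per-period growth. Period effects are deterministic
configured shifts, mirroring their fixed-effect treatment; day-number
effects are N(0, `sd_day`); a residual N(0, `sd_resid`) varies each
goat-period-day. Calibration anchors: breed intake levels put the
mid-lactation period means near 39 (Alpine) vs 34 (Saanen) g DM/kg BW;
default variances give goat × period trait CVs near 30%, much lower for
the sorting index; sorting intensity rises with age/period so the index
stays below 1 and decreases across periods.

A goat-day is realized as one large first bout (eagerness × target
intake at the goat's initial rate) followed by 0–6 later bouts from a
thinned renewal process with pauses of at least 30 min plus one sampling
interval, then 0–2 night bouts after the 900-min mark. Two discreteness
choices matter. First, bout boundaries are snapped to the sampling grid:
a 2-min scale cannot resolve sub-sample boundaries, and on-grid kinks
keep the latent schedule exactly recoverable, so recovery tolerances
measure noise robustness rather than sample-attribution ambiguity.
Second, the minimum pause exceeds the 30-min detection threshold by one
interval, because a pause of exactly 30 min is a knife-edge: a boundary
sample tying into the neighbouring bout shortens the detected pause
below threshold. Schedules that would overrun the window are
regenerated, dropping bouts as a last resort, so every series is valid.

The trough series is the offered as-fed mass minus the as-fed cumulative
intake, observed with N(0, 2 g) noise, rare transient positive bumps
(probability 0.002 per sample, exercising the monotone cleaning), and
quantization to the scale resolution. Refusals close the mass balance
exactly: refusal DM is offered minus intake, and the refusal NDF
fraction is solved from NDF mass conservation given the goat's sorting
intensity, capped at 0.92 to stay physical.

All randomness flows from one seed through named substreams (per stage
and per goat-day cell), so datasets are bit-reproducible and two runs
differing only in their missing lists agree on shared cells. Substream
seeds pass through a murmur-style 32-bit avalanche before seeding R's
generator: without it the near-consecutive per-cell seeds produce
correlated first draws, which visibly distorts the null distribution of
the 105-df day F-test.

`implied_icc()` gives the large-sample value of the repeatability ratio
under a variance specification — deterministic period shifts enter the
within-goat mean square, day-number effects (shared across periods) act
as extra between-goat variance, and breed mean contrasts add
between-goat variance beyond `sd_goat`² — so ICC recovery studies use
`variance_spec_for_icc()` together with equal breed means.

## What the tests do and do not show

The validation suite checks: exact design bookkeeping (560 expected
profiles, 19 missing leaving 541, 450 samples per 15-h window); exact
recovery of noiseless exponential curves and agreement of the fitted
RMSE with a dense grid-search oracle; equality of the dynamic-programming
segmentation cost with exhaustive enumeration on grids of up to 30
samples; first-meal recovery against generator truth (exact on noiseless
herds, within 5% relative error for at least 95% of profiles under 5-g
quantization, checked on 10 goats × 20 days); recovery of a true
repeatability ratio of 0.6 to within 0.05 averaged over 200 seeds at
35 goats × 4 periods; nominal 5% size of the day-within-goat F-test over
200 null seeds; and the global invariants (trait orderings, NDF mass
conservation, segment-intake telescoping, PCA variance summing to
100%). Simulation sizes were chosen so the whole suite runs in minutes
on a single core while keeping Monte-Carlo error well inside the
asserted bands.

Passing these tests shows the *machinery* is correct and calibrated on
data shaped like the generator's output: piecewise-linear bouts,
Gaussian sensor noise, exact mass balances. Real recordings differ in
ways the generator does not emulate — within-bout rate decay, nibbling
drift during pauses, scale failures that are not single-sample bumps,
diurnal structure, social or environmental disturbances, and refusal
composition measured with laboratory error. Conclusions about real
herds therefore rest on the method definitions, not on the synthetic
calibration; the generator's role is to make every contract testable,
not to certify field performance.

## Known limitations

- The segmentation fits independent lines per segment (the curve is not
  constrained to be continuous across change-points); slopes are still
  consistent for well-separated bouts.
- Slope clusters are fitted per dataset; labels are comparable within a
  run but not across runs with different herds.
- The within-period repeatability criterion (day-effect p > 0.95) is a
  literal implementation of an unusual rule; treat it as a screen, not a
  test with controlled error rates.
- `ddmi` is the intake over the 22-h recording window following the
  afternoon delivery, implemented literally; it is not a 24-h
  extrapolation.
- With a single recording day per goat-period the full ANOVA is
  unavailable (the day term is confounded); the pipeline then reports
  the simplified layers only.
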