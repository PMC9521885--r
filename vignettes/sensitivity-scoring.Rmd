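---
title: "Scoring neighborhood sensitivity to social distancing non-compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neighborhood sensitivity to social distancing non-compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsens)
```

## The problem

During an epidemic, resident complaint platforms (such as a city's 311
system) become a behavioral sensor: a complaint about social distancing
non-compliance is a response to perceived overcrowding at some establishment.
But neighborhoods differ in how much crowding they tolerate before anyone
reports it. If enforcement and outreach follow complaint volume, communities
that under-report — often lower-income and minority neighborhoods — receive
fewer resources despite comparable or worse crowding. Quantifying that
differential sensitivity is the purpose of this package.

## The model

The scoring unit is a building that pools one or more points of interest
(POIs), each with a floor area and a stream of hourly visit counts. Visits
are aggregated to six-hour intervals (half-open, anchored at 00/06/12/18
local clock time) and each open interval carries a flag for whether at least
one complaint was reported during it.

The stimulus is the **activity intensity**

$$I_{u,t} = \frac{N_{u,t}}{a_u} \times 10{,}000,$$

visits per 10,000 sq ft per six-hour interval. Two psychophysical thresholds
summarise a unit's complaint behavior:

* the **absolute threshold** $A_u$: the mean intensity over the unit's open,
  complaint-flagged intervals — the average stimulus that provoked a
  response;
* the **difference threshold** (Weber fraction) $D_u = (A_u - B_u)/B_u$,
  where $B_u$ is the mean intensity of the unit's open, complaint-free
  intervals — the *relative* excess over normal activity needed before
  someone complains.

Fechner's law combines them into a subjective sensation
$SS_u = D_u \log_{10} A_u$: a large sensation value means residents let
density climb far above baseline before reacting. The **SDS score** inverts
and rescales this over all scored units:

$$SDS_u = \left|1 - \frac{SS_u - \min SS}{\max SS - \min SS}\right| \times 100,$$

so 100 marks the most sensitive unit in the run and 0 the most tolerant.
Zip-code neighborhood scores are the plain mean of member unit scores, and
the disparity analysis classifies zips into quartiles (low / medium-low /
medium-high / high), compares covariates across quartiles with one-way ANOVA
plus Tukey's HSD, correlates scores with health indicators (Pearson), and
tests demographic composition across police-response strata (Welch t-tests
within quartiles).

A worked two-unit example: both units see 4 baseline visits per interval
(area 10,000 sq ft). One receives a complaint at 20 visits, the other at 6.
Their Weber fractions are $(20-4)/4 = 4.0$ (400%) and $(6-4)/4 = 0.5$ (50%);
the second unit reacts to a far smaller relative excursion, so it gets the
higher SDS score (100 against 0 in a two-unit normalisation).

```{r}
baseline <- activity_intensity(rep(4, 8), 10000)
difference_threshold(absolute_threshold(20), baseline)
difference_threshold(absolute_threshold(6), baseline)
```

## Parameters that matter

* **Intensity unit** — visits per 10,000 sq ft, pinned. SDS is *not*
  invariant to this unit: rescaling intensities shifts $\log A$ by a
  constant, which interacts with heterogeneous $D_u$ and reorders scores.
  The test suite asserts that the change does occur, documenting why the
  unit is fixed.
* **Log base** (`log_base`, default 10) — cosmetic. Changing base
  multiplies every $SS_u$ by the same positive constant, and min–max
  normalisation removes it; the suite verifies bit-level agreement to 1e-9
  between base 10 and base $e$.
* **`min_baseline`** (default 4) — the minimum number of open complaint-free
  intervals (about one day) required to score a unit. A mean over fewer
  intervals makes $D_u$ too noisy to rank; units below the floor go to the
  filter ledger.
* **Baseline population** (`stratified_baseline`, default `FALSE`) — by
  default $B_u$ is the whole-study mean over open complaint-free intervals,
  the literal reading of the threshold definition. The optional stratified
  mode references each complaint interval against the baseline mean of its
  own time-of-day slot, which removes diurnal confounding at the cost of
  needing history in every slot; it is off by default to keep the canonical
  definition.
* **Negative $D_u$ and $\log A_u < 0$** are kept as computed. Flooring
  either would silently compress the min–max range and bias every other
  unit's score.
* **Quartile cuts** use linear interpolation between closest ranks
  (`quantile` type 7), ties at a cut falling to the lower group, so boundary
  zips are reproducible.
* **Police-rate strata** at 0.3 and 0.6 (overridable), with Welch's
  unequal-variance t-test for the demographic comparison.

## The synthetic city

Real inputs of this kind (commercial mobility feeds joined to municipal
complaint registers) are proprietary, so the package ships a generator with
a *planted* sensitivity structure. Per POI, hourly visits are Poisson with
mean `base_rate` times a diurnal profile, zero when closed; Poisson is the
minimal integer-valued choice for sparse foot traffic. Each open six-hour
interval may receive a crowding burst (multiplier drawn from
`burst_multiplier_range`). A zip's planted threshold $\theta_z$ is the
minimum fractional excess over a POI's running baseline (the mean of its
earlier open, non-burst intervals) that triggers a complaint, emitted with
probability `report_prob`; the first two days are a warm-up with no
complaints so the running baseline exists before it is used. Covariates are
monotone transforms of $\theta_z$ (standardised rank, so an infinite
"never reports" sentinel stays well defined) plus Gaussian noise; police
action flags are Bernoulli per complaint with a per-zip probability,
independent of everything else so that disparity tests have a clean null.

Defaults (20 zips × 30 POIs × 60 days, $\theta_z$ spread evenly over
0.05–1.5, burst probability 0.05 with multipliers 1.5–6, `report_prob` 0.5,
covariate noise 0.5 on the standardised scale) were chosen once as a
plausible desk-scale city: thresholds span highly sensitive (a 5% excursion
suffices) to tolerant (activity must 2.5-fold), and burst sizes straddle the
threshold range so different $\theta_z$ censor different parts of the burst
distribution — which is what makes the thresholds identifiable downstream.
All randomness derives from one master seed through fixed child streams, so
identical configurations reproduce byte-identical tables, and every draw is
independent of $\theta$: lowering one zip's threshold can only add
complaints (a monotonicity the suite checks pathwise).

What the generator does **not** emulate: trend and weekend structure,
spatial correlation between neighboring zips, visitor cross-contamination
between POIs, complaint propensity depending on absolute crowd size rather
than the ratio (only the ratio mechanism is exposed), and reporting delays.
Passing tests therefore demonstrate that the estimator recovers a planted
ratio-threshold structure under Poisson noise — not that real complaint
streams obey that structure.

## What the checks compute

The test suite's end-to-end checks run at these problem sizes, chosen to
keep the full suite under a minute while leaving the statistics
well-resolved: oracle equivalence on fixtures of up to 20 units against an
independent straight-loop implementation (tolerance 1e-12); log-base
invariance on a 1,000-unit city; threshold recovery on the default city,
where the Spearman correlation between planted $-\theta_z$ and recovered
zip scores must reach at least 0.8 (it lands near 0.99); the disparity sign
pattern (quartile gradients monotone per planted direction, negative
case-rate and positive vaccination correlations, observed values inside
bands from re-simulating the covariate noise 200 times); and null
calibration of the ANOVA and stratified t-tests over 200 replicates against
the binomial band around the nominal 5% level.

## Degenerate inputs and numerical choices

* All sensation values equal, or fewer than two scored units → the min–max
  normalisation is undefined and the fit stops with a hard error rather than
  emitting arbitrary scores.
* A unit whose baseline mean is zero or whose $A \le 0$ cannot produce a
  finite sensation value; it is routed to the ledger.
* Duplicate (unit, hour) rows are an ambiguity error — summing them would
  double-count silently.
* Ties in sensation extremes: all tied-minimum units score 100, all
  tied-maximum units 0.
* Complaints that match no unit or no interval, malformed timestamps, and
  negative counts accumulate in the filter ledger, whose closure
  (`rows_in - dropped = rows_out` at every rule) is asserted in the suite.

## Limitations

Sensitivity and reporting propensity are confounded by design: a
neighborhood that tolerates crowding and one that notices but never reports
are indistinguishable in complaint data. The score is relative to the run's
own min–max range, so scores are comparable within a run, not across runs.
Establishment-type summaries average globally normalised scores; they do not
re-normalise per type. And the zip mean weights every scored building
equally regardless of its complaint volume.
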